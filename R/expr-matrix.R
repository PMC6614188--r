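# The expression-matrix container used throughout the package.
#
# Canonical layout is genes-as-rows, the standard orientation for bulk
# expression distributions; every downstream module assumes it.

#' Construct an expression matrix
#'
#' A thin validated container for a genes x samples grid of non-negative,
#' finite expression values (FPKM-like, unitless), with optional per-sample
#' class labels (`"normal"` / `"cancer"`) used only for evaluation.
#'
#' @param values numeric matrix, genes as rows, with unique rownames (gene
#'   IDs) and unique colnames (sample IDs).
#' @param labels optional named character vector mapping sample IDs to
#'   `"normal"` or `"cancer"`; every name must be a sample of `values`.
#' @return an object of class `expr_matrix`: the value matrix with a
#'   `labels` attribute.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' x <- expr_matrix(m, labels = c(s1 = "normal", s2 = "cancer"))
#' dim(x)
#' @export
expr_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_txa("`values` must be a numeric matrix (genes x samples)")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop_txa("`values` must carry gene IDs as rownames and sample IDs as colnames")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop_txa("duplicate gene ID(s): ", paste(utils::head(dup_g, 5L), collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop_txa("duplicate sample ID(s): ", paste(utils::head(dup_s, 5L), collapse = ", "))
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop_txa("non-finite expression value at gene '", gene_ids[rc[1L]],
             "', sample '", sample_ids[rc[2L]], "'")
  }
  neg <- which(values < 0)
  if (length(neg)) {
    rc <- arrayInd(neg[1L], dim(values))
    stop_txa("negative expression value at gene '", gene_ids[rc[1L]],
             "', sample '", sample_ids[rc[2L]], "'")
  }
  labels <- check_labels(labels, sample_ids)
  structure(values, labels = labels, class = c("expr_matrix", "matrix", "array"))
}

check_labels <- function(labels, sample_ids) {
  if (is.null(labels) || length(labels) == 0L) {
    return(NULL)
  }
  if (is.null(names(labels))) {
    stop_txa("`labels` must be a named vector (names = sample IDs)")
  }
  labels <- stats::setNames(tolower(as.character(labels)), names(labels))
  bad_tok <- setdiff(unique(labels), c("normal", "cancer"))
  if (length(bad_tok)) {
    stop_txa("unknown label token(s): ", paste(bad_tok, collapse = ", "),
             "; permitted tokens are 'normal' and 'cancer'")
  }
  dup <- unique(names(labels)[duplicated(names(labels))])
  if (length(dup)) {
    stop_txa("duplicate sample ID(s) in labels: ", paste(dup, collapse = ", "))
  }
  orphan <- setdiff(names(labels), sample_ids)
  if (length(orphan)) {
    stop_txa("label(s) for unknown sample(s): ",
             paste(utils::head(orphan, 5L), collapse = ", "))
  }
  labels
}

#' @export
print.expr_matrix <- function(x, ...) {
  lab <- attr(x, "labels")
  cat("expr_matrix: ", nrow(x), " genes x ", ncol(x), " samples\n", sep = "")
  if (!is.null(lab)) {
    tab <- table(factor(lab, levels = c("normal", "cancer")))
    cat("labels: ", tab[["normal"]], " normal, ", tab[["cancer"]], " cancer (",
        ncol(x) - length(lab), " unlabeled)\n", sep = "")
  } else {
    cat("labels: none\n")
  }
  invisible(x)
}

#' Per-sample labels of an expression matrix
#'
#' @param x an `expr_matrix`.
#' @return named character vector (possibly `NULL`).
#' @export
sample_labels <- function(x) {
  attr(x, "labels")
}

#' Subset an expression matrix by samples, keeping labels consistent
#'
#' @param x an `expr_matrix`.
#' @param samples character or integer index of samples to keep.
#' @return an `expr_matrix`.
#' @export
select_samples <- function(x, samples) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- unclass(x)[, samples, drop = FALSE]
  lab <- attr(x, "labels")
  if (!is.null(lab)) {
    lab <- lab[names(lab) %in% colnames(v)]
    if (length(lab) == 0L) lab <- NULL
  }
  expr_matrix(v, labels = lab)
}
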