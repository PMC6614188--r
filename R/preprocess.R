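# Per-gene standardization with parameters frozen on the training set.
#
# Test data are always expressed in training coordinates: the standardizer
# stores the training means/SDs (and the optional log-transform settings)
# and re-applies them verbatim, so no test-set information ever leaks into
# the standardization.

#' Log-transform an expression matrix
#'
#' Replaces every value v by `log2(v + pseudocount)`.  Expression values on
#' the FPKM scale are strongly right-skewed; the log roughly linearizes the
#' latent structure before standardization.
#'
#' @param x an [expr_matrix].
#' @param pseudocount non-negative offset added before the log; with
#'   `pseudocount = 0` every value must be strictly positive.
#' @return a plain numeric matrix of log2 expression (same dimnames); labels
#'   are preserved as an attribute when present.
#' @export
log_transform <- function(x, pseudocount = 1) {
  stopifnot(is.matrix(x), is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount >= 0)
  if (pseudocount == 0 && any(x == 0)) {
    stop_txa("pseudocount = 0 with zero expression values; log2 undefined")
  }
  out <- log2(unclass(x) + pseudocount)
  attr(out, "labels") <- attr(x, "labels")
  class(out) <- c("matrix", "array")
  out
}

new_standardizer <- function(gene_ids, means, sds, log_applied, pseudocount,
                             min_sd, n_dropped = 0L) {
  structure(list(gene_ids = gene_ids,
                 means = stats::setNames(means, gene_ids),
                 sds = stats::setNames(sds, gene_ids),
                 log_applied = log_applied,
                 pseudocount = pseudocount,
                 min_sd = min_sd,
                 n_dropped = n_dropped),
            class = "standardizer")
}

#' Fit a per-gene z-score standardizer on training data
#'
#' Computes per-gene means and standard deviations (denominator `n - 1`)
#' over the training samples.  Genes whose SD does not exceed `min_sd` are
#' dropped — near-constant genes would otherwise blow up the division — and
#' the number dropped is reported via [message()].
#'
#' @param train an [expr_matrix] with at least 2 samples.
#' @param min_sd non-negative variance-filter cutoff; genes with
#'   `sd <= min_sd` are removed.  Default `1e-8`.
#' @param log_transform logical; when `TRUE` the matrix is log2-transformed
#'   (with `pseudocount`) before computing means/SDs, and the same transform
#'   is re-applied by [apply_standardizer()].
#' @param pseudocount offset for the optional log transform.
#' @return a `standardizer` object.
#' @export
fit_standardizer <- function(train, min_sd = 1e-8, log_transform = FALSE,
                             pseudocount = 1) {
  stopifnot(is.matrix(train), is.numeric(min_sd), min_sd >= 0)
  if (ncol(train) < 2L) stop_txa("standardizer needs at least 2 training samples")
  v <- if (log_transform) {
    txanomaly::log_transform(train, pseudocount)
  } else {
    unclass(train)
  }
  n <- ncol(v)
  means <- rowMeans(v)
  sds <- sqrt(rowSums((v - means)^2) / (n - 1))
  keep <- sds > min_sd
  n_dropped <- sum(!keep)
  if (!any(keep)) stop_txa("all genes dropped by the SD filter (min_sd = ", min_sd, ")")
  if (n_dropped > 0L) {
    message("fit_standardizer: dropped ", n_dropped,
            " gene(s) with sd <= ", min_sd)
  }
  new_standardizer(gene_ids = rownames(v)[keep],
                   means = means[keep], sds = sds[keep],
                   log_applied = isTRUE(log_transform),
                   pseudocount = pseudocount, min_sd = min_sd,
                   n_dropped = as.integer(n_dropped))
}

#' Apply a frozen standardizer to an expression matrix
#'
#' Returns `(v - mean_g) / sd_g` using the training parameters only, with
#' genes ordered as in the standardizer.  Applying a standardizer to the
#' matrix it was fitted on yields per-gene mean 0 and SD 1.
#'
#' @param s a `standardizer`.
#' @param x an [expr_matrix] (or numeric matrix with gene rownames).
#' @param on_missing `"error"` (default): any standardizer gene absent from
#'   `x` is a hard error naming the first missing gene; `"intersect"`: the
#'   standardizer is first restricted to the shared genes and the
#'   restriction is reported via [message()].
#' @return numeric matrix, `length(s$gene_ids)` (or fewer, under
#'   `"intersect"`) genes x samples of `x`.
#' @export
apply_standardizer <- function(s, x, on_missing = c("error", "intersect")) {
  stopifnot(inherits(s, "standardizer"), is.matrix(x))
  on_missing <- match.arg(on_missing)
  missing <- setdiff(s$gene_ids, rownames(x))
  genes <- s$gene_ids
  if (length(missing)) {
    if (on_missing == "error") {
      stop_txa("gene '", missing[1L], "' required by the standardizer is ",
               "absent from the data (", length(missing), " missing in total)")
    }
    genes <- intersect(s$gene_ids, rownames(x))
    if (length(genes) == 0L) stop_txa("no standardizer genes present in the data")
    message("apply_standardizer: restricted to ", length(genes), " of ",
            length(s$gene_ids), " model genes present in the data")
  }
  v <- unclass(x)[genes, , drop = FALSE]
  if (s$log_applied) {
    v <- log_transform(v, s$pseudocount)
  }
  (v - s$means[genes]) / s$sds[genes]
}

#' @export
print.standardizer <- function(x, ...) {
  cat("standardizer: ", length(x$gene_ids), " genes (",
      x$n_dropped, " dropped, min_sd = ", format(x$min_sd), ")\n", sep = "")
  cat("log2 transform: ", if (x$log_applied) {
    paste0("yes (pseudocount = ", format(x$pseudocount), ")")
  } else "no", "\n", sep = "")
  invisible(x)
}
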