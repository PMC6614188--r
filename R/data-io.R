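# Delimited-text I/O for expression matrices, label sidecars, score tables,
# and the serialized model container.

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV matrix with IDs in the first row and column and returns
#' it in the canonical genes-as-rows layout regardless of the orientation on
#' disk.  Missing-value tokens are a hard error: dense matrices are assumed
#' and silent imputation is never performed.
#'
#' @param path file path.
#' @param orientation `"genes_as_rows"` (default) or `"samples_as_rows"`,
#'   describing the layout of the file.
#' @param delimiter field separator, default tab.
#' @return an [expr_matrix] (without labels; see [read_labels]).
#' @export
read_expression <- function(path,
                            orientation = c("genes_as_rows", "samples_as_rows"),
                            delimiter = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_txa("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "", row.names = NULL,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_txa("expression file needs an ID column plus data: ", path)
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  dup <- unique(row_ids[duplicated(row_ids)])
  if (length(dup)) {
    stop_txa("duplicate ID(s) in first column of ", path, ": ",
             paste(utils::head(dup, 5L), collapse = ", "))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(vals))
    stop_txa("non-numeric cell in ", path, " at row '", row_ids[rc[1L]],
             "', column '", col_ids[rc[2L]], "' (value '", raw[bad[1L]], "')")
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "samples_as_rows") vals <- t(vals)
  expr_matrix(vals)
}

#' Write an expression matrix to delimited text
#'
#' @param x an [expr_matrix].
#' @param path output file path.
#' @param delimiter field separator, default tab.
#' @param id_header name for the leading ID column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = "\t", id_header = "gene_id") {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_header
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a two-column sample-label file
#'
#' Expects `sample_id<sep>label` rows (with or without a header line named
#' `sample_id`); labels are matched case-insensitively against the permitted
#' tokens `normal` and `cancer`.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return named character vector sample_id -> `"normal"`/`"cancer"`;
#'   empty files give a zero-length vector.
#' @export
read_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_txa("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  df <- utils::read.table(text = lines, header = FALSE, sep = delimiter,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_txa("label file must have two columns: ", path)
  if (tolower(df[1L, 1L]) %in% c("sample_id", "sample", "id")) {
    df <- df[-1L, , drop = FALSE]
  }
  ids <- df[[1L]]
  labs <- tolower(df[[2L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_txa("duplicate sample ID(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(labs), c("normal", "cancer"))
  if (length(bad)) {
    stop_txa("unknown label token(s) in ", path, ": ", paste(bad, collapse = ", "),
             "; permitted tokens are 'normal' and 'cancer'")
  }
  stats::setNames(labs, ids)
}

#' Write a score table to delimited text
#'
#' Column order is `sample_id, score, log_ratio, call, true_label`; missing
#' true labels are written as the `NA` token.  Numeric columns are written
#' at full precision so a read-back reproduces the table.
#'
#' @param table a `score_table` data frame (see [classify]).
#' @param path output file path.
#' @param delimiter field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path, delimiter = "\t") {
  check_score_table(table)
  out <- table[, c("sample_id", "score", "log_ratio", "call", "true_label")]
  out$score <- format(out$score, digits = 17, trim = TRUE, scientific = TRUE)
  out$log_ratio <- format(out$log_ratio, digits = 17, trim = TRUE, scientific = TRUE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop_txa("cannot write score table to ", path, ": ",
                            conditionMessage(ok))
  invisible(path)
}

#' Read a score table written by [write_scores]
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return a `score_table` data frame.
#' @export
read_scores <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_txa("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character"))
  df$true_label <- ifelse(is.na(df$true_label), NA_character_, df$true_label)
  class(df) <- c("score_table", "data.frame")
  check_score_table(df)
  df
}

check_score_table <- function(table) {
  need <- c("sample_id", "score", "log_ratio", "call", "true_label")
  if (!is.data.frame(table) || !all(need %in% colnames(table))) {
    stop_txa("score table must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(table$score)) || any(table$score < 0)) {
    stop_txa("scores must be finite and non-negative")
  }
  bad <- setdiff(unique(table$call), c("normal", "anomaly"))
  if (length(bad)) stop_txa("unknown call token(s): ", paste(bad, collapse = ", "))
  invisible(table)
}

# ---- model container --------------------------------------------------------

MODEL_FORMAT_VERSION <- "1.0"

#' Serialize a fitted detector (with its embedded standardizer) to JSON
#'
#' The container is a single self-describing JSON document holding the
#' standardizer and the detector together under a `format_version` tag, so a
#' model can never be applied with a mismatched standardizer.
#'
#' @param model a `residual_detector` (see [fit_detector]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "residual_detector"))
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    package = "txanomaly",
    package_version = as.character(utils::packageVersion("txanomaly")),
    standardizer = unclass(model$standardizer),
    loadings = model$loadings,
    eigenvalues = model$eigenvalues,
    k = model$k,
    k_rule = model$k_rule,
    alpha = model$alpha,
    theta1 = model$theta1, theta2 = model$theta2, theta3 = model$theta3,
    h0 = model$h0, c_alpha = model$c_alpha,
    q_threshold = model$q_threshold,
    threshold_method = model$threshold_method,
    log_base = model$log_base
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           matrix = "rowmajor", null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a detector serialized by [save_detector]
#'
#' @param path file path.
#' @return a `residual_detector`.
#' @export
load_detector <- function(path) {
  if (!file.exists(path)) stop_txa("file not found: ", path)
  payload <- jsonlite::fromJSON(readLines(path), simplifyMatrix = TRUE)
  if (!identical(payload$format_version, MODEL_FORMAT_VERSION)) {
    stop_txa("unsupported model format version: ",
             payload$format_version %||% "<missing>")
  }
  s <- payload$standardizer
  std <- new_standardizer(gene_ids = as.character(s$gene_ids),
                          means = as.numeric(s$means),
                          sds = as.numeric(s$sds),
                          log_applied = isTRUE(s$log_applied),
                          pseudocount = as.numeric(s$pseudocount),
                          min_sd = as.numeric(s$min_sd),
                          n_dropped = as.integer(s$n_dropped))
  P <- payload$loadings
  if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
  rownames(P) <- std$gene_ids
  new_residual_detector(
    loadings = P,
    eigenvalues = as.numeric(payload$eigenvalues),
    k = as.integer(payload$k),
    k_rule = payload$k_rule,
    alpha = payload$alpha,
    theta1 = payload$theta1, theta2 = payload$theta2, theta3 = payload$theta3,
    h0 = payload$h0, c_alpha = payload$c_alpha,
    q_threshold = payload$q_threshold,
    threshold_method = payload$threshold_method,
    log_base = payload$log_base,
    standardizer = std
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
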