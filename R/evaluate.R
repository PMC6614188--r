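# Evaluation: confusion-matrix metrics, rank-based AUC, per-group
# log-ratio summaries, and the training-set-size subsampling experiment.
#
# The positive class is cancer/anomaly throughout; recall is computed over
# the cancer samples and specificity over the normals.

#' Confusion-matrix metrics of a labeled score table
#'
#' Counts true/false positives and negatives (anomaly call on a cancer
#' label = TP) and derives precision, recall, specificity, and accuracy.
#' A metric with a zero denominator (e.g. precision with no predicted
#' positives) is reported as `NA`, never silently as 0.
#'
#' @param table a `score_table` whose every row has a true label, with at
#'   least one cancer and one normal sample.
#' @return an `eval_report` list with fields `tp`, `fp`, `tn`, `fn`,
#'   `precision`, `recall`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(table) {
  check_score_table(table)
  if (any(is.na(table$true_label))) {
    stop_txa("confusion metrics need a true label for every sample")
  }
  pos <- table$true_label == "cancer"
  if (!any(pos) || all(pos)) {
    stop_txa("confusion metrics need at least one cancer and one normal sample")
  }
  called <- table$call == "anomaly"
  tp <- sum(called & pos)
  fp <- sum(called & !pos)
  tn <- sum(!called & !pos)
  fn <- sum(!called & pos)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = ratio(tp, tp + fp),
                 recall = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 accuracy = ratio(tp + tn, tp + fp + tn + fn)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: tp=", x$tp, " fp=", x$fp, " tn=", x$tn, " fn=", x$fn, "\n",
      sep = "")
  for (m in c("precision", "recall", "specificity", "accuracy")) {
    cat(sprintf("  %-11s %s\n", m, format(round(x[[m]], 4))))
  }
  if (!is.null(x$auc)) cat(sprintf("  %-11s %s\n", "auc", format(round(x$auc, 4))))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
             precision = x$precision, recall = x$recall,
             specificity = x$specificity, accuracy = x$accuracy,
             auc = if (is.null(x$auc)) NA_real_ else x$auc)
}

#' Mann-Whitney AUC
#'
#' The probability that a uniformly random positive sample outscores a
#' uniformly random negative one, with ties counted one half — computed
#' threshold-free from raw scores through midranks, and therefore invariant
#' to any strictly increasing transform of the scores.
#'
#' @param scores numeric per-sample scores.
#' @param labels parallel labels; `"cancer"` (or `TRUE`/`1`) marks the
#'   positive class, `"normal"` (or `FALSE`/`0`) the negative.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  pos <- if (is.character(labels) || is.factor(labels)) {
    tolower(as.character(labels)) == "cancer"
  } else {
    as.logical(labels)
  }
  if (any(is.na(pos)) || any(is.na(scores))) stop_txa("scores/labels must not be NA")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop_txa("AUC needs both a positive and a negative class")
  }
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a labeled score table: confusion metrics plus AUC
#'
#' @param table a fully labeled `score_table`.
#' @return an `eval_report` with an additional `auc` field.
#' @export
eval_report <- function(table) {
  rep <- confusion_metrics(table)
  rep$auc <- auc(table$score, table$true_label)
  rep
}

#' Per-group summaries of the score/threshold log-ratio
#'
#' Splits the log-ratio by true label — the numeric content of the familiar
#' per-group score plot where everything above 0 is called anomalous — and
#' reports machine-readable summaries suitable for plotting.  A group with
#' no samples is reported with `n = 0` and `NA` summaries.
#'
#' @param table a labeled `score_table`.
#' @return data frame with one row per group (`normal`, `cancer`) and
#'   columns `n`, `median`, `q1`, `q3`, `frac_above_threshold`.
#' @export
log_ratio_summary <- function(table) {
  check_score_table(table)
  if (all(is.na(table$true_label))) {
    stop_txa("log-ratio summary needs true labels")
  }
  groups <- c("normal", "cancer")
  out <- do.call(rbind, lapply(groups, function(g) {
    lr <- table$log_ratio[!is.na(table$true_label) & table$true_label == g]
    if (length(lr) == 0L) {
      return(data.frame(group = g, n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, frac_above_threshold = NA_real_))
    }
    qs <- stats::quantile(lr, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(group = g, n = length(lr), median = qs[2L], q1 = qs[1L],
               q3 = qs[3L], frac_above_threshold = mean(lr > 0))
  }))
  rownames(out) <- NULL
  out
}

#' Specificity versus training-set size, averaged over bootstraps
#'
#' For each requested size, draws `n_bootstraps` random subsets of the
#' training samples (without replacement within a subset, unless
#' `replace = TRUE`), refits the full pipeline — standardizer, subspace,
#' threshold — on each subset, scores the fixed test set, and averages the
#' resulting specificities.  Each (size, bootstrap) cell uses a logged
#' sub-seed derived from the master seed, so any single cell is
#' reproducible in isolation.  A size too small to fit the requested
#' components is skipped with a warning.
#'
#' @param train an [expr_matrix] of healthy training samples.
#' @param test an [expr_matrix] to score at every size; samples labeled
#'   `"normal"` (via `test_labels` or the matrix's own labels) define the
#'   specificity denominator.
#' @param sizes increasing positive training-set sizes, each at most
#'   `ncol(train)`.
#' @param n_bootstraps subset draws per size; default 10.
#' @param seed master integer seed.
#' @param test_labels optional named label vector overriding `test`'s
#'   labels.
#' @param replace draw subsets with replacement; default `FALSE`.
#' @param ... fitting options forwarded to [fit_detector()].
#' @return a `subsample_curve`: list with `sizes`, `mean_specificity`,
#'   `per_bootstrap` (size x bootstrap matrix), `n_bootstraps`, `seed`,
#'   and `sub_seeds`.
#' @export
subsample_experiment <- function(train, test, sizes, n_bootstraps = 10L,
                                 seed = 1L, test_labels = NULL,
                                 replace = FALSE, ...) {
  stopifnot(inherits(train, "expr_matrix"), inherits(test, "expr_matrix"),
            is.numeric(sizes), length(sizes) >= 1L,
            is_count(n_bootstraps), n_bootstraps >= 1L)
  sizes <- as.integer(sort(unique(sizes)))
  if (max(sizes) > ncol(train)) {
    stop_txa("max(sizes) = ", max(sizes), " exceeds the ", ncol(train),
             " available training samples")
  }
  if (is.null(test_labels)) test_labels <- attr(test, "labels")
  if (is.null(test_labels)) stop_txa("test labels are required for specificity")
  n_norm <- sum(test_labels == "normal")
  if (n_norm == 0L) stop_txa("no normal test samples; specificity undefined")

  per_boot <- matrix(NA_real_, nrow = length(sizes), ncol = n_bootstraps,
                     dimnames = list(size = sizes, bootstrap = seq_len(n_bootstraps)))
  sub_seeds <- per_boot
  for (i in seq_along(sizes)) {
    for (b in seq_len(n_bootstraps)) {
      cell_seed <- derive_seed(seed, (i - 1L) * n_bootstraps + b)
      sub_seeds[i, b] <- cell_seed
      idx <- with_seed(cell_seed, sample(ncol(train), sizes[i], replace = replace))
      sub <- select_samples(train, idx)
      fit <- tryCatch(
        suppressMessages(fit_detector(sub, ...)),
        error = function(e) e
      )
      if (inherits(fit, "error")) next
      st <- suppressMessages(predict(fit, test, labels = test_labels))
      norm_rows <- !is.na(st$true_label) & st$true_label == "normal"
      per_boot[i, b] <- mean(st$call[norm_rows] == "normal")
    }
  }
  failed <- rowSums(!is.na(per_boot)) == 0L
  if (any(failed)) {
    warning("skipped size(s) too small to fit the detector: ",
            paste(sizes[failed], collapse = ", "), call. = FALSE)
  }
  keep <- !failed
  structure(list(sizes = sizes[keep],
                 mean_specificity = rowMeans(per_boot[keep, , drop = FALSE],
                                             na.rm = TRUE),
                 per_bootstrap = per_boot[keep, , drop = FALSE],
                 n_bootstraps = as.integer(n_bootstraps),
                 seed = as.integer(seed),
                 sub_seeds = sub_seeds[keep, , drop = FALSE]),
            class = "subsample_curve")
}

#' @export
print.subsample_curve <- function(x, ...) {
  cat("subsample_curve: ", length(x$sizes), " sizes x ", x$n_bootstraps,
      " bootstraps (seed ", x$seed, ")\n", sep = "")
  print(data.frame(size = x$sizes,
                   mean_specificity = round(unname(x$mean_specificity), 4)))
  invisible(x)
}

#' @export
as.data.frame.subsample_curve <- function(x, ...) {
  data.frame(size = rep(x$sizes, x$n_bootstraps),
             bootstrap = rep(seq_len(x$n_bootstraps), each = length(x$sizes)),
             specificity = as.vector(x$per_bootstrap),
             mean_specificity = rep(unname(x$mean_specificity), x$n_bootstraps))
}

#' Write a subsampling curve as a plot-ready TSV
#'
#' @param curve a `subsample_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "subsample_curve"))
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
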