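# Core computation: principal-component subspace of standardized healthy
# data, squared-residual (Q / SPE) anomaly scores, and the false-alarm
# threshold.
#
# The subspace comes from an economy SVD of the standardized data rather
# than an explicit p x p covariance: expression matrices have tens of
# thousands of genes but at most a few hundred training samples, so the
# covariance never needs to be formed.

EIGEN_ZERO_REL <- 1e-12 # eigenvalues below this fraction of the largest are rank-0

#' Fit the principal-component subspace of standardized training data
#'
#' Eigen-decomposes the training sample covariance through the singular
#' value decomposition of the standardized genes x samples matrix:
#' eigenvalues are squared singular values divided by `n - 1`.  The number
#' of retained components `k` is either fixed or chosen as the smallest k
#' whose cumulative eigenvalue share reaches `variance_fraction`.
#'
#' @param z standardized matrix (genes x samples), at least 3 samples.
#' @param k fixed number of components to retain; overrides
#'   `variance_fraction` when non-`NULL`.
#' @param variance_fraction target cumulative variance share in (0, 1);
#'   default 0.90.
#' @return list with `loadings` (p x k orthonormal), `eigenvalues` (full
#'   non-increasing spectrum, numerically-zero values clipped to 0), `k`,
#'   and `rank`.
#' @export
fit_subspace <- function(z, k = NULL, variance_fraction = 0.90) {
  stopifnot(is.matrix(z), is.numeric(z))
  n <- ncol(z)
  if (n < 3L) stop_txa("subspace fit needs at least 3 samples")
  sv <- svd(z, nu = min(dim(z)), nv = 0L)
  lam <- sv$d^2 / (n - 1)
  lam[lam < EIGEN_ZERO_REL * lam[1L]] <- 0
  r <- sum(lam > 0)
  if (r < 2L) stop_txa("standardized data have rank < 2; cannot fit a subspace")
  if (is.null(k)) {
    stopifnot(is.numeric(variance_fraction), length(variance_fraction) == 1L,
              variance_fraction > 0, variance_fraction < 1)
    # small tolerance so an exact-boundary cumulative share is not lost to
    # floating-point rounding
    k <- which(cumsum(lam) / sum(lam) >= variance_fraction - 1e-12)[1L]
  } else {
    if (!is_count(k) || k < 1L) stop_txa("`k` must be a positive integer")
    k <- as.integer(k)
  }
  if (k >= r) {
    stop_txa("retained k = ", k, " >= rank ", r,
             ": no discarded components; residue degenerate")
  }
  P <- sv$u[, seq_len(k), drop = FALSE]
  rownames(P) <- rownames(z)
  list(loadings = P, eigenvalues = lam, k = as.integer(k), rank = as.integer(r))
}

#' Squared-residual (Q / SPE) anomaly scores
#'
#' For each standardized sample z the score is the squared Euclidean norm
#' of its component orthogonal to the retained subspace,
#' `||z - P P' z||^2` — the squared prediction error of reconstructing the
#' sample from the retained principal components.
#'
#' @param model a `residual_detector`, or directly a p x k orthonormal
#'   loadings matrix.
#' @param z standardized sample vector of length p, or a p x m matrix of
#'   samples as columns, in model gene order.
#' @return non-negative numeric vector of length m (named when `z` has
#'   colnames).
#' @export
residue_score <- function(model, z) {
  P <- if (inherits(model, "residual_detector")) model$loadings else model
  stopifnot(is.matrix(P))
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  if (nrow(z) != nrow(P)) {
    stop_txa("sample length ", nrow(z), " does not match model dimension ", nrow(P))
  }
  resid <- z - P %*% crossprod(P, z)
  stats::setNames(colSums(resid^2), colnames(z))
}

#' Jackson-Mudholkar control limit for the Q statistic
#'
#' Closed-form upper control limit `Q_alpha` targeting false-alarm rate
#' `alpha`, computed from the first three moments of the discarded
#' eigenvalue spectrum:
#' `theta_i = sum_(j>k) lambda_j^i`,
#' `h0 = 1 - 2*theta1*theta3 / (3*theta2^2)`, and
#' `Q_alpha = theta1 * (c_alpha*sqrt(2*theta2*h0^2)/theta1 + 1 +
#'  theta2*h0*(h0-1)/theta1^2)^(1/h0)`
#' with `c_alpha` the upper-`alpha` standard-normal quantile.  Under
#' approximate normality the Q statistic is a positively weighted sum of
#' chi-square variables; this is its classical normalizing-power
#' approximation from the process-surveillance literature.
#'
#' @param eigenvalues full non-increasing spectrum of the training
#'   covariance.
#' @param k number of retained components; components `k+1 ... r` form the
#'   discarded spectrum.
#' @param alpha stipulated false-alarm rate in (0, 1).
#' @return list with `theta1`, `theta2`, `theta3`, `h0`, `c_alpha`, and
#'   `q_threshold` — all intermediates are returned for auditability.
#' @export
jm_threshold <- function(eigenvalues, k, alpha = 0.05) {
  stopifnot(is.numeric(eigenvalues), is_count(k), k >= 1L,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (k >= length(eigenvalues)) stop_txa("k >= number of eigenvalues")
  disc <- eigenvalues[-seq_len(k)]
  if (all(disc <= 0)) {
    stop_txa("all discarded eigenvalues are zero; residue degenerate")
  }
  theta1 <- sum(disc)
  theta2 <- sum(disc^2)
  theta3 <- sum(disc^3)
  if (theta2 <= 0) stop_txa("theta2 must be positive")
  h0 <- 1 - 2 * theta1 * theta3 / (3 * theta2^2)
  c_alpha <- stats::qnorm(1 - alpha)
  bracket <- c_alpha * sqrt(2 * theta2 * h0^2) / theta1 + 1 +
    theta2 * h0 * (h0 - 1) / theta1^2
  if (!is.finite(bracket) || bracket <= 0) {
    stop_txa("Jackson-Mudholkar bracket term is non-positive for this ",
             "spectrum/alpha; use threshold_method = 'empirical' instead")
  }
  q <- theta1 * bracket^(1 / h0)
  list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
       h0 = h0, c_alpha = c_alpha, q_threshold = q)
}

#' Empirical false-alarm threshold from training scores
#'
#' The `1 - alpha` empirical quantile of the training residue scores, with
#' linear interpolation between order statistics.  A fallback for spectra
#' where the chi-square approximation behind [jm_threshold()] is
#' inapplicable.
#'
#' @param train_scores at least 20 non-negative training residue scores.
#' @param alpha stipulated false-alarm rate in (0, 1).
#' @return positive scalar threshold.
#' @export
empirical_threshold <- function(train_scores, alpha = 0.05) {
  stopifnot(is.numeric(train_scores), is.numeric(alpha), alpha > 0, alpha < 1)
  if (length(train_scores) < 20L) {
    stop_txa("empirical threshold needs at least 20 training scores")
  }
  unname(stats::quantile(train_scores, probs = 1 - alpha, type = 7))
}

new_residual_detector <- function(loadings, eigenvalues, k, k_rule, alpha,
                                  theta1, theta2, theta3, h0, c_alpha,
                                  q_threshold, threshold_method, log_base,
                                  standardizer) {
  structure(list(loadings = loadings, eigenvalues = eigenvalues, k = k,
                 k_rule = k_rule, alpha = alpha,
                 theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 h0 = h0, c_alpha = c_alpha, q_threshold = q_threshold,
                 threshold_method = threshold_method, log_base = log_base,
                 standardizer = standardizer),
            class = "residual_detector")
}

#' Train a complete anomaly detector on healthy expression data
#'
#' The one-call pipeline: (optional log2 transform +) per-gene z-score
#' standardization frozen on the training set, principal-component subspace
#' fit, and false-alarm threshold — together, a "tissue detector" trained
#' without a single anomalous example.
#'
#' @param train an [expr_matrix] of healthy training samples.
#' @param k,variance_fraction retained-component rule, see [fit_subspace()].
#' @param alpha stipulated false-alarm rate; default 0.05.
#' @param threshold_method `"jackson_mudholkar"` (default, closed form) or
#'   `"empirical"` (training-score quantile).
#' @param log_transform,pseudocount,min_sd standardization settings, see
#'   [fit_standardizer()].
#' @param log_base base of the reported score/threshold log-ratio; default
#'   natural log.
#' @return a `residual_detector` holding the loadings, the full eigenvalue
#'   spectrum, the threshold with all its intermediates, and the embedded
#'   standardizer.
#' @examples
#' spec <- synthetic_spec(p = 120, n_normal = 60, d = 3,
#'                        loading_scales = rep(2, 3), seed = 7)
#' x <- generate_normal(spec)
#' det <- fit_detector(x, log_transform = TRUE)
#' det
#' @export
fit_detector <- function(train,
                         k = NULL, variance_fraction = 0.90,
                         alpha = 0.05,
                         threshold_method = c("jackson_mudholkar", "empirical"),
                         log_transform = FALSE, pseudocount = 1,
                         min_sd = 1e-8, log_base = exp(1)) {
  threshold_method <- match.arg(threshold_method)
  std <- fit_standardizer(train, min_sd = min_sd,
                          log_transform = log_transform,
                          pseudocount = pseudocount)
  z <- apply_standardizer(std, train)
  sub <- fit_subspace(z, k = k, variance_fraction = variance_fraction)
  thr <- jm_threshold(sub$eigenvalues, sub$k, alpha)
  q <- thr$q_threshold
  if (threshold_method == "empirical") {
    q <- empirical_threshold(residue_score(sub$loadings, z), alpha)
  }
  k_rule <- if (is.null(k)) {
    list(rule = "variance_fraction", value = variance_fraction)
  } else {
    list(rule = "fixed_k", value = as.integer(k))
  }
  new_residual_detector(
    loadings = sub$loadings, eigenvalues = sub$eigenvalues, k = sub$k,
    k_rule = k_rule, alpha = alpha,
    theta1 = thr$theta1, theta2 = thr$theta2, theta3 = thr$theta3,
    h0 = thr$h0, c_alpha = thr$c_alpha, q_threshold = q,
    threshold_method = threshold_method, log_base = log_base,
    standardizer = std
  )
}

#' Score standardized samples and call anomalies
#'
#' Computes per-sample Q scores, calls a sample anomalous iff its score
#' strictly exceeds the threshold (a tie is called normal), and reports the
#' log-ratio of score to threshold (a zero score maps to `-Inf`).
#'
#' @param model a `residual_detector`.
#' @param z standardized matrix (model genes x samples) — use
#'   [predict.residual_detector()] to score raw expression directly.
#' @param true_labels optional named vector of `"normal"`/`"cancer"` truth
#'   for evaluation.
#' @return a `score_table` data frame with columns `sample_id`, `score`,
#'   `log_ratio`, `call`, `true_label`.
#' @export
classify <- function(model, z, true_labels = NULL) {
  stopifnot(inherits(model, "residual_detector"))
  scores <- residue_score(model, z)
  q <- model$q_threshold
  call <- ifelse(scores > q, "anomaly", "normal")
  log_ratio <- ifelse(scores == 0, -Inf, log(scores / q, base = model$log_base))
  ids <- colnames(z) %||% paste0("sample_", seq_along(scores))
  tl <- rep(NA_character_, length(ids))
  if (!is.null(true_labels)) {
    hit <- match(ids, names(true_labels))
    tl <- ifelse(is.na(hit), NA_character_, tolower(unname(true_labels[hit])))
    bad <- setdiff(stats::na.omit(unique(tl)), c("normal", "cancer"))
    if (length(bad)) stop_txa("unknown label token(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(sample_id = ids, score = unname(scores),
                    log_ratio = unname(log_ratio), call = unname(call),
                    true_label = tl, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Score raw expression data with a fitted detector
#'
#' Standardizes `newdata` with the model's frozen standardizer (applying
#' the same optional log transform) and delegates to [classify()].
#'
#' @param object a `residual_detector`.
#' @param newdata an [expr_matrix]; its `labels` attribute (or the `labels`
#'   argument) supplies the truth column of the score table.
#' @param labels optional named label vector overriding `newdata`'s labels.
#' @param on_missing gene-mismatch policy, see [apply_standardizer()].
#'   `"intersect"` additionally restricts the loadings to the shared genes.
#' @param ... unused.
#' @return a `score_table` data frame.
#' @export
predict.residual_detector <- function(object, newdata, labels = NULL,
                                      on_missing = c("error", "intersect"),
                                      ...) {
  on_missing <- match.arg(on_missing)
  z <- apply_standardizer(object$standardizer, newdata, on_missing = on_missing)
  model <- object
  if (nrow(z) < nrow(object$loadings)) {
    model$loadings <- object$loadings[rownames(z), , drop = FALSE]
  }
  if (is.null(labels)) labels <- attr(newdata, "labels")
  classify(model, z, true_labels = labels)
}

#' @export
print.residual_detector <- function(x, ...) {
  cat("residual_detector (PCA residual / Q-statistic anomaly detector)\n")
  cat("  genes: ", nrow(x$loadings), ", retained components k = ", x$k,
      " (", x$k_rule$rule, " = ", format(x$k_rule$value), "), rank = ",
      sum(x$eigenvalues > 0), "\n", sep = "")
  cat("  alpha = ", x$alpha, ", threshold = ", format(x$q_threshold),
      " (", x$threshold_method, ")\n", sep = "")
  invisible(x)
}
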