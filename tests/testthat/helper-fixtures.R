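# Shared fixtures: small matrices and score tables built in code.

# Non-negative random expression matrix with IDs.
rand_expr <- function(p, n, seed = 1, gene_prefix = "g") {
  set.seed(seed)
  m <- matrix(stats::rexp(p * n, rate = 0.1), p, n,
              dimnames = list(paste0(gene_prefix, seq_len(p)),
                              paste0("s", seq_len(n))))
  expr_matrix(m)
}

# Plain (possibly negative) Gaussian matrix, genes x samples, with IDs.
gauss_mat <- function(p, n, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(stats::rnorm(p * n, sd = sd), p, n,
         dimnames = list(paste0("g", seq_len(p)), paste0("s", seq_len(n))))
}

# Z-score a matrix per gene with its own statistics (test-side shortcut).
self_standardize <- function(m) {
  s <- fit_standardizer(m, min_sd = 0)
  apply_standardizer(s, m)
}

# Score table with prescribed confusion counts (threshold implicitly 1).
table_from_counts <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  call <- c(rep("anomaly", tp + fp), rep("normal", tn + fn))
  truth <- c(rep("cancer", tp), rep("normal", fp),
             rep("normal", tn), rep("cancer", fn))
  score <- ifelse(call == "anomaly", 2, 0.5)
  out <- data.frame(sample_id = paste0("s", seq_len(n)), score = score,
                    log_ratio = log(score), call = call, true_label = truth,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

# Principal angles (degrees) between the span of fitted loadings P and the
# span of the true loadings W expressed in standardized coordinates.
principal_angles <- function(P, W, standardizer) {
  Wstd <- W[standardizer$gene_ids, , drop = FALSE] / standardizer$sds
  Qw <- qr.Q(qr(Wstd))
  acos(pmin(1, svd(crossprod(P, Qw))$d)) * 180 / pi
}

# Small fast synthetic spec used across tests.
small_spec <- function(seed = 1, ...) {
  args <- list(p = 300L, n_normal = 160L, n_anomaly = 60L, d = 4L,
               loading_scales = rep(2, 4), noise_sd = 1, delta = 10,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

fit_quiet <- function(...) suppressMessages(fit_detector(...))
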