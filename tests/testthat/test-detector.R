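# Construct a matrix whose sample covariance has exactly the requested
# eigenvalue spectrum (padded with zeros to the ambient dimensions).
mat_with_spectrum <- function(lam, p, n, seed = 1) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(p * length(lam)), p)))
  V <- qr.Q(qr(matrix(rnorm(n * length(lam)), n)))
  m <- U %*% diag(sqrt(lam * (n - 1)), length(lam)) %*% t(V)
  dimnames(m) <- list(paste0("g", seq_len(p)), paste0("s", seq_len(n)))
  m
}

test_that("data lying in an (almost) exact low-rank subspace have negligible residues", {
  set.seed(21)
  W <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))
  scores2 <- matrix(rnorm(2 * 12), 2, 12)
  z_exact <- W[, 1:2] %*% scores2
  dimnames(z_exact) <- list(paste0("g", 1:20), paste0("s", 1:12))
  # exactly rank 2: retaining both components leaves a degenerate residue
  expect_error(fit_subspace(z_exact, k = 2), "residue degenerate")
  expect_identical(sum(fit_subspace(z_exact, k = 1)$eigenvalues > 0), 2L)

  # a vanishing third direction keeps k = 2 legal; residues are its energy
  z <- z_exact + 1e-5 * W[, 3] %*% t(rnorm(12))
  fit <- fit_subspace(z, k = 2)
  expect_lt(fit$eigenvalues[3], 1e-8 * fit$eigenvalues[1])
  expect_lt(max(residue_score(fit$loadings, z)), 1e-8)
})

test_that("SVD-path eigenvalues match a dense covariance eigendecomposition", {
  z <- gauss_mat(30, 20, seed = 31)
  zc <- z - rowMeans(z) # center so cov() and the SVD path agree
  fit <- fit_subspace(zc, k = 3)
  dense <- eigen(tcrossprod(zc) / 19, symmetric = TRUE)$values
  nz <- fit$eigenvalues > 0
  expect_equal(fit$eigenvalues[nz], dense[seq_len(sum(nz))], tolerance = 1e-8)
})

test_that("the variance-fraction rule picks the smallest sufficient k", {
  z <- mat_with_spectrum(c(0.6, 0.3, 0.08, 0.02), p = 8, n = 6)
  expect_identical(fit_subspace(z, variance_fraction = 0.9)$k, 2L)
  expect_identical(fit_subspace(z, variance_fraction = 0.95)$k, 3L)
  # reaching 0.99 needs every component: the residue would be degenerate
  expect_error(fit_subspace(z, variance_fraction = 0.99), "residue degenerate")
  expect_error(fit_subspace(z, k = 4), "residue degenerate")
})

test_that("residue scores match the explicit-projection oracle", {
  z <- gauss_mat(60, 40, seed = 41)
  fit <- fit_subspace(self_standardize(z), k = 5)
  P <- fit$loadings
  probes <- gauss_mat(60, 50, seed = 42)
  oracle <- colSums((probes - P %*% t(P) %*% probes)^2) # forms P P' explicitly
  expect_equal(unname(residue_score(P, probes)), unname(oracle),
               tolerance = 1e-8)
  # membership of the retained span scores zero
  expect_lt(residue_score(P, P[, 2]), 1e-16)
  expect_identical(unname(residue_score(P, rep(0, 60))), 0)
  expect_error(residue_score(P, rep(0, 59)), "does not match")
})

test_that("residue scores are rotation invariant and Pythagorean", {
  z <- gauss_mat(50, 30, seed = 51)
  fit <- fit_subspace(self_standardize(z), k = 4)
  P <- fit$loadings
  set.seed(52)
  R <- qr.Q(qr(matrix(rnorm(16), 4)))
  probes <- gauss_mat(50, 20, seed = 53)
  s1 <- residue_score(P, probes)
  s2 <- residue_score(P %*% R, probes)
  expect_equal(s1, s2, tolerance = 1e-8)
  # ||z||^2 = residue + ||P' z||^2
  expect_equal(unname(s1 + colSums((t(P) %*% probes)^2)),
               unname(colSums(probes^2)), tolerance = 1e-8)
  # growing the off-subspace component never decreases the score
  resid <- probes - P %*% (t(P) %*% probes)
  bumped <- probes + 0.5 * resid
  expect_true(all(residue_score(P, bumped) >= s1 - 1e-12))
})

test_that("the Jackson-Mudholkar limit reduces correctly in closed-form cases", {
  # a single discarded eigenvalue forces h0 = 1 - 2*l*l^3/(3*l^4) = 1/3
  thr <- jm_threshold(c(5, 2, 0.7), k = 2, alpha = 0.05)
  expect_equal(thr$h0, 1 / 3, tolerance = 1e-12)
  # at alpha = 0.5 the normal quantile vanishes
  thr2 <- jm_threshold(c(5, 2, 1, 0.5), k = 1, alpha = 0.5)
  expect_identical(thr2$c_alpha, 0)
  with(thr2, expect_equal(q_threshold,
                          theta1 * (1 + theta2 * h0 * (h0 - 1) / theta1^2)^(1 / h0),
                          tolerance = 1e-12))
  expect_error(jm_threshold(c(3, 2, 0, 0), k = 2, alpha = 0.05), "zero")
})

test_that("for a flat discarded spectrum the JM limit approximates the chi-square quantile", {
  # discarded eigenvalues all 1 => Q ~ chi-square with (r - k) df exactly
  lam <- rep(1, 50)
  for (alpha in c(0.01, 0.05, 0.1)) {
    q <- jm_threshold(lam, k = 5, alpha = alpha)$q_threshold
    expect_equal(q, qchisq(1 - alpha, df = 45), tolerance = 0.01)
  }
})

test_that("the empirical threshold is the interpolated upper quantile", {
  expect_gt(empirical_threshold(1:100, 0.05), 95)
  expect_lt(empirical_threshold(1:100, 0.05), 96)
  expect_identical(empirical_threshold(rep(3.5, 30), 0.2), 3.5)
  expect_error(empirical_threshold(1:19, 0.05), "at least 20")
  set.seed(61)
  thr <- empirical_threshold(runif(10000), alpha = 0.1)
  expect_gt(thr, 0.88)
  expect_lt(thr, 0.92)
})

test_that("JM and empirical thresholds agree on well-behaved Gaussian spectra", {
  z <- self_standardize(gauss_mat(40, 1200, seed = 71))
  fit <- fit_subspace(z, k = 5)
  q_jm <- jm_threshold(fit$eigenvalues, 5, alpha = 0.05)$q_threshold
  q_emp <- empirical_threshold(residue_score(fit$loadings, z), alpha = 0.05)
  expect_lt(abs(q_jm - q_emp) / q_emp, 0.15)
})

test_that("calls use a strict threshold with ties broken toward normal", {
  x <- rand_expr(30, 25, seed = 81)
  det <- fit_quiet(x, k = 3)
  z <- apply_standardizer(det$standardizer, x)
  det$q_threshold <- unname(residue_score(det, z[, 5])) # exact tie
  tab <- classify(det, z)
  expect_identical(tab$call[5], "normal")
  expect_equal(tab$log_ratio[5], 0, tolerance = 1e-12)
  # the training mean vector standardizes to the origin: score 0, call normal
  z0 <- matrix(0, nrow(z), 1, dimnames = list(rownames(z), "mean"))
  tab0 <- classify(det, z0)
  expect_identical(tab0$score, 0)
  expect_identical(tab0$call, "normal")
  expect_identical(tab0$log_ratio, -Inf)
  # anomaly <=> score above threshold <=> positive log-ratio
  expect_identical(tab$call == "anomaly", tab$score > det$q_threshold)
  expect_identical(tab$call == "anomaly", tab$log_ratio > 0)
})

test_that("a far off-subspace sample is called anomalous with positive log-ratio", {
  # at p = 300 the per-gene standardization shrinks the displacement, so a
  # decisively large delta is used to demonstrate the call rule
  spec <- small_spec(seed = 91, delta = 25)
  x <- generate_normal(spec)
  det <- fit_quiet(x, k = spec$d, log_transform = TRUE, pseudocount = 0)
  anom <- generate_anomalies(spec, truth = attr(x, "truth"))
  # delta = 10 sigma at p = 300 is a strong displacement
  tab <- predict(det, anom)
  expect_gt(mean(tab$call == "anomaly"), 0.9)
  expect_gt(median(tab$log_ratio), 0)
})
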