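# Helper: held-out samples from the healthy law of `spec`, labeled normal.
heldout_normals <- function(spec, truth, n, seed_offset = 1000L) {
  s2 <- do.call(synthetic_spec, utils::modifyList(
    unclass(spec), list(n_anomaly = as.integer(n), delta = 0,
                        anomaly_mode = "off_subspace",
                        seed = spec$seed + seed_offset)))
  h <- generate_anomalies(s2, truth = truth)
  v <- unclass(h)
  colnames(v) <- paste0("h", seq_len(ncol(v)))
  expr_matrix(v, labels = setNames(rep("normal", ncol(v)), colnames(v)))
}

test_that("generators are pure functions of spec and seed", {
  spec <- small_spec(seed = 5)
  a <- generate_normal(spec)
  b <- generate_normal(spec)
  expect_identical(unclass(a), unclass(b))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  x1 <- generate_anomalies(spec)
  x2 <- generate_anomalies(spec, truth = attr(a, "truth"))
  expect_identical(unclass(x1), unclass(x2))
  s1 <- apply_batch_shift(a, 0.4, seed = 9, pseudocount = 0)
  s2 <- apply_batch_shift(a, 0.4, seed = 9, pseudocount = 0)
  expect_identical(unclass(s1), unclass(s2))
  # a different seed changes the data
  expect_false(identical(unclass(a), unclass(generate_normal(small_spec(seed = 6)))))
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(synthetic_spec(p = 50, n_normal = 40, d = 45), "d must")
  expect_error(synthetic_spec(d = 3, loading_scales = c(1, 2)), "loading_scales")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(delta = -1), "delta")
})

test_that("loadings are orthogonal with the stated column norms", {
  spec <- small_spec(seed = 8)
  W <- attr(generate_normal(spec), "truth")$W
  G <- crossprod(W)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  expect_equal(sqrt(diag(G)), spec$loading_scales * sqrt(spec$p),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a near-noiseless rank-2 generator yields two dominant eigenvalues", {
  spec <- synthetic_spec(p = 120L, n_normal = 60L, n_anomaly = 1L, d = 2L,
                         loading_scales = rep(2, 2), noise_sd = 0.01, seed = 13)
  x <- generate_normal(spec)
  det <- fit_quiet(x, k = 2, log_transform = TRUE, pseudocount = 0)
  lam <- det$eigenvalues
  expect_lt(lam[3], 0.01 * lam[1])
})

test_that("delta = 0 anomalies are indistinguishable from healthy samples", {
  n_sig <- 0L
  for (rep_seed in 1:10) {
    spec <- small_spec(seed = rep_seed, p = 150L, n_normal = 120L,
                       n_anomaly = 40L, delta = 0)
    x <- generate_normal(spec)
    train <- select_samples(x, 1:80)
    held <- select_samples(x, 81:120)
    det <- fit_quiet(train, k = spec$d, log_transform = TRUE, pseudocount = 0)
    s_held <- predict(det, held)$score
    s_anom <- predict(det, generate_anomalies(spec, attr(x, "truth")))$score
    p <- wilcox.test(s_held, s_anom)$p.value
    n_sig <- n_sig + (p < 0.01)
  }
  expect_lte(n_sig, 1L)
})

test_that("off-subspace displacement raises scores by about its standardized energy", {
  spec <- small_spec(seed = 19, p = 400L, n_normal = 200L, n_anomaly = 100L,
                     d = 5L, loading_scales = rep(2, 5), delta = 10)
  x <- generate_normal(spec)
  det <- fit_quiet(x, k = spec$d, log_transform = TRUE, pseudocount = 0)
  held <- heldout_normals(spec, attr(x, "truth"), 100)
  anom <- generate_anomalies(spec, attr(x, "truth"))
  observed <- mean(predict(det, anom)$score) - mean(predict(det, held)$score)
  # the delta displacement is shrunk per gene by the training SD, so the
  # expected score increment is delta^2 * mean(1 / sd_g^2)
  expected <- spec$delta^2 * mean(1 / det$standardizer$sds^2)
  expect_lt(abs(observed - expected) / expected, 0.25)
})

test_that("within-subspace inflation is invisible to the residue of the true subspace", {
  spec <- small_spec(seed = 31, p = 300L, n_normal = 150L, n_anomaly = 80L,
                     d = 4L, delta = 5, anomaly_mode = "factor_inflation")
  x <- generate_normal(spec)
  det <- fit_quiet(x, k = spec$d, log_transform = TRUE, pseudocount = 0)
  # replace the fitted loadings by the true subspace in standardized coords
  s <- det$standardizer
  Wstd <- attr(x, "truth")$W[s$gene_ids, ] / s$sds
  P_true <- qr.Q(qr(Wstd))
  held <- heldout_normals(spec, attr(x, "truth"), 80)
  z_held <- apply_standardizer(s, held)
  z_anom <- apply_standardizer(s, generate_anomalies(spec, attr(x, "truth")))
  m_held <- mean(residue_score(P_true, z_held))
  m_anom <- mean(residue_score(P_true, z_anom))
  expect_lt(abs(m_anom - m_held) / m_held, 0.1)
})

test_that("detection power is monotone in the displacement magnitude", {
  # n > p keeps the threshold calibrated, so recall reflects delta alone
  recalls <- matrix(NA_real_, nrow = 10, ncol = 4)
  deltas <- c(0, 2, 5, 10)
  for (i in 1:10) {
    base <- small_spec(seed = 100 + i, p = 200L, n_normal = 400L,
                       n_anomaly = 60L, d = 5L, loading_scales = rep(2, 5))
    x <- generate_normal(base)
    det <- fit_quiet(x, k = base$d, log_transform = TRUE, pseudocount = 0)
    truth <- attr(x, "truth")
    for (j in seq_along(deltas)) {
      sp <- do.call(synthetic_spec,
                    utils::modifyList(unclass(base), list(delta = deltas[j])))
      st <- predict(det, generate_anomalies(sp, truth))
      recalls[i, j] <- mean(st$call == "anomaly")
    }
  }
  avg <- colMeans(recalls)
  expect_true(all(diff(avg) >= -0.03))
  expect_gt(avg[4], avg[1])
})

test_that("batch shifts are identity at zero and inflate false alarms otherwise", {
  # n > p so the no-shift false-alarm rate sits near alpha, not at saturation
  spec <- small_spec(seed = 43, p = 200L, n_normal = 400L, n_anomaly = 1L,
                     d = 5L, loading_scales = rep(2, 5))
  x <- generate_normal(spec)
  expect_identical(unclass(apply_batch_shift(x, 0, seed = 1)), unclass(x))

  det <- fit_quiet(x, k = spec$d, log_transform = TRUE, pseudocount = 0)
  held <- heldout_normals(spec, attr(x, "truth"), 200)
  shifted <- apply_batch_shift(held, 0.5, seed = 77, pseudocount = 0)
  far_plain <- mean(predict(det, held)$call == "anomaly")
  far_shift <- mean(predict(det, shifted)$call == "anomaly")
  expect_gt(far_shift, far_plain)
})

test_that("the fitted subspace recovers the true one under high signal-to-noise", {
  spec <- synthetic_spec(p = 500L, n_normal = 150L, n_anomaly = 1L, d = 5L,
                         loading_scales = rep(2, 5), noise_sd = 0.1, seed = 47)
  x <- generate_normal(spec)
  det <- fit_quiet(x, k = 5, log_transform = TRUE, pseudocount = 0)
  ang <- principal_angles(det$loadings, attr(x, "truth")$W, det$standardizer)
  expect_lt(max(ang), 10)
})
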