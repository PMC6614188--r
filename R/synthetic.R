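# Seeded synthetic expression generator with known low-rank latent
# structure: normal tissue lives near a d-dimensional factor subspace on
# the log scale, anomalies depart from it (or inflate within it, as a
# documented negative control), and a batch-shift stress input adds a
# shared per-gene offset.
#
# Generation happens on the log2 scale and is then exponentiated, so the
# pipeline's optional log transform roughly linearizes the structure —
# mirroring how FPKM data behave.

#' Specification of a synthetic expression data set
#'
#' Defaults describe the regime the package's experiments run in: 2000
#' genes, 300 healthy samples near a 10-dimensional latent subspace with
#' per-gene per-factor SD 3 (log2 units) over isotropic noise of SD 1, and
#' 200 anomalies displaced 10 noise-SDs off the subspace.
#'
#' @param p gene count.
#' @param n_normal healthy sample count.
#' @param n_anomaly anomalous sample count.
#' @param d latent dimension (true subspace rank), `d < min(p, n_normal)`.
#' @param loading_scales `d` positive factor strengths; factor j contributes
#'   per-gene log2-SD `loading_scales[j]` (its loading column has norm
#'   `loading_scales[j] * sqrt(p)`).
#' @param noise_sd isotropic log2-scale noise SD (sigma).
#' @param baseline_log_mean,baseline_log_sd distribution of per-gene log2
#'   intercepts.
#' @param delta anomaly displacement magnitude, in units of log2 expression
#'   (off_subspace) or as a latent scale factor (factor_inflation).
#' @param anomaly_mode `"off_subspace"` (displacement orthogonal to the
#'   latent subspace, resampled per sample) or `"factor_inflation"`
#'   (within-subspace; invisible to the residue statistic in the
#'   exact-subspace limit).
#' @param batch_shift_sd SD of the optional shared per-gene log2 offset.
#' @param pseudocount offset used when mapping log2 values back to the
#'   FPKM-like scale (`expression = max(2^L - pseudocount, 0)`).  The
#'   default 0 makes the mapping bijective (strictly positive values, no
#'   clipping), so the pipeline's log transform recovers the latent
#'   log-scale structure exactly; a positive pseudocount emulates data that
#'   were themselves shifted before logging, at the cost of clipping the
#'   low tail.
#' @param seed integer seed; every generator is a pure function of the spec
#'   plus this seed.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(p = 2000L, n_normal = 300L, n_anomaly = 200L,
                           d = 10L, loading_scales = rep(3, d), noise_sd = 1,
                           baseline_log_mean = 3, baseline_log_sd = 2,
                           delta = 10, anomaly_mode = c("off_subspace",
                                                        "factor_inflation"),
                           batch_shift_sd = 0, pseudocount = 0, seed = 1L) {
  anomaly_mode <- match.arg(anomaly_mode)
  spec <- list(p = as.integer(p), n_normal = as.integer(n_normal),
               n_anomaly = as.integer(n_anomaly), d = as.integer(d),
               loading_scales = as.numeric(loading_scales),
               noise_sd = noise_sd, baseline_log_mean = baseline_log_mean,
               baseline_log_sd = baseline_log_sd, delta = delta,
               anomaly_mode = anomaly_mode, batch_shift_sd = batch_shift_sd,
               pseudocount = pseudocount, seed = as.integer(seed))
  validate_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_spec <- function(spec) {
  with(spec, {
    if (!is_count(p) || p < 2L) stop_txa("invalid spec: p must be an integer >= 2")
    if (!is_count(n_normal) || n_normal < 2L) {
      stop_txa("invalid spec: n_normal must be an integer >= 2")
    }
    if (!is_count(n_anomaly) || n_anomaly < 0L) {
      stop_txa("invalid spec: n_anomaly must be a non-negative integer")
    }
    if (!is_count(d) || d < 1L || d >= min(p, n_normal)) {
      stop_txa("invalid spec: d must satisfy 1 <= d < min(p, n_normal)")
    }
    if (length(loading_scales) != d || any(loading_scales <= 0)) {
      stop_txa("invalid spec: loading_scales must be ", d, " positive reals")
    }
    if (!is.numeric(noise_sd) || noise_sd <= 0) {
      stop_txa("invalid spec: noise_sd must be positive")
    }
    if (!is.numeric(delta) || delta < 0) {
      stop_txa("invalid spec: delta must be non-negative")
    }
    if (!is.numeric(batch_shift_sd) || batch_shift_sd < 0) {
      stop_txa("invalid spec: batch_shift_sd must be non-negative")
    }
    if (!is.numeric(pseudocount) || pseudocount < 0) {
      stop_txa("invalid spec: pseudocount must be non-negative")
    }
  })
  invisible(spec)
}

# Deterministic sequential projection-removal (Gram-Schmidt): orthogonalize
# the columns of M in order, then give column j Euclidean norm `norms[j]`.
gram_schmidt <- function(M, norms) {
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (j > 1L) {
      for (i in seq_len(j - 1L)) {
        u <- M[, i]
        v <- v - sum(v * u) / sum(u * u) * u
      }
    }
    M[, j] <- v / sqrt(sum(v^2)) * norms[j]
  }
  M
}

# Remove the span(W) component of v and normalize to unit length.
orthogonal_unit <- function(v, W) {
  for (j in seq_len(ncol(W))) {
    u <- W[, j]
    v <- v - sum(v * u) / sum(u * u) * u
  }
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop_txa("degenerate orthogonal direction")
  v / nv
}

synthetic_truth <- function(spec) {
  with_seed(derive_seed(spec$seed, 0L), {
    mu <- stats::rnorm(spec$p, spec$baseline_log_mean, spec$baseline_log_sd)
    W <- matrix(stats::rnorm(spec$p * spec$d), spec$p, spec$d)
    W <- gram_schmidt(W, spec$loading_scales * sqrt(spec$p))
    gene_ids <- sprintf("g%05d", seq_len(spec$p))
    rownames(W) <- gene_ids
    names(mu) <- gene_ids
    list(W = W, mu = mu)
  })
}

log_to_expression <- function(L, pseudocount) {
  pmax(2^L - pseudocount, 0)
}

#' Generate healthy synthetic expression samples
#'
#' Log2-scale expression is `L = mu + W z + eps` with per-gene intercepts
#' `mu`, orthogonalized scaled loadings `W`, standard-normal latent `z` per
#' sample, and isotropic noise `eps`; reported expression is
#' `max(2^L - pseudocount, 0)`, i.e. FPKM-like and non-negative.
#'
#' @param spec a [synthetic_spec].
#' @return an [expr_matrix] with all labels `"normal"` and an attribute
#'   `truth = list(W, mu)` carrying the generating loadings and intercepts
#'   (needed by [generate_anomalies()] and the subspace-recovery checks).
#' @export
generate_normal <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  truth <- synthetic_truth(spec)
  L <- with_seed(derive_seed(spec$seed, 1L), {
    z <- matrix(stats::rnorm(spec$d * spec$n_normal), spec$d, spec$n_normal)
    eps <- matrix(stats::rnorm(spec$p * spec$n_normal, 0, spec$noise_sd),
                  spec$p, spec$n_normal)
    truth$mu + truth$W %*% z + eps
  })
  dimnames(L) <- list(sprintf("g%05d", seq_len(spec$p)),
                      sprintf("n%04d", seq_len(spec$n_normal)))
  x <- expr_matrix(log_to_expression(L, spec$pseudocount),
                   labels = stats::setNames(rep("normal", spec$n_normal),
                                            colnames(L)))
  attr(x, "truth") <- truth
  x
}

#' Generate anomalous synthetic expression samples
#'
#' In `off_subspace` mode each anomaly is `mu + W z + delta * u + eps` with
#' `u` a fresh unit vector orthogonal to every column of `W` — anomalies
#' need not resemble each other.  In `factor_inflation` mode the latent `z`
#' is scaled by `delta` instead: the displacement stays inside the modeled
#' subspace, which the residue statistic cannot see when the subspace is
#' known exactly (a documented negative control).  With `delta = 0`,
#' `off_subspace` samples follow exactly the healthy generative law.
#'
#' @param spec a [synthetic_spec] with `n_anomaly >= 1`.
#' @param truth optional `list(W, mu)` as attached by [generate_normal()];
#'   defaults to the truth implied by `spec$seed`.
#' @return an [expr_matrix] with all labels `"cancer"`.
#' @export
generate_anomalies <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  if (spec$n_anomaly < 1L) stop_txa("spec$n_anomaly must be >= 1")
  if (spec$anomaly_mode == "off_subspace" && spec$d >= spec$p) {
    stop_txa("off_subspace anomalies need d < p (no orthogonal direction exists)")
  }
  if (is.null(truth)) truth <- synthetic_truth(spec)
  L <- with_seed(derive_seed(spec$seed, 2L), {
    z <- matrix(stats::rnorm(spec$d * spec$n_anomaly), spec$d, spec$n_anomaly)
    if (spec$anomaly_mode == "factor_inflation") z <- z * spec$delta
    eps <- matrix(stats::rnorm(spec$p * spec$n_anomaly, 0, spec$noise_sd),
                  spec$p, spec$n_anomaly)
    L <- truth$mu + truth$W %*% z + eps
    if (spec$anomaly_mode == "off_subspace" && spec$delta > 0) {
      for (s in seq_len(spec$n_anomaly)) {
        u <- orthogonal_unit(stats::rnorm(spec$p), truth$W)
        L[, s] <- L[, s] + spec$delta * u
      }
    }
    L
  })
  dimnames(L) <- list(sprintf("g%05d", seq_len(spec$p)),
                      sprintf("a%04d", seq_len(spec$n_anomaly)))
  expr_matrix(log_to_expression(L, spec$pseudocount),
              labels = stats::setNames(rep("cancer", spec$n_anomaly),
                                       colnames(L)))
}

#' Apply a shared per-gene batch shift
#'
#' Adds one per-gene log2-scale offset, drawn once with SD
#' `batch_shift_sd`, to every sample: a stress input emulating the residual
#' inter-batch bias between cohorts that inflates false alarms.  With
#' `batch_shift_sd = 0` the matrix is returned unchanged.
#'
#' @param x an [expr_matrix].
#' @param batch_shift_sd non-negative offset SD (log2 units).
#' @param seed integer seed for the offset draw.
#' @param pseudocount offset used for the log2 <-> FPKM mapping; should
#'   match the generating spec.
#' @return an [expr_matrix] of the same shape and labels.
#' @export
apply_batch_shift <- function(x, batch_shift_sd, seed = 1L, pseudocount = 1) {
  stopifnot(inherits(x, "expr_matrix"), is.numeric(batch_shift_sd),
            batch_shift_sd >= 0)
  if (batch_shift_sd == 0) {
    return(x)
  }
  b <- with_seed(derive_seed(seed, 3L),
                 stats::rnorm(nrow(x), 0, batch_shift_sd))
  L <- log2(unclass(x) + pseudocount) + b
  expr_matrix(log_to_expression(L, pseudocount), labels = attr(x, "labels"))
}

#' Generate a complete labeled data set and write it to disk
#'
#' Emits three files into `dir`: `expression.tsv` (healthy plus anomalous
#' samples, genes as rows), `labels.tsv`, and `spec.yaml` echoing every
#' generator parameter and the seed.
#'
#' @param spec a [synthetic_spec].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
simulate_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  normal <- generate_normal(spec)
  combined <- normal
  if (spec$n_anomaly > 0L) {
    anom <- generate_anomalies(spec, truth = attr(normal, "truth"))
    vals <- cbind(unclass(normal), unclass(anom))
    combined <- expr_matrix(vals, labels = c(attr(normal, "labels"),
                                             attr(anom, "labels")))
  }
  if (spec$batch_shift_sd > 0) {
    combined <- apply_batch_shift(combined, spec$batch_shift_sd,
                                  seed = spec$seed,
                                  pseudocount = spec$pseudocount)
  }
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             spec = file.path(dir, "spec.yaml"))
  write_expression(combined, paths[["expression"]])
  lab <- attr(combined, "labels")
  utils::write.table(data.frame(sample_id = names(lab), label = unname(lab)),
                     paths[["labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(spec), paths[["spec"]])
  invisible(paths)
}
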