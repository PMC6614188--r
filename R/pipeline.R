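# End-to-end runs wiring the stages together: simulate -> fit -> score ->
# curve.  Each command takes a fully-explicit config (defaults are filled
# in and echoed to the run log), so every run is reproducible from its
# logged config plus the master seed.

run_defaults <- list(
  delimiter = "\t",
  orientation = "genes_as_rows",
  log_transform = FALSE,
  pseudocount = 1,
  min_sd = 1e-8,
  on_missing = "error",
  k = NULL,
  variance_fraction = 0.90,
  alpha = 0.05,
  threshold_method = "jackson_mudholkar",
  log_base = exp(1),
  sizes = NULL,
  n_bootstraps = 10L,
  seed = 1L
)

#' Assemble a run configuration
#'
#' Merges user settings (a list or a YAML file path) over the package
#' defaults; unknown keys are an error.  All values, defaults included, are
#' echoed by the run commands so a threshold is always auditable after the
#' fact.
#'
#' @param config named list of settings, or the path of a YAML file
#'   containing one.
#' @param ... individual settings overriding `config`.
#' @return a complete named list of settings.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  over <- list(...)
  config[names(over)] <- over
  known <- c(names(run_defaults), "train", "test", "labels", "model",
             "output_dir", "spec")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_txa("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  out <- run_defaults
  out[names(config)] <- config
  out
}

log_config <- function(stage, config) {
  shown <- vapply(config, function(v) {
    if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
  }, character(1L))
  message(stage, " config: ",
          paste(names(shown), shown, sep = "=", collapse = " "))
}

#' Fit a detector from files
#'
#' Reads the training matrix, runs standardization + subspace fit +
#' thresholding, and writes the serialized model container.
#'
#' @param config see [run_config()]; uses `train` (expression TSV path),
#'   `model` (output path), and the preprocessing/detector settings.
#' @return the fitted `residual_detector`, invisibly.
#' @export
run_fit <- function(config) {
  config <- run_config(config)
  if (is.null(config$train) || is.null(config$model)) {
    stop_txa("run_fit needs config$train and config$model paths")
  }
  log_config("fit", config[c("train", "model", "log_transform", "pseudocount",
                             "min_sd", "k", "variance_fraction", "alpha",
                             "threshold_method")])
  train <- read_expression(config$train, orientation = config$orientation,
                           delimiter = config$delimiter)
  model <- withCallingHandlers(
    fit_detector(train, k = config$k,
                 variance_fraction = config$variance_fraction,
                 alpha = config$alpha,
                 threshold_method = config$threshold_method,
                 log_transform = config$log_transform,
                 pseudocount = config$pseudocount,
                 min_sd = config$min_sd, log_base = config$log_base),
    error = function(e) stop_txa("fit stage: ", conditionMessage(e))
  )
  save_detector(model, config$model)
  message("fit: n=", ncol(train), " p=", nrow(train), " k=", model$k,
          " alpha=", model$alpha,
          " threshold=", format(model$q_threshold),
          " dropped_genes=", model$standardizer$n_dropped)
  invisible(model)
}

#' Score test data from files
#'
#' Loads a serialized model, standardizes the test matrix with the frozen
#' standardizer, scores and calls every sample, and writes the score table;
#' when labels are supplied, an evaluation report and a log-ratio summary
#' are written as well.
#'
#' @param config see [run_config()]; uses `model`, `test`, optional
#'   `labels`, and `output_dir`.
#' @return the `score_table`, invisibly.
#' @export
run_score <- function(config) {
  config <- run_config(config)
  if (is.null(config$model) || is.null(config$test) ||
      is.null(config$output_dir)) {
    stop_txa("run_score needs config$model, config$test and config$output_dir")
  }
  log_config("score", config[c("model", "test", "labels", "output_dir",
                               "on_missing")])
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_detector(config$model)
  test <- read_expression(config$test, orientation = config$orientation,
                          delimiter = config$delimiter)
  labels <- if (!is.null(config$labels)) read_labels(config$labels,
                                                     config$delimiter)
  table <- predict(model, test, labels = labels,
                   on_missing = config$on_missing)
  write_scores(table, file.path(config$output_dir, "scores.tsv"))
  if (!is.null(labels) && length(labels)) {
    labeled <- table[!is.na(table$true_label), , drop = FALSE]
    if (length(unique(labeled$true_label)) == 2L) {
      rep <- eval_report(labeled)
      utils::write.table(as.data.frame(rep),
                         file.path(config$output_dir, "eval_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(log_ratio_summary(table),
                       file.path(config$output_dir, "log_ratio_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message("score: ", nrow(table), " samples, ",
          sum(table$call == "anomaly"), " called anomalous")
  invisible(table)
}

#' Run the training-set-size subsampling experiment from files
#'
#' @param config see [run_config()]; uses `train`, `test`, `labels`,
#'   `sizes`, `n_bootstraps`, `seed`, `output_dir`, and the fitting
#'   settings.
#' @return the `subsample_curve`, invisibly.
#' @export
run_curve <- function(config) {
  config <- run_config(config)
  if (is.null(config$train) || is.null(config$test) ||
      is.null(config$labels) || is.null(config$sizes) ||
      is.null(config$output_dir)) {
    stop_txa("run_curve needs config$train, config$test, config$labels, ",
             "config$sizes and config$output_dir")
  }
  log_config("curve", config[c("train", "test", "labels", "sizes",
                               "n_bootstraps", "seed")])
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  train <- read_expression(config$train, orientation = config$orientation,
                           delimiter = config$delimiter)
  test <- read_expression(config$test, orientation = config$orientation,
                          delimiter = config$delimiter)
  labels <- read_labels(config$labels, config$delimiter)
  curve <- subsample_experiment(
    train, test, sizes = config$sizes, n_bootstraps = config$n_bootstraps,
    seed = config$seed, test_labels = labels,
    k = config$k, variance_fraction = config$variance_fraction,
    alpha = config$alpha, threshold_method = config$threshold_method,
    log_transform = config$log_transform, pseudocount = config$pseudocount,
    min_sd = config$min_sd, log_base = config$log_base
  )
  write_curve(curve, file.path(config$output_dir, "subsample_curve.tsv"))
  invisible(curve)
}

#' Generate a synthetic data set from a spec file or spec object
#'
#' @param config see [run_config()]; uses `spec` (a [synthetic_spec], or a
#'   YAML file of its fields) and `output_dir`.
#' @return file paths, invisibly (see [simulate_dataset()]).
#' @export
run_simulate <- function(config) {
  config <- run_config(config)
  if (is.null(config$spec) || is.null(config$output_dir)) {
    stop_txa("run_simulate needs config$spec and config$output_dir")
  }
  spec <- config$spec
  if (is.character(spec)) {
    spec <- do.call(synthetic_spec, yaml::read_yaml(spec))
  } else if (!inherits(spec, "synthetic_spec")) {
    spec <- do.call(synthetic_spec, as.list(spec))
  }
  log_config("simulate", unclass(spec))
  simulate_dataset(spec, config$output_dir)
}
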