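#' Assemble and validate the pipeline configuration
#'
#' Collects every tunable of the selection and evaluation stages, with
#' defaults matching the pipeline's study design: 75/25 stratified splits,
#' 10-fold inner cross-validation, 100 selection iterations with a strict
#' ">90 appearances" stability threshold, and 1000 evaluation resamples.
#'
#' @param alpha elastic-net mixing parameter in `[0, 1]`: 1 is the LASSO,
#'   0.5 the default Elastic Net. May be a vector to run several methods.
#' @param lambda_grid `"auto"` (100 log-spaced values from the data-derived
#'   `lambda_max` down to `1e-4 * lambda_max`, recomputed on each training
#'   split) or a decreasing positive numeric vector.
#' @param n_folds folds of the inner cross-validation.
#' @param cv_rule how the cross-validated penalty is picked: `"1se"`
#'   (default; largest penalty within one standard error of the deviance
#'   minimum, favouring sparse, stable selections) or `"min"` (the deviance
#'   minimum itself).
#' @param n_iterations number of stability-selection iterations.
#' @param appearance_threshold a feature is stable when its appearance count
#'   is strictly greater than this.
#' @param train_fraction proportion of samples in each training split.
#' @param n_resamples resamples for panel evaluation and the permutation
#'   null.
#' @param max_panel_size largest panel enumerated in the combinatorial
#'   search; `NULL` means all sizes when the stable set has at most 10
#'   features, otherwise sizes up to 3.
#' @param seed master seed; every random stream in a run derives from it.
#' @return a validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alpha = c(1, 0.5), lambda_grid = "auto",
                            n_folds = 10, cv_rule = c("1se", "min"),
                            n_iterations = 100,
                            appearance_threshold = 90,
                            train_fraction = 0.75, n_resamples = 1000,
                            max_panel_size = NULL, seed = 1) {
  cv_rule <- match.arg(cv_rule)
  cfg <- list(alpha = alpha, lambda_grid = lambda_grid, n_folds = n_folds,
              cv_rule = cv_rule, n_iterations = n_iterations,
              appearance_threshold = appearance_threshold,
              train_fraction = train_fraction, n_resamples = n_resamples,
              max_panel_size = max_panel_size, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
    if (!identical(lambda_grid, "auto")) {
      if (!is.numeric(lambda_grid) || !length(lambda_grid) ||
          any(lambda_grid < 0))
        stop("lambda_grid must be 'auto' or a positive numeric vector")
      if (is.unsorted(rev(lambda_grid), strictly = TRUE))
        stop("lambda_grid must be strictly decreasing")
    }
    if (train_fraction <= 0 || train_fraction >= 1)
      stop("train_fraction must be in (0, 1)")
    if (appearance_threshold > n_iterations)
      stop("appearance_threshold exceeds n_iterations")
    if (n_folds < 2) stop("n_folds must be at least 2")
    if (!cv_rule %in% c("min", "1se")) stop("cv_rule must be 'min' or '1se'")
    if (n_resamples < 1) stop("n_resamples must be positive")
  })
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat("  alpha:               ", paste(x$alpha, collapse = ", "), "\n")
  cat("  lambda grid:         ",
      if (identical(x$lambda_grid, "auto")) "auto (100 log-spaced)"
      else paste0(length(x$lambda_grid), " values"), "\n")
  cat("  inner CV folds:      ", x$n_folds, sprintf("(%s rule)", x$cv_rule),
      "\n")
  cat("  iterations:          ", x$n_iterations, "\n")
  cat("  stability threshold: >", x$appearance_threshold, "\n")
  cat("  train fraction:      ", x$train_fraction, "\n")
  cat("  evaluation resamples:", x$n_resamples, "\n")
  cat("  seed:                ", x$seed, "\n")
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys `input`, `outcome_column`, `probe_map`, `simulate`, `sep`,
#' `transpose` and `scale` describe the data source and are passed through;
#' all remaining keys override [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return list with elements `config` (a `pipeline_config`) and `data`
#'   (data-source fields).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  data_keys <- c("input", "outcome_column", "probe_map", "simulate", "sep",
                 "transpose", "scale")
  cfg_args <- raw[setdiff(names(raw), data_keys)]
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg_args), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg_args$alpha <- unlist(cfg_args$alpha)
  if (!is.null(cfg_args$lambda_grid) &&
      !identical(cfg_args$lambda_grid, "auto"))
    cfg_args$lambda_grid <- unlist(cfg_args$lambda_grid)
  list(config = do.call(pipeline_config, cfg_args), data = raw[data_keys])
}

# derive a stream of per-task seeds from one master seed so that tasks are
# reproducible and order-independent
spawn_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}
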