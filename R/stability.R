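#' Stability selection by iterated penalized regression
#'
#' The core selection procedure: for each of `n_iterations` iterations a
#' fresh stratified train/test split is drawn, the penalty is optimised by
#' stratified k-fold cross-validation on the training part, a penalized
#' logistic model is fitted at the chosen penalty, and every feature with a
#' nonzero coefficient is recorded as "appearing". Features appearing
#' strictly more than `appearance_threshold` times across iterations form
#' the stable set of candidate biomarkers. Per-iteration coefficients are
#' retained for the weight-distribution display.
#'
#' Each iteration runs on its own RNG stream derived from the master seed,
#' so results are bit-reproducible and independent of iteration order.
#'
#' @param x preprocessed numeric matrix (samples x features), standardized.
#' @param y two-level factor aligned with `x` (second level positive).
#' @param config a [pipeline_config()]; its single `alpha` is used — call
#'   once per method when comparing LASSO and Elastic Net.
#' @param alpha optional override of `config$alpha` (must be length 1).
#' @return object of class `"selection_profile"`: list with
#'   `counts` (named appearance counts), `coef_matrix` (features x
#'   iterations matrix of fitted coefficients), `stable_set` (character),
#'   `lambdas` (chosen penalty per iteration), `alpha`, `threshold`,
#'   `n_iterations`, `config`.
#' @examples
#' sim <- simulate_omics(n_samples = 60, n_features = 12, n_informative = 2,
#'                       effect_size = 2.5, seed = 1)
#' cfg <- pipeline_config(alpha = 1, n_iterations = 10,
#'                        appearance_threshold = 9, seed = 1)
#' prof <- stability_select(autoscale(sim$x), sim$y, cfg)
#' prof$stable_set
#' @export
stability_select <- function(x, y, config = pipeline_config(),
                             alpha = NULL) {
  validate_config(config)
  if (is.null(alpha)) alpha <- config$alpha[1L]
  stopifnot(length(alpha) == 1L, is.factor(y), nlevels(y) == 2L,
            nrow(x) == length(y))
  if (anyNA(x)) stop("preprocess the matrix before selection (missing values)")

  n_iter <- config$n_iterations
  seeds <- spawn_seeds(config$seed, n_iter)
  p <- ncol(x)
  coef_matrix <- matrix(0, p, n_iter,
                        dimnames = list(colnames(x), NULL))
  lambdas <- numeric(n_iter)

  for (i in seq_len(n_iter)) {
    res <- tryCatch({
      set.seed(seeds[i])
      sp <- stratified_split(y, config$train_fraction)
      xtr <- x[sp$train, , drop = FALSE]
      ytr <- y[sp$train]
      grid <- if (identical(config$lambda_grid, "auto"))
        auto_lambda_grid(xtr, ytr, alpha) else config$lambda_grid
      cv <- cv_optimize_penalty(xtr, ytr, alpha, config$n_folds, grid,
                                rule = config$cv_rule)
      fit <- fit_path(xtr, ytr, alpha, grid)
      cf <- stats::predict(fit, s = cv$lambda, type = "coefficients")
      list(beta = as.numeric(cf)[-1L], lambda = cv$lambda)
    }, error = function(e) {
      stop("selection iteration ", i, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    coef_matrix[, i] <- res$beta
    lambdas[i] <- res$lambda
  }

  counts <- rowSums(coef_matrix != 0)
  stable <- names(counts)[counts > config$appearance_threshold]
  structure(list(counts = counts, coef_matrix = coef_matrix,
                 stable_set = stable, lambdas = lambdas, alpha = alpha,
                 threshold = config$appearance_threshold,
                 n_iterations = n_iter, config = config),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  method <- if (x$alpha == 1) "LASSO" else
    sprintf("Elastic Net (alpha = %g)", x$alpha)
  cat(sprintf("Stability selection profile — %s\n", method))
  cat(sprintf("  %d features, %d iterations, stability threshold > %d\n",
              length(x$counts), x$n_iterations, x$threshold))
  cat(sprintf("  stable set: %d feature(s)", length(x$stable_set)))
  if (length(x$stable_set))
    cat(": ", paste(x$stable_set, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.selection_profile <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[df$appearance_count > 0, , drop = FALSE]
  cat("Features with at least one appearance:\n")
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("  ... and", nrow(df) - 20, "more\n")
  invisible(df)
}

#' Tabulate a selection profile
#'
#' @param x a `"selection_profile"`.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return data.frame with columns `feature`, `appearance_count`,
#'   `mean_coefficient`, `median_coefficient`, `in_stable_set`, ordered by
#'   decreasing appearance count.
#' @export
as.data.frame.selection_profile <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  cm <- x$coef_matrix
  mean_nz <- apply(cm, 1L, function(b) {
    nz <- b[b != 0]
    if (length(nz)) mean(nz) else 0
  })
  median_nz <- apply(cm, 1L, function(b) {
    nz <- b[b != 0]
    if (length(nz)) stats::median(nz) else 0
  })
  df <- data.frame(feature = names(x$counts),
                   appearance_count = as.integer(x$counts),
                   mean_coefficient = mean_nz,
                   median_coefficient = median_nz,
                   in_stable_set = names(x$counts) %in% x$stable_set,
                   stringsAsFactors = FALSE)
  df[order(-df$appearance_count, df$feature), , drop = FALSE]
}

#' Coefficients of a selection profile
#'
#' @param object a `"selection_profile"`.
#' @param ... unused.
#' @return the features x iterations coefficient matrix.
#' @export
coef.selection_profile <- function(object, ...) object$coef_matrix

#' Frequency-ranking bar chart of a selection profile
#'
#' Plots appearance counts of the most frequently selected features, the
#' display used to judge selection stability; the dashed line marks the
#' stability threshold.
#'
#' @param x a `"selection_profile"`.
#' @param top number of top-ranked features to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.selection_profile <- function(x, top = 20, ...) {
  df <- as.data.frame(x)
  df <- utils::head(df[df$appearance_count > 0, , drop = FALSE], top)
  if (!nrow(df)) {
    graphics::plot.new()
    graphics::title(main = "No features selected in any iteration")
    return(invisible(x))
  }
  method <- if (x$alpha == 1) "LASSO" else
    sprintf("Elastic Net (alpha = %g)", x$alpha)
  op <- graphics::par(mar = c(8, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(df$appearance_count, names.arg = df$feature, las = 2,
                    ylab = sprintf("Appearances in %d iterations",
                                   x$n_iterations),
                    main = sprintf("Selection frequency — %s", method),
                    col = ifelse(df$in_stable_set, "steelblue", "grey70"),
                    ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
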