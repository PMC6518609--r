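#' Stratified random train/test split
#'
#' Partitions samples so that both partitions retain the class proportions of
#' the outcome: each class contributes `round(train_fraction * class size)`
#' samples to the training set, adjusted only so that both partitions contain
#' both classes. No artificial rebalancing (boosting, undersampling) is
#' applied. Randomness comes from the current RNG state; seed before calling
#' for reproducibility.
#'
#' @param y factor of class labels.
#' @param train_fraction proportion of each class assigned to training.
#' @return list with integer index vectors `train` and `test`.
#' @examples
#' set.seed(1)
#' y <- factor(rep(c("A", "B"), c(60, 40)))
#' sp <- stratified_split(y, 0.75)
#' table(y[sp$train])  # 45 A, 30 B
#' @export
stratified_split <- function(y, train_fraction = 0.75) {
  stopifnot(is.factor(y), train_fraction > 0, train_fraction < 1)
  sizes <- table(y)
  if (any(sizes < 2L))
    stop("every class needs at least 2 samples to split; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both partitions nonempty
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# recode a two-level factor as 0/1 with the second level positive
as_binary <- function(y) {
  stopifnot(is.factor(y), nlevels(y) == 2L)
  as.numeric(y == levels(y)[2L])
}

#' Smallest penalty at which every coefficient is zero
#'
#' For the penalized binomial deviance with mixing parameter `alpha`, the
#' entire coefficient vector is exactly zero whenever
#' `lambda >= max_j |<x_j, y - mean(y)>| / (n * alpha)`.
#'
#' @param x numeric training matrix (samples x features).
#' @param y two-level factor or 0/1 vector.
#' @param alpha elastic-net mixing parameter (values below 0.001 are floored
#'   when computing the bound, as is conventional for ridge-leaning mixes).
#' @return the penalty bound, a single number.
#' @export
lambda_max <- function(x, y, alpha = 1) {
  y01 <- if (is.factor(y)) as_binary(y) else as.numeric(y)
  max(abs(crossprod(x, y01 - mean(y01)))) / (nrow(x) * max(alpha, 1e-3))
}

#' Automatic penalty grid
#'
#' 100 log-spaced values from the data-derived [lambda_max()] down to
#' `min_ratio` times it, in decreasing order.
#'
#' @inheritParams lambda_max
#' @param nlambda grid length.
#' @param min_ratio ratio of the smallest to the largest grid value.
#' @return decreasing numeric vector.
#' @export
auto_lambda_grid <- function(x, y, alpha = 1, nlambda = 100,
                             min_ratio = 1e-4) {
  lmax <- lambda_max(x, y, alpha)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

# shared path fit: penalized logistic regression over a decreasing lambda
# sequence; features are expected pre-standardized, so glmnet's internal
# standardization is disabled and coefficients come back on the input scale
fit_path <- function(x, y, alpha, lambda_seq, ...) {
  y01 <- if (is.factor(y)) as_binary(y) else as.numeric(y)
  glmnet::glmnet(x, y01, family = "binomial", alpha = alpha,
                 lambda = lambda_seq, standardize = FALSE, ...)
}

#' Fit a penalized logistic model at a single penalty value
#'
#' Minimizes the penalized binomial deviance
#' \deqn{-\tfrac1n \ell(\beta_0, \beta) +
#'   \lambda\big[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\big]}
#' with an unpenalized intercept. `alpha = 1` gives the LASSO, intermediate
#' values the Elastic Net. Features are assumed standardized (see
#' [autoscale()]); coefficients are reported on the input scale.
#'
#' @param x numeric training matrix.
#' @param y two-level factor (second level positive) or 0/1 vector.
#' @param alpha mixing parameter in `[0, 1]`.
#' @param lambda penalty value, `>= 0`. `lambda = 0` yields the unpenalized
#'   maximum-likelihood fit.
#' @param thresh convergence threshold of the coordinate-descent solver.
#' @return object of class `"penalized_fit"`: list with `intercept`,
#'   `coefficients` (named numeric, length = feature count), `alpha`,
#'   `lambda`, `train_ids`.
#' @export
fit_regularized <- function(x, y, alpha = 1, lambda, thresh = 1e-10) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (anyNA(x)) stop("matrix contains missing values")
  y01 <- if (is.factor(y)) as_binary(y) else as.numeric(y)
  # at lambda >= lambda_max the all-zero coefficient vector solves the
  # KKT conditions exactly, with the intercept at the empirical log-odds
  if (alpha > 0 && lambda > 0) {
    bound <- max(abs(crossprod(x, y01 - mean(y01)))) / (nrow(x) * alpha)
    if (lambda >= bound) {
      beta <- stats::setNames(numeric(ncol(x)), colnames(x))
      return(structure(list(intercept = stats::qlogis(mean(y01)),
                            coefficients = beta, alpha = alpha,
                            lambda = lambda, train_ids = rownames(x)),
                       class = "penalized_fit"))
    }
  }
  # glmnet needs a decreasing path for a stable solution at the target
  lmax <- lambda_max(x, y, alpha)
  upper <- exp(seq(log(max(lmax, lambda, 1e-3)),
                   log(max(lmax, 1e-3) * 1e-4), length.out = 30))
  path <- sort(unique(c(upper[upper > lambda], lambda)), decreasing = TRUE)
  fit <- fit_path(x, y, alpha, path, thresh = thresh, maxit = 1e6)
  cf <- as.numeric(stats::predict(fit, s = lambda, type = "coefficients",
                                  exact = FALSE))
  beta <- stats::setNames(cf[-1L], colnames(x))
  structure(list(intercept = cf[1L], coefficients = beta,
                 alpha = alpha, lambda = lambda,
                 train_ids = rownames(x)),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "Penalized logistic fit (alpha = %g, lambda = %.4g): %d of %d nonzero\n",
    x$alpha, x$lambda, nz, length(x$coefficients)))
  invisible(x)
}

#' @export
coef.penalized_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
predict.penalized_fit <- function(object, newx,
                                  type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- drop(newx[, names(object$coefficients), drop = FALSE] %*%
                object$coefficients) + object$intercept
  if (type == "response") stats::plogis(eta) else eta
}

# stratified fold assignment: within each class, shuffled indices are dealt
# to folds round-robin so every fold holds both classes whenever possible
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

binomial_deviance <- function(p, y01) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * (y01 * log(p) + (1 - y01) * log(1 - p))
}

#' Choose the penalty by stratified k-fold cross-validation
#'
#' Fits the regularization path on each training fold and scores the
#' held-out fold by binomial deviance at every grid value. Under
#' `rule = "min"` the grid lambda minimizing the mean out-of-fold deviance
#' is returned, exact ties going to the largest lambda (the sparser model);
#' under `rule = "1se"` the largest lambda whose mean deviance lies within
#' one standard error of that minimum is returned, trading a little
#' in-sample fit for a sparser, more stable model. When a class has fewer
#' members than `n_folds`, the fold count is reduced with a warning so
#' every fold can contain both classes.
#'
#' @param x numeric matrix (training set of the outer split).
#' @param y two-level factor.
#' @param alpha mixing parameter.
#' @param n_folds number of folds (default 10).
#' @param lambda_grid decreasing positive numeric vector; `NULL` builds the
#'   automatic grid from this data.
#' @param fold_ids optional integer vector of fold assignments (1..k per
#'   sample), overriding the random stratified assignment; every fold must
#'   contain both classes.
#' @param rule `"min"` or `"1se"` (see above).
#' @return list with `lambda` (the chosen value), `lambda_min`,
#'   `lambda_1se`, `lambda_grid`, `mean_deviance` and `se_deviance` (per
#'   grid value, across folds), `n_folds` actually used, and `fold_ids`.
#' @export
cv_optimize_penalty <- function(x, y, alpha = 1, n_folds = 10,
                                lambda_grid = NULL, fold_ids = NULL,
                                rule = c("min", "1se")) {
  rule <- match.arg(rule)
  stopifnot(is.factor(y), nlevels(y) == 2L)
  if (is.null(lambda_grid)) lambda_grid <- auto_lambda_grid(x, y, alpha)
  if (!length(lambda_grid)) stop("empty lambda grid")
  if (length(lambda_grid) == 1L)
    return(list(lambda = lambda_grid, lambda_min = lambda_grid,
                lambda_1se = lambda_grid, lambda_grid = lambda_grid,
                mean_deviance = NA_real_, se_deviance = NA_real_,
                n_folds = 0L))

  y01 <- as_binary(y)
  if (is.null(fold_ids)) {
    min_class <- min(table(y))
    if (min_class < n_folds) {
      warning("reducing fold count from ", n_folds, " to ", min_class,
              " so each fold keeps both classes")
      n_folds <- min_class
    }
    folds <- stratified_folds(y, n_folds)
  } else {
    stopifnot(length(fold_ids) == length(y))
    folds <- as.integer(fold_ids)
    n_folds <- max(folds)
  }
  dev_fold <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (k in seq_len(n_folds)) {
    hold <- folds == k
    fit <- fit_path(x[!hold, , drop = FALSE], y[!hold], alpha, lambda_grid)
    # predict at the full grid: glmnet may truncate a path it could not
    # finish, and s-interpolation restores the missing tail
    p <- stats::predict(fit, x[hold, , drop = FALSE], s = lambda_grid,
                        type = "response")
    dev_fold[k, ] <- colMeans(binomial_deviance(p, y01[hold]))
  }
  cvm <- colMeans(dev_fold)
  cvsd <- apply(dev_fold, 2L, stats::sd) / sqrt(n_folds)
  # grid is decreasing, so the first minimum is the largest (sparsest) lambda
  i_min <- which.min(cvm)
  i_1se <- which(cvm <= cvm[i_min] + cvsd[i_min])[1L]
  list(lambda = lambda_grid[if (rule == "min") i_min else i_1se],
       lambda_min = lambda_grid[i_min], lambda_1se = lambda_grid[i_1se],
       lambda_grid = lambda_grid, mean_deviance = cvm, se_deviance = cvsd,
       n_folds = n_folds, fold_ids = folds)
}
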