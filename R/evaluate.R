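#' Rank-based ROC AUC
#'
#' The area under the ROC curve computed by the Mann–Whitney identity: the
#' probability that a randomly chosen positive sample is scored above a
#' randomly chosen negative one, with tied scores counted one half.
#'
#' @param scores numeric prediction scores, higher = more positive.
#' @param y two-level factor (second level positive) or logical/0-1 vector.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' roc_auc(rep(0.5, 4), c(1, 1, 0, 0))            # 0.5
#' @export
roc_auc <- function(scores, y) {
  pos <- if (is.factor(y)) y == levels(y)[2L] else as.logical(y > 0)
  stopifnot(length(scores) == length(pos))
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)` and accuracy `(TP+TN)/n`. When no positive predictions are
#' made, precision is undefined and reported as `NA` (not 0).
#'
#' @param predicted predicted classes, logical or 0/1.
#' @param actual true classes, logical or 0/1, same length.
#' @return named numeric vector `sensitivity`, `specificity`, `precision`,
#'   `accuracy`.
#' @export
confusion_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual differ in length")
  if (!length(actual)) stop("empty input")
  p <- as.logical(predicted); a <- as.logical(actual)
  tp <- sum(p & a); fn <- sum(!p & a)
  tn <- sum(!p & !a); fp <- sum(p & !a)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    accuracy = (tp + tn) / length(a))
}

# unpenalized logistic fit with a bounded iteration count; perfect
# separation merely saturates the coefficients and never aborts
logistic_scores <- function(xtr, ytr01, xte) {
  qr_x <- cbind(`(Intercept)` = 1, xtr)
  fit <- suppressWarnings(
    stats::glm.fit(qr_x, ytr01, family = stats::binomial(),
                   control = list(maxit = 50))
  )
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  drop(cbind(1, xte) %*% beta)
}

# a shared schedule of stratified splits so that competing panels are scored
# on identical resamples
make_resample_schedule <- function(y, n_resamples, train_fraction, seed) {
  seeds <- spawn_seeds(seed, n_resamples)
  lapply(seq_len(n_resamples), function(r) {
    set.seed(seeds[r])
    stratified_split(y, train_fraction)
  })
}

# score one feature subset over a fixed schedule; returns per-resample AUC
# and confusion metrics
score_panel <- function(x, y, subset, schedule) {
  y01 <- as_binary(y)
  auc <- numeric(length(schedule))
  cm <- matrix(NA_real_, length(schedule), 4,
               dimnames = list(NULL, c("sensitivity", "specificity",
                                       "precision", "accuracy")))
  xs <- x[, subset, drop = FALSE]
  for (r in seq_along(schedule)) {
    sp <- schedule[[r]]
    eta <- logistic_scores(xs[sp$train, , drop = FALSE], y01[sp$train],
                           xs[sp$test, , drop = FALSE])
    yte <- y01[sp$test]
    auc[r] <- roc_auc(eta, yte)
    cm[r, ] <- confusion_metrics(stats::plogis(eta) > 0.5, yte)
  }
  list(auc = auc, cm = cm)
}

#' Evaluate one candidate panel by resampled test-set AUC
#'
#' Over `n_resamples` stratified 75/25 train/test splits, fits an
#' unpenalized logistic model on the panel's features and scores the test
#' set; returns the mean and SD of the test AUC together with mean
#' sensitivity, specificity, precision and accuracy at a 0.5
#' predicted-probability threshold.
#'
#' @param x numeric matrix (samples x features).
#' @param y two-level factor (second level positive).
#' @param panel character vector of feature ids (must be columns of `x`).
#' @param n_resamples number of random splits.
#' @param train_fraction training proportion of each split.
#' @param seed master seed for the resample schedule.
#' @param schedule optional precomputed schedule (overrides
#'   `n_resamples`/`seed`), used to share splits across panels.
#' @return one-row data.frame: `panel`, `size`, `mean_auc`, `sd_auc`,
#'   `sensitivity`, `specificity`, `precision`, `accuracy`.
#' @export
evaluate_panel <- function(x, y, panel, n_resamples = 1000,
                           train_fraction = 0.75, seed = 1,
                           schedule = NULL) {
  missing_f <- setdiff(panel, colnames(x))
  if (length(missing_f))
    stop("panel feature(s) not in matrix: ",
         paste(missing_f, collapse = ", "))
  if (!length(panel)) stop("empty panel")
  if (is.null(schedule))
    schedule <- make_resample_schedule(y, n_resamples, train_fraction, seed)
  sc <- score_panel(x, y, panel, schedule)
  data.frame(panel = paste(sort(panel), collapse = "+"),
             size = length(panel),
             mean_auc = mean(sc$auc), sd_auc = stats::sd(sc$auc),
             sensitivity = mean(sc$cm[, "sensitivity"]),
             specificity = mean(sc$cm[, "specificity"]),
             precision = mean(sc$cm[, "precision"], na.rm = TRUE),
             accuracy = mean(sc$cm[, "accuracy"]),
             stringsAsFactors = FALSE)
}

#' Exhaustive combinatorial panel search over the stable set
#'
#' Enumerates every subset of the stable feature set up to `max_panel_size`
#' and evaluates each with [evaluate_panel()] on one shared resample
#' schedule, so AUC differences between panels cannot be attributed to
#' split randomness. Panels are ranked by decreasing mean test AUC; ties go
#' to the smaller panel, then lexicographic order.
#'
#' @param x numeric matrix.
#' @param y two-level factor.
#' @param stable_set character vector of candidate features.
#' @param max_panel_size largest subset size; `NULL` enumerates all sizes
#'   when the stable set has at most 10 features, otherwise sizes up to 3.
#' @param n_resamples splits per panel.
#' @param train_fraction training proportion.
#' @param seed master seed for the shared schedule.
#' @return object of class `"panel_ranking"`: the ranked results
#'   data.frame with attributes; zero rows (and a message on print) when
#'   `stable_set` is empty.
#' @export
combinatorial_search <- function(x, y, stable_set, max_panel_size = NULL,
                                 n_resamples = 1000, train_fraction = 0.75,
                                 seed = 1) {
  empty <- data.frame(panel = character(0), size = integer(0),
                      mean_auc = numeric(0), sd_auc = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      precision = numeric(0), accuracy = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(stable_set))
    return(structure(empty, class = c("panel_ranking", "data.frame")))
  if (is.null(max_panel_size))
    max_panel_size <- if (length(stable_set) <= 10) length(stable_set) else 3
  max_panel_size <- min(max_panel_size, length(stable_set))

  schedule <- make_resample_schedule(y, n_resamples, train_fraction, seed)
  stable_set <- sort(stable_set)
  subsets <- unlist(lapply(seq_len(max_panel_size), function(k)
    utils::combn(stable_set, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(s)
    evaluate_panel(x, y, s, schedule = schedule))
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_auc, out$size, out$panel), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("panel_ranking", "data.frame"))
}

#' @export
print.panel_ranking <- function(x, ...) {
  if (!nrow(x)) {
    cat("No stable features: no panels to rank.\n")
    return(invisible(x))
  }
  cat(sprintf("Combinatorial panel ranking (%d panels):\n", nrow(x)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ... and", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Permutation-null stability analysis of a fixed panel
#'
#' Builds the empirical performance assessment of a pre-selected panel: the
#' "real" arm repeats stratified 75/25 splitting, unpenalized logistic
#' fitting on the panel, and test-set AUC scoring over `n_resamples`
#' resamples; the "permuted" arm does exactly the same except the outcome
#' labels are re-shuffled uniformly at random before every resample (the
#' permutation precedes the split, so class proportions are preserved while
#' any feature–label association is destroyed). A genuinely informative
#' panel separates the two AUC distributions; the permuted arm concentrates
#' around 0.5. The panel is fixed in advance — selection is not repeated
#' inside the permutation arm.
#'
#' @param x numeric matrix.
#' @param y two-level factor (second level positive).
#' @param panel character vector of feature ids.
#' @param n_resamples resamples per arm (default 1000).
#' @param train_fraction training proportion of each split.
#' @param seed master seed; each resample has its own derived stream.
#' @return object of class `"evaluation_result"`: list with `real_aucs`,
#'   `permuted_aucs` (length `n_resamples` each), `real_metrics`
#'   (per-resample confusion metrics of the real arm), `panel`, and a
#'   `summary` data.frame of means and SDs.
#' @export
permutation_stability <- function(x, y, panel, n_resamples = 1000,
                                  train_fraction = 0.75, seed = 1) {
  missing_f <- setdiff(panel, colnames(x))
  if (length(missing_f))
    stop("panel feature(s) not in matrix: ",
         paste(missing_f, collapse = ", "))
  stopifnot(is.factor(y), nlevels(y) == 2L, nrow(x) == length(y))
  y01 <- as_binary(y)
  xs <- x[, panel, drop = FALSE]
  seeds <- spawn_seeds(seed, n_resamples)

  real <- numeric(n_resamples)
  perm <- numeric(n_resamples)
  cm <- matrix(NA_real_, n_resamples, 4,
               dimnames = list(NULL, c("sensitivity", "specificity",
                                       "precision", "accuracy")))
  for (r in seq_len(n_resamples)) {
    set.seed(seeds[r])
    sp <- stratified_split(y, train_fraction)
    eta <- logistic_scores(xs[sp$train, , drop = FALSE], y01[sp$train],
                           xs[sp$test, , drop = FALSE])
    real[r] <- roc_auc(eta, y01[sp$test])
    cm[r, ] <- confusion_metrics(stats::plogis(eta) > 0.5, y01[sp$test])

    yp <- sample(y)                  # fresh label permutation per resample
    yp01 <- as_binary(yp)
    spp <- stratified_split(yp, train_fraction)
    eta_p <- logistic_scores(xs[spp$train, , drop = FALSE], yp01[spp$train],
                             xs[spp$test, , drop = FALSE])
    perm[r] <- roc_auc(eta_p, yp01[spp$test])
  }
  summary_df <- data.frame(
    arm = c("real", "permuted"),
    mean_auc = c(mean(real), mean(perm)),
    sd_auc = c(stats::sd(real), stats::sd(perm)),
    stringsAsFactors = FALSE)
  structure(list(real_aucs = real, permuted_aucs = perm, real_metrics = cm,
                 panel = panel, n_resamples = n_resamples,
                 summary = summary_df),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Permutation-null stability analysis\n")
  cat("  panel:", paste(x$panel, collapse = " + "), "\n")
  cat(sprintf("  real arm:     mean AUC %.3f (SD %.3f) over %d resamples\n",
              x$summary$mean_auc[1], x$summary$sd_auc[1], x$n_resamples))
  cat(sprintf("  permuted arm: mean AUC %.3f (SD %.3f)\n",
              x$summary$mean_auc[2], x$summary$sd_auc[2]))
  cm <- colMeans(x$real_metrics, na.rm = TRUE)
  cat(sprintf(paste0("  real-arm means: sensitivity %.3f, specificity %.3f,",
                     " precision %.3f, accuracy %.3f\n"),
              cm["sensitivity"], cm["specificity"], cm["precision"],
              cm["accuracy"]))
  invisible(x)
}

#' Density plot of real versus permuted AUC distributions
#'
#' The standard display of the permutation analysis: both AUC densities with
#' dashed vertical lines at their means.
#'
#' @param x an `"evaluation_result"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.evaluation_result <- function(x, ...) {
  d_real <- stats::density(x$real_aucs, from = 0, to = 1)
  d_perm <- stats::density(x$permuted_aucs, from = 0, to = 1)
  ylim <- c(0, max(d_real$y, d_perm$y))
  graphics::plot(d_real, col = "steelblue", lwd = 2, ylim = ylim,
                 xlab = "ROC AUC", main = "Real vs permuted-label AUC", ...)
  graphics::lines(d_perm, col = "goldenrod", lwd = 2)
  graphics::abline(v = mean(x$real_aucs), col = "steelblue", lty = 2)
  graphics::abline(v = mean(x$permuted_aucs), col = "goldenrod", lty = 2)
  graphics::legend("topleft", legend = c("real", "permuted"),
                   col = c("steelblue", "goldenrod"), lwd = 2, bty = "n")
  invisible(x)
}
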