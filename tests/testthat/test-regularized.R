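test_that("stratified splits hit the exact per-class counts", {
  y <- factor(rep(c("A", "B"), c(60, 40)))
  set.seed(1)
  sp <- stratified_split(y, 0.75)
  expect_identical(as.integer(table(y[sp$train])), c(45L, 30L))
  expect_identical(length(sp$train), 75L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)

  y2 <- factor(rep(c("A", "B"), each = 2))
  sp2 <- stratified_split(y2, 0.5)
  expect_identical(as.integer(table(y2[sp2$train])), c(1L, 1L))
  expect_identical(as.integer(table(y2[sp2$test])), c(1L, 1L))

  y_bad <- factor(rep(c("A", "B"), c(1, 10)))
  expect_error(stratified_split(y_bad, 0.75), "at least 2 samples")
})

test_that("class proportions are preserved exactly over repeated draws", {
  y <- factor(rep(c("A", "B"), c(60, 40)))
  set.seed(99)
  props <- replicate(1000, {
    sp <- stratified_split(y, 0.75)
    mean(y[sp$train] == "A")
  })
  expect_true(all(props == 0.6))
})

test_that("all coefficients vanish at and above lambda_max", {
  for (seed in 1:3) {
    toy <- toy_classification(n = 50, p = 8, effect = 1.5, seed = seed)
    lmax <- lambda_max(toy$x, toy$y, alpha = 1)
    fit <- fit_regularized(toy$x, toy$y, alpha = 1, lambda = lmax)
    expect_identical(sum(fit$coefficients != 0), 0L)
    fit2 <- fit_regularized(toy$x, toy$y, alpha = 1, lambda = 2 * lmax)
    expect_identical(sum(fit2$coefficients != 0), 0L)
  }
})

test_that("the unpenalized limit matches a maximum-likelihood oracle", {
  toy <- toy_classification(n = 300, p = 4, effect = 0.8, seed = 11)
  fit <- fit_regularized(toy$x, toy$y, alpha = 1, lambda = 0)
  oracle <- glm(as_binary_test(toy$y) ~ toy$x, family = binomial())
  expect_lt(max(abs(coef(fit) - coef(oracle))), 1e-4)
})

test_that("identical feature columns share the elastic-net coefficient", {
  toy <- toy_classification(n = 80, p = 3, effect = 1.2, seed = 5)
  x <- cbind(toy$x, dup = toy$x[, 1])
  colnames(x) <- c(colnames(toy$x), "dup")
  lam <- 0.05
  fit <- fit_regularized(x, toy$y, alpha = 0.5, lambda = lam, thresh = 1e-12)
  # equal up to the coordinate-descent convergence tolerance
  expect_lt(abs(fit$coefficients["v1"] - fit$coefficients["dup"]), 1e-4)
})

test_that("penalized fits refuse invalid inputs", {
  toy <- toy_classification()
  expect_error(fit_regularized(toy$x, toy$y, lambda = -1), "nonnegative")
  xna <- toy$x; xna[1, 1] <- NA
  expect_error(fit_regularized(xna, toy$y, lambda = 0.1), "missing values")
})

test_that("a single-element grid is returned untouched", {
  toy <- toy_classification()
  res <- cv_optimize_penalty(toy$x, toy$y, lambda_grid = 0.3)
  expect_identical(res$lambda, 0.3)
})

test_that("cross-validated lambda matches a brute-force fold-wise oracle", {
  toy <- toy_classification(n = 30, p = 10, effect = 1.5, seed = 21)
  grid <- auto_lambda_grid(toy$x, toy$y, alpha = 1, nlambda = 25)
  # deterministic stratified folds: both classes present in each fold
  fold_ids <- ave(seq_along(toy$y), toy$y,
                  FUN = function(i) rep_len(1:5, length(i)))
  res <- cv_optimize_penalty(toy$x, toy$y, alpha = 1, lambda_grid = grid,
                             fold_ids = fold_ids)
  # oracle: per lambda, refit each fold separately and pool deviance
  dev <- sapply(grid, function(lam) {
    total <- 0
    for (k in 1:5) {
      hold <- fold_ids == k
      fit <- fit_regularized(toy$x[!hold, ], toy$y[!hold], alpha = 1,
                             lambda = lam)
      p <- predict(fit, toy$x[hold, , drop = FALSE], type = "response")
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      yh <- as_binary_test(toy$y)[hold]
      total <- total + sum(-2 * (yh * log(p) + (1 - yh) * log(1 - p)))
    }
    total / 30
  })
  expect_identical(res$lambda, grid[which.min(dev)])
})

test_that("pure-noise data drives the chosen penalty into the upper grid", {
  set.seed(1)
  upper <- replicate(50, {
    y <- factor(rep(c("a", "b"), each = 30), levels = c("a", "b"))
    x <- matrix(rnorm(60 * 30), 60, 30,
                dimnames = list(NULL, paste0("f", 1:30)))
    x <- scale(x)
    res <- suppressWarnings(cv_optimize_penalty(x, y, alpha = 1, n_folds = 5))
    which(res$lambda_grid == res$lambda) <= length(res$lambda_grid) / 2
  })
  expect_gte(mean(upper), 0.8)
})

test_that("sparsity grows monotonically along the penalty path", {
  toy <- toy_classification(n = 100, p = 20, effect = 1.5, seed = 31)
  grid <- auto_lambda_grid(toy$x, toy$y, alpha = 1)
  fit_hi <- fit_regularized(toy$x, toy$y, alpha = 1, lambda = grid[1])
  fit_lo <- fit_regularized(toy$x, toy$y, alpha = 1, lambda = min(grid))
  expect_identical(sum(fit_hi$coefficients != 0), 0L)
  expect_gte(sum(fit_lo$coefficients != 0),
             sum(fit_hi$coefficients != 0))
})

test_that("a fixed master seed makes the whole profile bit-reproducible", {
  sim <- simulate_omics(n_samples = 60, n_features = 10, n_informative = 2,
                        effect_size = 2, seed = 4)
  x <- autoscale(sim$x)
  cfg <- pipeline_config(alpha = 1, n_iterations = 6,
                         appearance_threshold = 5, n_folds = 5, seed = 17)
  p1 <- stability_select(x, sim$y, cfg)
  p2 <- stability_select(x, sim$y, cfg)
  expect_identical(p1$coef_matrix, p2$coef_matrix)
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$lambdas, p2$lambdas)
})

test_that("appearance counts do not depend on feature column order", {
  sim <- simulate_omics(n_samples = 80, n_features = 8, n_informative = 2,
                        effect_size = 2.5, seed = 6)
  x <- autoscale(sim$x)
  cfg <- pipeline_config(alpha = 1, n_iterations = 8,
                         appearance_threshold = 7, n_folds = 5, seed = 2)
  p1 <- stability_select(x, sim$y, cfg)
  perm <- rev(seq_len(ncol(x)))
  p2 <- stability_select(x[, perm], sim$y, cfg)
  expect_identical(p1$counts[colnames(x)[perm]], p2$counts)
  expect_setequal(p1$stable_set, p2$stable_set)
})

test_that("the stable set applies the threshold strictly", {
  sim <- simulate_omics(n_samples = 80, n_features = 6, n_informative = 2,
                        effect_size = 3, seed = 8)
  x <- autoscale(sim$x)
  cfg <- pipeline_config(alpha = 1, n_iterations = 5,
                         appearance_threshold = 5, n_folds = 5, seed = 3)
  prof <- stability_select(x, sim$y, cfg)
  # threshold equals n_iterations: only counts strictly above (impossible
  # value) would qualify, so nothing at exactly 5 of 5 may enter
  expect_length(prof$stable_set, 0)
  cfg2 <- pipeline_config(alpha = 1, n_iterations = 5,
                          appearance_threshold = 4, n_folds = 5, seed = 3)
  prof2 <- stability_select(x, sim$y, cfg2)
  expect_setequal(prof2$stable_set,
                  names(prof2$counts)[prof2$counts > 4])
  expect_true(all(sim$truth %in% prof2$stable_set))
  # config invariant behind the rule
  expect_error(pipeline_config(appearance_threshold = 101,
                               n_iterations = 100),
               "exceeds n_iterations")
})
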