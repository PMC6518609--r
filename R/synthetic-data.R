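#' Simulate an omics-like feature matrix with planted informative features
#'
#' Generates a samples-by-features numeric matrix with a binary outcome and a
#' known set of informative features, for benchmarking feature-selection
#' pipelines without external data. Noise features are iid standard normal
#' (optionally equicorrelated within consecutive blocks); informative features
#' add a fixed mean shift, in standard-deviation units, to the positive class.
#' Under this model a single informative feature has population ROC AUC
#' \eqn{\Phi(\delta/\sqrt{2})} where \eqn{\delta} is `effect_size`.
#'
#' @param n_samples number of samples (rows).
#' @param n_features total number of features (columns).
#' @param n_informative number of features carrying the class mean shift;
#'   these are the first `n_informative` columns and are named in `truth`.
#' @param effect_size between-class mean shift of each informative feature,
#'   in units of the within-class standard deviation (which is 1).
#' @param class_balance proportion of samples in the positive class
#'   (`"case"`); the positive count is `round(class_balance * n_samples)`.
#' @param rho within-block equicorrelation of noise features; 0 disables
#'   correlated blocks.
#' @param block_size number of consecutive noise features per correlated
#'   block when `rho > 0`.
#' @param missing_rate proportion of cells masked to `NA`, uniformly at
#'   random.
#' @param seed optional integer seed; when given the output is reproducible.
#'
#' @return A list with elements `x` (numeric matrix, rownames = sample ids,
#'   colnames = feature ids), `y` (factor with levels `c("control", "case")`,
#'   `"case"` positive), and `truth` (character vector of informative feature
#'   ids).
#' @examples
#' sim <- simulate_omics(n_samples = 40, n_features = 10, n_informative = 2,
#'                       effect_size = 2, seed = 1)
#' dim(sim$x)
#' sim$truth
#' @export
simulate_omics <- function(n_samples = 200, n_features = 103,
                           n_informative = 3, effect_size = 2,
                           class_balance = 0.5, rho = 0, block_size = 0,
                           missing_rate = 0, seed = NULL) {
  stopifnot(n_informative <= n_features, n_samples >= 4,
            class_balance > 0, class_balance < 1,
            rho >= 0, rho < 1, missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)

  n_pos <- round(class_balance * n_samples)
  n_pos <- min(max(n_pos, 2L), n_samples - 2L)
  y <- rep(c("control", "case"), c(n_samples - n_pos, n_pos))
  y <- factor(sample(y), levels = c("control", "case"))

  x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  if (rho > 0 && block_size > 1) {
    noise_cols <- seq_len(n_features)[-seq_len(n_informative)]
    blocks <- split(noise_cols,
                    ceiling(seq_along(noise_cols) / block_size))
    for (b in blocks) {
      z <- stats::rnorm(n_samples)
      x[, b] <- sqrt(rho) * z + sqrt(1 - rho) * x[, b]
    }
  }
  if (n_informative > 0) {
    shift <- effect_size * (y == "case")
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + shift
  }
  if (missing_rate > 0) {
    mask <- stats::runif(length(x)) < missing_rate
    x[mask] <- NA_real_
  }

  feature_ids <- sprintf("f%03d", seq_len(n_features))
  dimnames(x) <- list(sprintf("s%04d", seq_len(n_samples)), feature_ids)
  names(y) <- rownames(x)
  list(x = x, y = y,
       truth = feature_ids[seq_len(min(n_informative, n_features))])
}

#' Build a small fixture with duplicate probes and degenerate columns
#'
#' Emits a 100-sample expression-like matrix that deliberately contains
#' duplicated probe ids (replicate measurements of the same probe),
#' multi-probe genes, one constant column and one near-zero-variance column,
#' together with a probe-to-gene map covering every probe and the gene list
#' expected to survive the full preprocessing chain (duplicate-probe merge,
#' probe-to-gene collapse, near-zero-variance filter).
#'
#' @param seed integer seed for the random expression values.
#' @return list with `x` (matrix whose colnames contain duplicates),
#'   `probe_map` (data.frame probe_id, gene_id), and
#'   `expected_survivors` (character vector of gene ids that the default
#'   preprocessing chain retains).
#' @export
duplicate_probe_fixture <- function(seed = 1) {
  set.seed(seed)
  n <- 100
  rn <- function() stats::rnorm(n)
  # pDUP measured twice; gene gMULTI has two probes (pHI has the larger
  # mean); gCONST is constant; gNZV is 97/2/1 almost-constant.
  cols <- list(
    pDUP  = rn() + 1,
    pDUP2 = rn() - 1,          # renamed to pDUP below (replicate)
    pA    = rn(),
    pLO   = rn(),              # gene gMULTI, mean 0
    pHI   = rn() + 5,          # gene gMULTI, mean 5 -> retained
    pCONST = rep(2, n),
    pNZV  = c(rep(0, 97), 1, 1, 2)
  )
  x <- do.call(cbind, cols)
  colnames(x) <- c("pDUP", "pDUP", "pA", "pLO", "pHI", "pCONST", "pNZV")
  rownames(x) <- sprintf("s%03d", seq_len(n))
  probe_map <- data.frame(
    probe_id = c("pDUP", "pA", "pLO", "pHI", "pCONST", "pNZV"),
    gene_id  = c("gDUP", "gA", "gMULTI", "gMULTI", "gCONST", "gNZV"),
    stringsAsFactors = FALSE
  )
  list(x = x, probe_map = probe_map,
       expected_survivors = c("gDUP", "gA", "gMULTI"))
}

#' Write a simulated dataset to disk
#'
#' Convenience wrapper used by the command-line `simulate` subcommand: writes
#' the matrix plus outcome column as CSV (first column `sample_id`, outcome
#' column `class`) and the planted informative feature ids as JSON.
#'
#' @param sim result of [simulate_omics()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_simulated <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(sample_id = rownames(sim$x), class = as.character(sim$y),
                   sim$x, check.names = FALSE, stringsAsFactors = FALSE)
  matrix_path <- file.path(dir, "matrix.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(df, matrix_path, row.names = FALSE)
  jsonlite::write_json(sim$truth, truth_path)
  invisible(c(matrix = matrix_path, truth = truth_path))
}
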