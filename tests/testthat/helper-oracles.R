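# independent oracles used across test files

# ROC AUC by exhaustive positive-negative pair enumeration, ties counted 1/2
brute_auc <- function(scores, pos) {
  pos <- as.logical(pos)
  s1 <- scores[pos]; s0 <- scores[!pos]
  wins <- 0
  for (a in s1) for (b in s0)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(s1) * length(s0))
}

# write a samples x features table with an outcome column to a temp file
write_omics_fixture <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# 0/1 coding with the factor's second level positive (test-side copy)
as_binary_test <- function(y) as.numeric(y == levels(y)[2L])

# small, well-behaved classification matrix for fit-level tests
toy_classification <- function(n = 60, p = 5, effect = 1, seed = 42) {
  set.seed(seed)
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("v", 1:p)))
  x[, 1] <- x[, 1] + effect * (y == "case")
  list(x = scale(x), y = y)
}
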