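test_that("read_omics parses a CSV into an aligned matrix and labels", {
  df <- data.frame(sample_id = paste0("s", 1:4),
                   class = c("a", "b", "a", "b"),
                   g1 = 1:4, g2 = c(0.5, 0.25, 0.125, 1), g3 = 5:8)
  loaded <- read_omics(write_omics_fixture(df), "class")
  expect_identical(dim(loaded$x), c(4L, 3L))
  expect_identical(colnames(loaded$x), c("g1", "g2", "g3"))
  expect_identical(as.character(loaded$y), c("a", "b", "a", "b"))
  expect_identical(rownames(loaded$x), names(loaded$y))
})

test_that("read_omics rejects degenerate inputs with named errors", {
  one_class <- data.frame(sample_id = paste0("s", 1:3),
                          class = "a", g1 = 1:3)
  expect_error(read_omics(write_omics_fixture(one_class), "class"),
               "single-class outcome")
  df <- data.frame(sample_id = c("s1", "s1", "s2"),
                   class = c("a", "b", "a"), g1 = 1:3)
  expect_error(read_omics(write_omics_fixture(df), "class"),
               "duplicate sample ids")
  df2 <- data.frame(sample_id = paste0("s", 1:3), class = c("a", "b", "a"),
                    g1 = 1:3)
  expect_error(read_omics(write_omics_fixture(df2), "phenotype"),
               "missing outcome column")
  df3 <- data.frame(sample_id = paste0("s", 1:4),
                    class = c("a", "b", "a", "b"),
                    g1 = c("x", "y", "z", "w"), g2 = 1:4)
  expect_error(read_omics(write_omics_fixture(df3), "class"),
               "non-numeric feature columns: g1")
})

test_that("read_omics keeps missing cells and reads TSV", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tclass\tg1\tg2",
               "s1\ta\t1\t4", "s2\tb\t\t5", "s3\ta\tNaN\t6", "s4\tb\t2\t7"),
             path)
  loaded <- read_omics(path, "class", sep = "\t")
  expect_true(is.na(loaded$x["s2", "g1"]))
  expect_true(is.na(loaded$x["s3", "g1"]))
  expect_equal(loaded$x[, "g2"], c(s1 = 4, s2 = 5, s3 = 6, s4 = 7))
})

test_that("duplicate probes merge to their per-sample median", {
  x <- cbind(c(1, 3), c(5, 7))
  colnames(x) <- c("P", "P")
  rownames(x) <- c("s1", "s2")
  expect_equal(collapse_duplicate_probes(x),
               matrix(c(3, 5), 2, 1, dimnames = list(c("s1", "s2"), "P")))

  x3 <- cbind(A = c(1, 0), A = c(2, 0), A = c(9, 0))
  colnames(x3) <- rep("A", 3)
  rownames(x3) <- c("s1", "s2")
  expect_equal(collapse_duplicate_probes(x3)[1, "A"], 2)

  no_dup <- matrix(1:4, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_identical(collapse_duplicate_probes(no_dup), no_dup)
})

test_that("gene collapse keeps the maximally expressed probe verbatim", {
  x <- cbind(A = c(1, 1, 1), B = c(4, 6, 5), C = c(0, 0, 1))
  rownames(x) <- paste0("s", 1:3)
  pm <- data.frame(probe_id = c("A", "B", "C"),
                   gene_id = c("G", "G", "H"))
  out <- collapse_probes_to_genes(x, pm)
  expect_equal(out[, "G"], c(s1 = 4, s2 = 6, s3 = 5))  # B wins on mean
  expect_equal(out[, "H"], c(s1 = 0, s2 = 0, s3 = 1))  # single probe intact
})

test_that("equal probe means break ties lexicographically", {
  x <- cbind(zzz = c(1, 3), aaa = c(3, 1))   # both means 2
  rownames(x) <- c("s1", "s2")
  pm <- data.frame(probe_id = c("zzz", "aaa"), gene_id = c("G", "G"))
  out <- collapse_probes_to_genes(x, pm)
  expect_equal(out[, "G"], c(s1 = 3, s2 = 1))  # probe "aaa"
})

test_that("unmapped probes drop with a warning or raise on request", {
  x <- cbind(A = c(1, 2), X = c(3, 4))
  rownames(x) <- c("s1", "s2")
  pm <- data.frame(probe_id = "A", gene_id = "G")
  expect_warning(out <- collapse_probes_to_genes(x, pm), "unmapped")
  expect_identical(colnames(out), "G")
  expect_error(collapse_probes_to_genes(x, pm, on_unmapped = "error"),
               "absent from map")
})

test_that("near-zero-variance filter applies both criteria jointly", {
  set.seed(1)
  x <- cbind(const = rep(1, 100),
             continuous = rnorm(100),
             almost = c(rep(0, 97), 1, 1, 2),
             binary_balanced = rep(c(0, 1), 50))  # ratio 1, kept
  rownames(x) <- paste0("s", 1:100)
  flt <- filter_near_zero_variance(x)
  expect_setequal(flt$removed, c("const", "almost"))
  expect_setequal(colnames(flt$x), c("continuous", "binary_balanced"))
  # 97/2/1 column: ratio 48.5 > 19 and 3% unique < 10%
  expect_true("almost" %in% flt$removed)

  clean <- x[, c("continuous", "binary_balanced")]
  expect_identical(filter_near_zero_variance(clean)$x, clean)
  expect_error(filter_near_zero_variance(x[, "const", drop = FALSE]),
               "no features survive")
})

test_that("near-zero-variance filter agrees with the caret reference", {
  skip_if_not_installed("caret")
  set.seed(42)
  x <- cbind(matrix(rnorm(600), 100, 6),
             c(rep(0, 96), 1, 1, 2, 2),
             rep(3.5, 100),
             c(rep(1, 98), 2, 2),
             sample(1:3, 100, replace = TRUE))
  colnames(x) <- paste0("f", 1:10)
  rownames(x) <- paste0("s", 1:100)
  ours <- filter_near_zero_variance(x)$removed
  ref <- colnames(x)[caret::nearZeroVar(as.data.frame(x))]
  expect_setequal(ours, ref)
})

test_that("median imputation fills gaps and enforces missingness caps", {
  # wide enough that the single gap stays under both missingness caps
  x <- cbind(a = c(1, NA, 3, 5), b = c(2, 2, 2, 4), c = 1:4, d = 4:1,
             e = c(0.5, 1, 1.5, 2))
  rownames(x) <- paste0("s", 1:4)
  out <- impute_missing(x, max_feature_missing = 30)
  expect_equal(out[, "a"], c(s1 = 1, s2 = 3, s3 = 3, s4 = 5))

  clean <- matrix(rnorm(20), 5, 4,
                  dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  out2 <- impute_missing(clean)
  expect_equal(unclass(out2)[, ], clean[, ])

  x10 <- matrix(rnorm(100), 10, 10,
                dimnames = list(paste0("s", 1:10), paste0("f", 1:10)))
  x10[1:3, 1] <- NA  # 30% missing > 20% cap
  out3 <- impute_missing(x10)
  expect_false("f1" %in% colnames(out3))
  expect_identical(attr(out3, "dropped_features"), "f1")
})

test_that("autoscaling standardizes, bypasses, and refuses constants", {
  x <- matrix(c(2, 4, 6), 3, 1, dimnames = list(paste0("s", 1:3), "f"))
  expect_equal(autoscale(x)[, "f"], c(s1 = -1, s2 = 0, s3 = 1))
  expect_identical(autoscale(x, enabled = FALSE), x)

  set.seed(1)
  big <- matrix(rnorm(200), 20, 10)
  dimnames(big) <- list(paste0("s", 1:20), paste0("f", 1:10))
  expect_true(all(abs(colMeans(autoscale(big))) < 1e-10))
  expect_true(all(abs(apply(autoscale(big), 2, sd) - 1) < 1e-10))

  bad <- cbind(big, const = 1)
  expect_error(autoscale(bad), "zero-variance")
})

test_that("collapsing operations are idempotent and preserve samples", {
  fx <- duplicate_probe_fixture(seed = 2)
  m1 <- collapse_duplicate_probes(fx$x)
  expect_identical(collapse_duplicate_probes(m1), m1)
  expect_identical(nrow(m1), nrow(fx$x))

  pm2 <- data.frame(probe_id = fx$probe_map$gene_id,
                    gene_id = fx$probe_map$gene_id)
  g1 <- collapse_probes_to_genes(m1, fx$probe_map)
  expect_identical(collapse_probes_to_genes(g1, unique(pm2)), g1)
  expect_identical(nrow(g1), nrow(fx$x))
  expect_identical(nrow(filter_near_zero_variance(g1)$x), nrow(fx$x))
})

test_that("contrast constructor pools levels and excludes the rest", {
  y <- rep(c("FM", "HM", "Mixed"), c(10, 12, 8))
  ct <- make_contrast(y, positive = "HM", negative = c("FM", "Mixed"))
  expect_identical(levels(ct$y), c("FM+Mixed", "HM"))
  expect_identical(length(ct$idx), 30L)
  expect_identical(as.integer(ct$counts), c(18L, 12L))

  expect_error(make_contrast(y, positive = "HM", negative = "HM"),
               "both classes")
  expect_error(make_contrast(y, positive = "XX", negative = "FM"),
               "absent from labels")
  y1 <- c("a", rep("b", 5))
  expect_error(make_contrast(y1, positive = "a", negative = "b"),
               "at least 2 samples")
})
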