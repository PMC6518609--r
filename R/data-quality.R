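#' Read a delimited feature table with an outcome column
#'
#' Parses a samples-by-features delimited text file into a numeric matrix and
#' an aligned outcome factor. The first column must hold unique sample ids,
#' one named column holds the outcome, and every remaining column must be
#' numeric. Empty cells, `NA`, and `NaN` (case-insensitive) are read as
#' missing values.
#'
#' @param path path to the delimited file.
#' @param outcome_column name of the outcome column.
#' @param sep field separator: `","` (default) or `"\t"`.
#' @param transpose set `TRUE` when the file stores features as rows and
#'   samples as columns; the orientation is never guessed.
#' @return list with `x` (numeric matrix, rownames = sample ids) and `y`
#'   (factor of outcome labels, named by sample id).
#' @export
read_omics <- function(path, outcome_column, sep = ",", transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  na_strings <- c("", "NA", "NaN", "na", "nan", "Na", "NAN", "nA", "NAn")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = na_strings, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (transpose) {
    ids <- df[[1L]]
    df <- as.data.frame(t(df[, -1L, drop = FALSE]),
                        stringsAsFactors = FALSE)
    colnames(df) <- ids
    df <- cbind(sample_id = rownames(df), df, stringsAsFactors = FALSE)
  }
  sample_ids <- as.character(df[[1L]])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!outcome_column %in% colnames(df))
    stop("missing outcome column: ", outcome_column)

  y <- factor(as.character(df[[outcome_column]]))
  if (nlevels(y) < 2L) stop("single-class outcome")

  feat <- df[, setdiff(colnames(df)[-1L], outcome_column), drop = FALSE]
  bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature columns: ", paste(bad, collapse = ", "))
  x <- as.matrix(feat)
  rownames(x) <- sample_ids
  names(y) <- sample_ids
  list(x = x, y = y)
}

#' Merge duplicate probe measurements by their per-sample median
#'
#' Microarray matrices can report the same probe several times; replicates
#' are merged into one column holding, for each sample, the median of the
#' replicate values. Matrices without duplicated feature ids pass through
#' unchanged.
#'
#' @param x numeric matrix, samples in rows; colnames may repeat.
#' @return matrix with one column per unique feature id, sample rows intact.
#' @export
collapse_duplicate_probes <- function(x) {
  ids <- colnames(x)
  if (is.null(ids)) stop("matrix must have feature ids as colnames")
  if (!anyDuplicated(ids)) return(x)
  uid <- unique(ids)
  out <- matrix(NA_real_, nrow(x), length(uid),
                dimnames = list(rownames(x), uid))
  for (id in uid) {
    cols <- x[, ids == id, drop = FALSE]
    out[, id] <- if (ncol(cols) == 1L) cols[, 1L]
                 else apply(cols, 1L, stats::median, na.rm = TRUE)
  }
  out
}

#' Collapse probes to genes, keeping the maximally expressed probe
#'
#' For each gene owning several probes, the probe with the highest mean value
#' across all samples is retained verbatim (no averaging across probes); ties
#' are broken by the lexicographically first probe id. Probes absent from the
#' map are dropped with a warning by default.
#'
#' @param x numeric matrix with unique probe ids as colnames.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; every
#'   probe maps to exactly one gene.
#' @param on_unmapped `"drop"` (default; warn and discard probes not in the
#'   map) or `"error"`.
#' @return matrix with one column per gene, colnames = gene ids.
#' @export
collapse_probes_to_genes <- function(x, probe_map,
                                     on_unmapped = c("drop", "error")) {
  on_unmapped <- match.arg(on_unmapped)
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(probe_map)))
  if (anyDuplicated(probe_map$probe_id))
    stop("probe map assigns a probe to more than one gene")
  if (anyDuplicated(colnames(x)))
    stop("duplicate probe ids; run collapse_duplicate_probes() first")

  unmapped <- setdiff(colnames(x), probe_map$probe_id)
  if (length(unmapped)) {
    if (on_unmapped == "error")
      stop("probes absent from map: ", paste(unmapped, collapse = ", "))
    warning("dropping ", length(unmapped), " unmapped probe(s): ",
            paste(unmapped, collapse = ", "))
    x <- x[, setdiff(colnames(x), unmapped), drop = FALSE]
  }
  gene_of <- stats::setNames(probe_map$gene_id, probe_map$probe_id)
  genes <- gene_of[colnames(x)]
  probe_means <- colMeans(x, na.rm = TRUE)

  keep <- character(0)
  for (g in unique(genes)) {
    probes <- colnames(x)[genes == g]
    # max-mean probe wins; ties resolved by lexicographic probe id
    probes <- probes[order(-probe_means[probes], probes)]
    keep <- c(keep, probes[1L])
  }
  out <- x[, keep, drop = FALSE]
  colnames(out) <- unname(gene_of[keep])
  out
}

#' Remove near-zero-variance features
#'
#' A feature is removed when it is almost constant: the ratio of the most
#' common to the second most common value exceeds `freq_ratio_cut` AND the
#' percentage of distinct values relative to the sample count falls below
#' `unique_pct_cut`. Constant columns (one distinct value) always satisfy
#' the frequency criterion. Missing values are ignored when tabulating.
#'
#' @param x numeric matrix, samples in rows.
#' @param freq_ratio_cut frequency-ratio cutoff (default 19, i.e. 95/5).
#' @param unique_pct_cut distinct-value percentage cutoff (default 10).
#' @return list with `x` (surviving columns) and `removed` (character vector
#'   of removed feature ids).
#' @export
filter_near_zero_variance <- function(x, freq_ratio_cut = 19,
                                      unique_pct_cut = 10) {
  if (ncol(x) == 0L || nrow(x) == 0L) stop("empty matrix")
  nzv <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    v <- v[!is.na(v)]
    if (!length(v)) return(TRUE)
    tab <- sort(table(v), decreasing = TRUE)
    freq_ratio <- if (length(tab) == 1L) Inf else
      as.numeric(tab[1L]) / as.numeric(tab[2L])
    unique_pct <- 100 * length(tab) / nrow(x)
    freq_ratio > freq_ratio_cut && unique_pct < unique_pct_cut
  }, logical(1))
  if (all(nzv)) stop("no features survive variance filter")
  list(x = x[, !nzv, drop = FALSE], removed = colnames(x)[nzv])
}

#' Impute missing values by the per-feature median
#'
#' Features whose missingness exceeds `max_feature_missing` percent are
#' dropped first, then samples above `max_sample_missing` percent; remaining
#' gaps are filled with the median of each feature's observed values. A
#' feature left entirely missing after the sample drops is removed with a
#' message.
#'
#' @param x numeric matrix, samples in rows.
#' @param max_feature_missing maximum tolerated feature missingness, percent.
#' @param max_sample_missing maximum tolerated sample missingness, percent.
#' @return matrix with no missing values; dropped ids are attached as
#'   attributes `dropped_features` and `dropped_samples`.
#' @export
impute_missing <- function(x, max_feature_missing = 20,
                           max_sample_missing = 20) {
  feat_miss <- 100 * colMeans(is.na(x))
  dropped_features <- colnames(x)[feat_miss > max_feature_missing]
  x <- x[, feat_miss <= max_feature_missing, drop = FALSE]

  samp_miss <- 100 * rowMeans(is.na(x))
  dropped_samples <- rownames(x)[samp_miss > max_sample_missing]
  x <- x[samp_miss <= max_sample_missing, , drop = FALSE]

  all_missing <- colnames(x)[colSums(!is.na(x)) == 0L]
  if (length(all_missing)) {
    message("removing feature(s) fully missing after sample drops: ",
            paste(all_missing, collapse = ", "))
    dropped_features <- c(dropped_features, all_missing)
    x <- x[, !colnames(x) %in% all_missing, drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- stats::median(x[!miss, j])
  }
  structure(x, dropped_features = dropped_features,
            dropped_samples = dropped_samples)
}

#' Autoscale features to zero mean and unit standard deviation
#'
#' Centers and scales each feature column (sample standard deviation). Can be
#' bypassed when the input is already normalised, e.g. RMA-processed
#' microarray matrices.
#'
#' @param x numeric matrix with no missing values.
#' @param enabled when `FALSE` the input is returned unchanged.
#' @return scaled matrix with the same dimnames.
#' @export
autoscale <- function(x, enabled = TRUE) {
  if (!enabled) return(x)
  if (anyNA(x)) stop("missing values present; impute before autoscaling")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s) reached autoscaling (run the variance ",
         "filter first): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Run the full preprocessing chain in its fixed order
#'
#' Applies, in order: duplicate-probe merging, probe-to-gene collapsing (only
#' when a probe map is supplied), near-zero-variance filtering, missingness
#' handling with median imputation, and autoscaling. The order is fixed and
#' recorded in the returned log.
#'
#' @param x numeric matrix, samples in rows.
#' @param probe_map optional probe-to-gene map (see
#'   [collapse_probes_to_genes()]).
#' @param freq_ratio_cut,unique_pct_cut variance-filter cutoffs.
#' @param max_feature_missing,max_sample_missing missingness caps, percent.
#' @param scale. apply autoscaling (default `TRUE`).
#' @return list with `x` (clean matrix), `removed` (features removed by the
#'   variance filter), `dropped_features`, `dropped_samples` (missingness
#'   drops), and `log` (character vector describing each stage).
#' @export
preprocess_omics <- function(x, probe_map = NULL,
                             freq_ratio_cut = 19, unique_pct_cut = 10,
                             max_feature_missing = 20,
                             max_sample_missing = 20, scale. = TRUE) {
  log <- sprintf("input: %d samples x %d features", nrow(x), ncol(x))
  x <- collapse_duplicate_probes(x)
  log <- c(log, sprintf("median-collapse: %d features", ncol(x)))
  if (!is.null(probe_map)) {
    x <- collapse_probes_to_genes(x, probe_map)
    log <- c(log, sprintf("gene-collapse: %d features", ncol(x)))
  }
  flt <- filter_near_zero_variance(x, freq_ratio_cut, unique_pct_cut)
  x <- flt$x
  log <- c(log, sprintf("variance filter: removed %d, kept %d",
                        length(flt$removed), ncol(x)))
  x <- impute_missing(x, max_feature_missing, max_sample_missing)
  dropped_features <- attr(x, "dropped_features")
  dropped_samples <- attr(x, "dropped_samples")
  attr(x, "dropped_features") <- NULL
  attr(x, "dropped_samples") <- NULL
  log <- c(log, sprintf("imputation: %d samples x %d features remain",
                        nrow(x), ncol(x)))
  x <- autoscale(x, enabled = scale.)
  log <- c(log, if (scale.) "autoscale: applied" else "autoscale: bypassed")
  list(x = x, removed = flt$removed, dropped_features = dropped_features,
       dropped_samples = dropped_samples, log = log)
}

#' Construct a binary contrast from multi-level outcome labels
#'
#' Reduces a categorical outcome to a two-level comparison: the levels in
#' `positive` are pooled into the positive class, those in `negative` into
#' the negative class, and samples carrying any other level are excluded
#' (e.g. contrasting AML against controls while excluding a transitional
#' MDS cohort). Pooled classes are named by joining their source levels
#' with `+`.
#'
#' @param y factor (or character) of per-sample outcome labels.
#' @param positive character vector of levels forming the positive class.
#' @param negative character vector of levels forming the negative class.
#' @return list with `y` (factor, levels `c(negative, positive)` so the
#'   positive class is the second level), `idx` (integer indices of retained
#'   samples, for subsetting the matrix), and `counts` (retained samples per
#'   class).
#' @examples
#' y <- rep(c("AML", "control", "MDS"), c(404, 138, 164))
#' ct <- make_contrast(y, positive = "AML", negative = "control")
#' length(ct$idx)  # 542
#' @export
make_contrast <- function(y, positive, negative) {
  y <- as.character(y)
  if (length(intersect(positive, negative)))
    stop("a level cannot be in both classes")
  unknown <- setdiff(c(positive, negative), unique(y))
  if (length(unknown))
    stop("contrast level(s) absent from labels: ",
         paste(unknown, collapse = ", "))
  idx <- which(y %in% c(positive, negative))
  pos_name <- paste(positive, collapse = "+")
  neg_name <- paste(negative, collapse = "+")
  lab <- ifelse(y[idx] %in% positive, pos_name, neg_name)
  out <- factor(lab, levels = c(neg_name, pos_name))
  counts <- table(out)
  if (any(counts < 2L))
    stop("each contrast class needs at least 2 samples")
  list(y = out, idx = idx, counts = counts)
}
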