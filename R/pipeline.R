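`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full biomarker-identification pipeline
#'
#' Executes the four stages in their fixed order — data quality, penalty-
#' optimised feature selection, stability-based biomarker identification,
#' and clinical-relevance assessment (combinatorial panel search plus the
#' permuted-label AUC null) — and writes every artifact to `output_dir`:
#' selection profiles and the panel ranking as CSV, both AUC vectors as CSV,
#' a JSON evaluation summary, figures, a Markdown report, and a run manifest
#' that fully determines a re-run.
#'
#' When several `alpha` values are configured (default: LASSO and Elastic
#' Net) each method is profiled on the same split schedule and features
#' identified by all methods are carried into the combinatorial stage.
#'
#' @param config a [pipeline_config()], or the path to a YAML file holding
#'   config keys plus a data source (`input`/`outcome_column`/`probe_map`
#'   or a `simulate:` block of [simulate_omics()] arguments).
#' @param output_dir directory for all artifacts (created if absent).
#' @param data data-source list when `config` is given in-memory; ignored
#'   when `config` is a YAML path.
#' @return invisibly, an object of class `"pipeline_run"` holding the
#'   preprocessed data, all selection profiles, the panel ranking, the
#'   evaluation result and the manifest.
#' @export
run_pipeline <- function(config, output_dir, data = NULL) {
  if (is.character(config) && length(config) == 1L) {
    parsed <- read_pipeline_config(config)
    cfg <- parsed$config
    data <- parsed$data
  } else {
    cfg <- config
    validate_config(cfg)
  }
  if (is.null(data) || (is.null(data$input) && is.null(data$simulate)))
    stop("no data source: supply 'input' + 'outcome_column' or 'simulate'")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- stage 1: data quality ------------------------------------------------
  input_files <- character(0)
  dq <- run_stage("data_quality", {
    if (!is.null(data$simulate)) {
      args <- data$simulate
      args$seed <- args$seed %||% cfg$seed
      sim <- do.call(simulate_omics, args)
      x <- sim$x; y <- sim$y
      probe_map <- NULL
    } else {
      input_files <- c(input_files, data$input)
      loaded <- read_omics(data$input, data$outcome_column,
                           sep = data$sep %||% ",",
                           transpose = isTRUE(data$transpose))
      x <- loaded$x; y <- loaded$y
      probe_map <- NULL
      if (!is.null(data$probe_map)) {
        input_files <- c(input_files, data$probe_map)
        probe_map <- utils::read.csv(data$probe_map,
                                     stringsAsFactors = FALSE)
      }
    }
    pp <- preprocess_omics(x, probe_map, scale. = data$scale %||% TRUE)
    keep <- rownames(pp$x)
    y <- droplevels(y[keep])
    if (nlevels(y) != 2L)
      stop("outcome must have exactly two levels after preprocessing; ",
           "use make_contrast() to reduce multi-level outcomes")
    list(x = pp$x, y = y, log = pp$log, removed = pp$removed,
         input_files = input_files)
  })

  # -- stage 2+3: selection with optimised penalty, stability ranking -------
  profiles <- run_stage("feature_selection", {
    lapply(cfg$alpha, function(a)
      stability_select(dq$x, dq$y, cfg, alpha = a))
  })
  names(profiles) <- vapply(cfg$alpha, function(a)
    if (a == 1) "lasso" else sprintf("en_alpha_%g", a), character(1))
  stable <- Reduce(intersect, lapply(profiles, `[[`, "stable_set"))

  # -- stage 4: clinical relevance ------------------------------------------
  ranking <- run_stage("panel_search",
    combinatorial_search(dq$x, dq$y, stable, cfg$max_panel_size,
                         cfg$n_resamples, cfg$train_fraction, cfg$seed))
  evaluation <- NULL
  if (nrow(ranking)) {
    top_panel <- strsplit(ranking$panel[1L], "+", fixed = TRUE)[[1L]]
    evaluation <- run_stage("permutation_null",
      permutation_stability(dq$x, dq$y, top_panel, cfg$n_resamples,
                            cfg$train_fraction, cfg$seed))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("stabmark")),
    seed = cfg$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(cfg),
    input_hashes = if (length(dq$input_files))
      as.list(tools::md5sum(dq$input_files)) else list(),
    stage_counts = list(
      samples = nrow(dq$x), features = ncol(dq$x),
      removed_near_zero_variance = length(dq$removed),
      stable_features = length(stable),
      panels_evaluated = nrow(ranking))
  )

  run <- structure(list(x = dq$x, y = dq$y, log = dq$log,
                        profiles = profiles, stable_set = stable,
                        ranking = ranking, evaluation = evaluation,
                        config = cfg, manifest = manifest,
                        output_dir = output_dir),
                   class = "pipeline_run")
  write_run_artifacts(run)
  render_report(run)
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run —", nrow(x$x), "samples x", ncol(x$x), "features\n")
  cat("  stable set:", if (length(x$stable_set))
    paste(x$stable_set, collapse = ", ") else "(empty)", "\n")
  if (!is.null(x$evaluation))
    cat(sprintf("  top panel %s: real AUC %.3f vs permuted %.3f\n",
                x$ranking$panel[1L], x$evaluation$summary$mean_auc[1L],
                x$evaluation$summary$mean_auc[2L]))
  cat("  artifacts in", x$output_dir, "\n")
  invisible(x)
}

write_run_artifacts <- function(run) {
  out <- run$output_dir
  for (m in names(run$profiles))
    utils::write.csv(as.data.frame(run$profiles[[m]]),
                     file.path(out, sprintf("selection_%s.csv", m)),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(run$ranking),
                   file.path(out, "panel_ranking.csv"), row.names = FALSE)
  if (!is.null(run$evaluation)) {
    ev <- run$evaluation
    utils::write.csv(data.frame(resample = seq_along(ev$real_aucs),
                                real_auc = ev$real_aucs,
                                permuted_auc = ev$permuted_aucs),
                     file.path(out, "aucs.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(panel = ev$panel,
           real = list(mean_auc = mean(ev$real_aucs),
                       sd_auc = stats::sd(ev$real_aucs)),
           permuted = list(mean_auc = mean(ev$permuted_aucs),
                           sd_auc = stats::sd(ev$permuted_aucs)),
           real_metrics = as.list(colMeans(ev$real_metrics, na.rm = TRUE))),
      file.path(out, "evaluation_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  writeLines(run$stable_set, file.path(out, "feature_list.txt"))
  writeLines(run$log, file.path(out, "preprocessing_log.txt"))
  jsonlite::write_json(run$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(run)
}

#' Render the figures and Markdown report of a pipeline run
#'
#' Produces the run's human-readable outputs: a selection-frequency bar
#' chart per method, per-feature class box plots annotated with two-sided
#' rank-sum (Wilcoxon) p-values, the real-versus-permuted AUC density plot
#' with dashed mean lines, a coefficient-weight distribution plot, the
#' plain-text stable feature list (ready to paste into enrichment tools),
#' and `report.md` tying them together. Every number shown in the report is
#' also present in a machine-readable CSV/JSON artifact. With an empty
#' stable set the report states so and panel figures are omitted.
#'
#' @param run a `"pipeline_run"` object.
#' @return invisibly, the path of the report.
#' @export
render_report <- function(run) {
  out <- run$output_dir
  fig <- function(name, w = 900, h = 600, expr) {
    path <- file.path(out, name)
    grDevices::png(path, width = w, height = h)
    on.exit(grDevices::dev.off())
    expr
    path
  }
  for (m in names(run$profiles))
    fig(sprintf("frequency_%s.png", m), expr = plot(run$profiles[[m]]))

  pvals <- NULL
  if (length(run$stable_set)) {
    pvals <- vapply(run$stable_set, function(f)
      stats::wilcox.test(run$x[, f] ~ run$y, exact = FALSE,
                         correct = FALSE)$p.value,
      numeric(1))
    utils::write.csv(data.frame(feature = run$stable_set,
                                rank_sum_p = unname(pvals)),
                     file.path(out, "boxplot_pvalues.csv"),
                     row.names = FALSE)
    fig("class_boxplots.png", expr = {
      k <- length(run$stable_set)
      graphics::par(mfrow = c(1, k), mar = c(4, 4, 3, 1))
      for (f in run$stable_set)
        graphics::boxplot(run$x[, f] ~ run$y, xlab = "", ylab = f,
                          main = sprintf("%s\np = %.2e", f, pvals[[f]]),
                          col = c("grey80", "steelblue"))
    })
    fig("coefficient_weights.png", expr = {
      cm <- run$profiles[[1L]]$coef_matrix[run$stable_set, , drop = FALSE]
      graphics::boxplot(t(cm), las = 2,
                        ylab = "Fitted coefficient across iterations",
                        main = "Coefficient-weight distributions",
                        col = "steelblue")
      graphics::abline(h = 0, lty = 2)
    })
  }
  if (!is.null(run$evaluation))
    fig("auc_density.png", expr = plot(run$evaluation))

  lines <- c(
    "# Biomarker identification report", "",
    sprintf("- samples: %d, features after preprocessing: %d",
            nrow(run$x), ncol(run$x)),
    sprintf("- methods: %s", paste(names(run$profiles), collapse = ", ")),
    sprintf("- stability threshold: > %d of %d iterations",
            run$config$appearance_threshold, run$config$n_iterations),
    "", "## Preprocessing", "",
    paste0("    ", run$log),
    "", "## Stable features", "")
  if (length(run$stable_set)) {
    lines <- c(lines,
      sprintf("Features selected by every method (`feature_list.txt`): %s",
              paste(run$stable_set, collapse = ", ")),
      "", "Per-method profiles: `selection_*.csv`; frequency charts: ",
      paste(sprintf("`frequency_%s.png`", names(run$profiles)),
            collapse = ", "),
      "", "Class box plots with rank-sum p-values",
      "(`class_boxplots.png`, `boxplot_pvalues.csv`);",
      "coefficient weights: `coefficient_weights.png`.",
      "", "## Panel ranking", "",
      sprintf("%d panels evaluated over %d resamples (`panel_ranking.csv`).",
              nrow(run$ranking), run$config$n_resamples),
      sprintf("Top panel: **%s**, mean test AUC %.3f (SD %.3f).",
              run$ranking$panel[1L], run$ranking$mean_auc[1L],
              run$ranking$sd_auc[1L]))
    if (!is.null(run$evaluation)) {
      s <- run$evaluation$summary
      lines <- c(lines, "", "## Permutation-null validation", "",
        sprintf(paste0("Real arm mean AUC %.3f (SD %.3f) vs permuted ",
                       "%.3f (SD %.3f) over %d resamples "),
                s$mean_auc[1L], s$sd_auc[1L], s$mean_auc[2L], s$sd_auc[2L],
                run$evaluation$n_resamples),
        "(`aucs.csv`, `evaluation_summary.json`, `auc_density.png`).")
    }
  } else {
    lines <- c(lines, "No stable features were identified at this threshold;",
               "panel search and permutation validation were skipped.")
  }
  report <- file.path(out, "report.md")
  writeLines(lines, report)
  invisible(report)
}
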