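#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one named list with
#' explicit seeds. The configuration round-trips losslessly through its text
#' file form ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param n_bands Wavelength grid size (default 61 bands over 400-1000 nm).
#' @param n_plants_per_species Plants per species (default 25).
#' @param roi_counts Per-species ROI totals (default [weed_roi_counts()],
#'   the reported imbalanced counts); `NULL` draws 2-3 ROIs per plant.
#' @param pixels_per_roi Pixels per ROI (default 60).
#' @param smooth_window Moving-average window (default 5).
#' @param snv_enabled Apply SNV (default `TRUE`).
#' @param metric_window Wavelength window for the spectral metrics (nm).
#' @param train_fraction Plant-wise training fraction (default 0.7).
#' @param algorithms Classifier ids to train.
#' @param hyperparams Named list of per-algorithm hyperparameter overrides.
#' @param pca_k Components retained in the pixel PCA stage.
#' @param seed Top-level seed; stage seeds are derived from it
#'   deterministically.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_bands = 61, n_plants_per_species = 25,
                            roi_counts = weed_roi_counts(),
                            pixels_per_roi = 60, smooth_window = 5,
                            snv_enabled = TRUE, metric_window = c(500, 780),
                            train_fraction = 0.7,
                            algorithms = .algorithms(),
                            hyperparams = list(), pca_k = 6, seed = 1) {
  bad <- setdiff(algorithms, .algorithms())
  if (length(bad))
    stop("unknown algorithm id(s) in 'algorithms': ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_bands = n_bands,
                 n_plants_per_species = n_plants_per_species,
                 roi_counts = roi_counts, pixels_per_roi = pixels_per_roi,
                 smooth_window = smooth_window, snv_enabled = snv_enabled,
                 metric_window = metric_window,
                 train_fraction = train_fraction, algorithms = algorithms,
                 hyperparams = hyperparams, pca_k = pca_k, seed = seed),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as text
#'
#' @param config A `pipeline_config`.
#' @param path File path (R `dput` text form).
#' @return `read_pipeline_config` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(deparse(unclass(config)), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- eval(parse(text = paste(readLines(path), collapse = "\n")))
  class(x) <- "pipeline_config"
  x
}

# Deterministic stage seeds from the top-level seed; kept below 2^31.
.stage_seed <- function(seed, stage) {
  (seed * 1000 + match(stage, c("cohort", "split", "train", "pca"))) %%
    .Machine$integer.max
}

#' Run the end-to-end analysis
#'
#' simulate -> preprocess -> pixel PCA -> spectral metrics -> plant-wise
#' split -> train every configured classifier -> evaluate on the held-out
#' plants. Writes all artifacts (delimited tables, per-algorithm reports, a
#' comparison table, a log with stage timings and the configuration hash)
#' under `out_dir` and returns them invisibly. Rerunning with the same
#' configuration reproduces the deterministic outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `cohort`, `pca`, `metrics`, `split`,
#'   `reports`, `comparison`, `paths`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("weedspec_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.txt")
  write_pipeline_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      msg <- paste0("stage '", stage, "' failed: ", conditionMessage(e))
      writeLines(msg, log_con)
      stop(msg, call. = FALSE)
    })
    writeLines(sprintf("[%s] %s: %.2fs", cfg_hash, stage,
                       proc.time()[["elapsed"]] - t0), log_con)
    res
  }

  cohort <- tick("simulate", generate_cohort(
    n_plants_per_species = config$n_plants_per_species,
    pixels_per_roi = config$pixels_per_roi,
    wavelengths = default_wavelengths(config$n_bands),
    roi_counts = config$roi_counts,
    seed = .stage_seed(config$seed, "cohort")))

  metrics <- tick("metrics", stats_table(cohort,
                                         window = config$metric_window))
  metrics_path <- file.path(out_dir, "species_metrics.tsv")
  utils::write.table(metrics, metrics_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pca <- tick("pca", fit_pixel_pca(
    cohort_pixels(cohort, max_pixels = 10000,
                  seed = .stage_seed(config$seed, "pca")),
    k = config$pca_k))
  utils::write.table(
    data.frame(component = seq_len(config$pca_k),
               eigenvalue = pca$eigenvalues,
               explained_pct = explained_variance(pca),
               cumulative_pct = vapply(seq_len(config$pca_k),
                                       function(k) cumulative_variance(pca, k),
                                       0)),
    file.path(out_dir, "pca_variance.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  feats <- tick("features", roi_features(cohort,
                                         smooth_window = config$smooth_window,
                                         snv_enabled = config$snv_enabled))
  plan <- tick("split", plant_wise_split(cohort,
                                         train_fraction = config$train_fraction,
                                         seed = .stage_seed(config$seed,
                                                            "split")))
  write_split_plan(plan, file.path(out_dir, "split_plan.tsv"))
  role <- stats::setNames(plan$role, plan$plant_id)[feats$plant]
  tr <- role == "train"

  reports <- list()
  for (algo in config$algorithms) {
    mdl <- tick(paste0("train_", algo), train_classifier(
      feats$x[tr, , drop = FALSE], algo, y = feats$y[tr],
      hyperparams = if (!is.null(config$hyperparams[[algo]]))
        config$hyperparams[[algo]] else list(),
      seed = .stage_seed(config$seed, "train")))
    prob <- stats::predict(mdl, feats$x[!tr, , drop = FALSE], type = "prob")
    rep <- evaluation_report(feats$y[!tr], prob, priors = mdl$priors,
                             algorithm = algo)
    reports[[algo]] <- rep
    utils::write.table(rep$per_class,
                       file.path(out_dir, paste0("report_", algo, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  comparison <- compare_report(reports)
  utils::write.table(comparison, file.path(out_dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("[%s] done", cfg_hash), log_con)
  invisible(list(cohort = cohort, pca = pca, metrics = metrics, split = plan,
                 reports = reports, comparison = comparison,
                 paths = list(out_dir = out_dir, metrics = metrics_path,
                              config = cfg_path, log = log_path)))
}
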