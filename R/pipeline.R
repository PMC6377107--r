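#' Run the full texture-analysis pipeline
#'
#' Executes, under one seed: simulate (or ingest) -> preprocess -> PCA score
#' maps -> Haralick features -> pairwise dose comparison, writing every
#' intermediate artifact to `out_dir`:
#'
#' * `dataset.csv` — the (simulated or ingested) spectra;
#' * `maps/<map_id>.pgm` + `maps/<map_id>.csv` and `maps/manifest.csv`;
#' * `features.csv` — the per-map Haralick feature table;
#' * `comparisons.csv` — the pairwise Kruskal-Wallis table;
#' * `boxplot_<feature>.png` — one box-plot figure per feature;
#' * `run_manifest.yaml` — configuration, seed and per-file MD5 checksums.
#'
#' Identical `(config, seed)` give identical feature and comparison tables.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param input Optional path to a spectral CSV to ingest instead of
#'   simulating.
#' @param figures Write box-plot PNGs (default `TRUE`).
#' @return Invisible list with the in-memory artifacts: `dataset` (raw),
#'   `preprocessed`, `fit`, `maps`, `features`, `comparisons`, `paths`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, input = NULL,
                         figures = TRUE) {
  if (!inherits(config, "run_config")) stopf("`config` must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  maps_dir <- file.path(out_dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ds <- stage("simulate/ingest", {
    if (is.null(input)) {
      design_args <- config$design
      design_args$seed <- config$seed
      synthesize_study(do.call(study_design, design_args))
    } else {
      read_spectral_csv(input)
    }
  })
  write_spectral_csv(ds, file.path(out_dir, "dataset.csv"))

  pp <- stage("preprocess", {
    preprocess_dataset(ds, do.call(preprocess_config, config$preprocess))
  })

  fit <- stage("map", fit_pca(pp, q = 3))
  maps <- stage("map", gray_maps_from_scores(
    fit, n_levels = config$n_levels, scale_mode = config$scale_mode))
  manifest <- do.call(rbind, lapply(maps, function(m) data.frame(
    map_id = m$map_id, mouse_id = m$mouse_id, dose_gy = m$dose_gy,
    rows = nrow(m$levels), cols = ncol(m$levels), n_levels = m$n_levels,
    stringsAsFactors = FALSE
  )))
  write.csv(manifest, file.path(maps_dir, "manifest.csv"), row.names = FALSE)
  for (m in maps) {
    write_pgm(m, file.path(maps_dir, paste0(m$map_id, ".pgm")))
    write.table(m$levels, file.path(maps_dir, paste0(m$map_id, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }

  features <- stage("texture", features_for_dataset(
    maps, distance = config$distance, angles = config$angles,
    log_base = if (config$log_base == "2") 2 else exp(1)))
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)

  comparisons <- stage("compare", pairwise_dose_tests(
    features, correction = config$correction, cluster = config$cluster))
  write.csv(comparisons, file.path(out_dir, "comparisons.csv"), row.names = FALSE)

  if (figures) {
    plots <- plot_feature_boxplots(features)
    for (feat in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, sprintf("boxplot_%s.png", feat)),
                      plots[[feat]], width = 5, height = 4, dpi = 120)
    }
  }

  files <- c("dataset.csv", "features.csv", "comparisons.csv")
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest_doc <- list(config = unclass(config), seed = config$seed,
                       checksums = as.list(checksums))
  yaml::write_yaml(manifest_doc, file.path(out_dir, "run_manifest.yaml"))

  invisible(list(dataset = ds, preprocessed = pp, fit = fit, maps = maps,
                 features = features, comparisons = comparisons,
                 paths = list(out_dir = out_dir)))
}
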