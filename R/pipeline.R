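# End-to-end orchestration: scene -> features -> screening/SPA ->
# models -> sweep/reports. All randomness flows from one root seed via
# named substreams so any run can be replayed from its manifest.

.substream <- function(root, name) {
  offset <- c(scene = 1, split = 2, rf = 3, cnn = 4, spa = 5, sweep = 6)
  if (!name %in% names(offset)) stop("unknown substream: ", name)
  as.integer((as.numeric(root) + offset[[name]] * 1000003) %% 2147483647)
}

#' Pipeline run configuration
#'
#' @param scene A [scene_config()].
#' @param feature_sets Subset of `"MS_VI"`, `"RGB_VI"`, `"RGB_TF"`,
#'   `"RGB_VI&TF"`; `MS_VI` requires `scene$ms_enabled`.
#' @param k_min,k_max SPA subset-size range.
#' @param specs List of [model_spec()]s.
#' @param sizes Sample sizes for the sweep.
#' @param seeds Sweep seeds.
#' @param seed Root seed feeding every stage's substream.
#' @return A `run_config` list, validated.
#' @export
run_config <- function(scene = scene_config(),
                       feature_sets = c("RGB_VI", "RGB_TF", "RGB_VI&TF"),
                       k_min = 3, k_max = 15,
                       specs = list(model_spec("RF"), model_spec("CNN")),
                       sizes = seq(140, 840, by = 100),
                       seeds = 1L, seed = 1L) {
  known <- c("MS_VI", "RGB_VI", "RGB_TF", "RGB_VI&TF")
  if (!all(feature_sets %in% known))
    stop("unknown feature set(s): ",
         paste(setdiff(feature_sets, known), collapse = ", "))
  if ("MS_VI" %in% feature_sets && !scene$ms_enabled)
    stop("feature set MS_VI requires a scene with ms_enabled = TRUE")
  total <- scene$n_trees_per_class * length(scene$classes)
  if (max(sizes) > total)
    stop("sweep size ", max(sizes), " exceeds the ", total,
         "-tree scene")
  structure(list(scene = scene, feature_sets = feature_sets,
                 k_min = k_min, k_max = k_max, specs = specs,
                 sizes = sizes, seeds = as.integer(seeds),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Extract every feature family from a scene
#'
#' Vegetation-index canopy means plus GLCM texture canopy means, min-max
#' normalised, in one table.
#'
#' @param scene A [generate_scene()] scene.
#' @param normalise Normalise the combined table (default TRUE)?
#' @return A [feature_table()] with `RGB_VI:*`, `RGB_TF:*` and (for
#'   multispectral scenes) `MS_VI:*` columns.
#' @export
scene_features <- function(scene, normalise = TRUE) {
  vi <- extract_canopy_means(scene)
  tf <- canopy_texture_features(scene)
  out <- cbind_features(vi, tf)
  if (normalise) normalise_features(out) else out
}

#' Run the full experiment
#'
#' Generates the scene, extracts and normalises all features, screens and
#' SPA-selects a sensitive subset per feature set, runs the sample-size
#' sweep for every model, and — at full sample size — writes confusion
#' matrices, feature importances and an SPA-vs-all-features comparison.
#' Fully reproducible per root seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `sweep.csv`,
#'   `sweep_summary.csv`, `selection.json`, `screening.csv`,
#'   `confusion_<set>_<model>.csv`, `importances.csv`,
#'   `spa_vs_all.csv` and `manifest.json` there.
#' @return List with elements `scene`, `features` (normalised table),
#'   `screening`, `selection` (per feature set), `sweep`,
#'   `sweep_summary`, `full_reports` (per set x model at full size) and
#'   `spa_vs_all`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  scene_cfg <- config$scene
  scene_cfg$seed <- .substream(config$seed, "scene")
  scene <- generate_scene(scene_cfg)
  labels <- scene$truth$level
  features <- scene_features(scene)

  screening <- screen_features(features, labels)
  selection <- list()
  sel_tabs <- list()
  all_tabs <- list()
  for (fs in config$feature_sets) {
    sub <- select_features(features, set = fs)
    res <- select_sensitive(sub, labels, k_min = min(config$k_min,
                                                     ncol(sub$values)),
                            k_max = min(config$k_max, ncol(sub$values)),
                            seed = .substream(config$seed, "spa"))
    selection[[fs]] <- res$selection
    sel_tabs[[fs]] <- select_features(features,
                                      features = res$selection$selected)
    all_tabs[[fs]] <- sub
  }

  sweep <- sample_size_sweep(sel_tabs, labels, sizes = config$sizes,
                             specs = config$specs, seeds = config$seeds)
  sweep_summary <- summarise_sweep(sweep)

  # full-sample reports and the SPA-vs-all-features comparison
  plan <- make_split(features$tree_id, labels,
                     seed = .substream(config$seed, "split"))
  full_reports <- list()
  cmp_rows <- list()
  for (fs in config$feature_sets) {
    for (spec in config$specs) {
      spec$seed <- .substream(config$seed,
                              if (spec$kind == "RF") "rf" else "cnn")
      rep_spa <- evaluate_split(sel_tabs[[fs]], labels, plan, spec,
                                meta = list(feature_set = fs,
                                            features = "SPA"))
      rep_all <- evaluate_split(all_tabs[[fs]], labels, plan, spec,
                                meta = list(feature_set = fs,
                                            features = "all"))
      full_reports[[paste(fs, spec$kind, sep = "_")]] <- rep_spa
      cmp_rows[[length(cmp_rows) + 1]] <- data.frame(
        feature_set = fs, model = spec$kind,
        OA_spa = rep_spa$OA, Kappa_spa = rep_spa$Kappa,
        OA_all = rep_all$OA, Kappa_all = rep_all$Kappa)
    }
  }
  spa_vs_all <- do.call(rbind, cmp_rows)

  result <- list(scene = scene, features = features,
                 screening = screening, selection = selection,
                 sweep = sweep, sweep_summary = sweep_summary,
                 full_reports = full_reports, spa_vs_all = spa_vs_all)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sweep, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(sweep_summary,
                     file.path(out_dir, "sweep_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(screening, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(selection, function(s) list(
        selected = s$selected, k = s$k, error = s$error,
        scores = s$scores)),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    for (nm in names(full_reports))
      write_confusion(full_reports[[nm]]$confusion,
                      file.path(out_dir, paste0("confusion_",
                                                gsub("[&]", "", nm),
                                                ".csv")))
    imp <- do.call(rbind, lapply(names(full_reports), function(nm) {
      v <- full_reports[[nm]]$importances
      data.frame(run = nm, feature = names(v), importance = unname(v))
    }))
    utils::write.csv(imp, file.path(out_dir, "importances.csv"),
                     row.names = FALSE)
    utils::write.csv(spa_vs_all, file.path(out_dir, "spa_vs_all.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "needlegrade",
      version = as.character(utils::packageVersion("needlegrade")),
      seed = config$seed, seeds = config$seeds,
      sizes = config$sizes, feature_sets = config$feature_sets,
      scene = config$scene[setdiff(names(config$scene),
                                   "class_color_means")],
      class_color_means = config$scene$class_color_means,
      models = lapply(config$specs, function(s)
        c(list(kind = s$kind), s$hyper[!vapply(s$hyper, is.null, TRUE)])))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
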