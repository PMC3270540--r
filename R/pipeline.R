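## Run configuration and the extract / select / evaluate pipeline stages.

#' Default run configuration
#'
#' Every tunable of the pipeline, with the method's standard settings as
#' defaults: averaging-filter kernel 3; quantization to 256 grey levels;
#' order-2 displacement magnitude 1 and orders-3/5 component magnitude 2;
#' GLCM orders 2, 3, 5 and EOCM orders 2, 3 with direction averaging
#' (single named combinations, e.g. `"0_270"`, are accepted for the
#' order-3/5 modes); edge threshold 0 with 1-degree orientation bins;
#' Laws detection threshold 1 sd; genetic search with population 20, 20
#' generations, crossover 0.6, mutation 0.033, seed 1; IG top-10 union;
#' the four classifiers; stratified 5-fold cross-validation.
#'
#' @param ... Named overrides of any default.
#' @return A `hotex_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    version = 1L,
    denoise_kernel = 3L,
    quant_L = 256L,
    d2 = 1L,
    d_high = 2L,
    glcm_orders = c(2L, 3L, 5L),
    glcm3_mode = "avg",
    glcm5_mode = "0_180_90_270",
    eocm_orders = c(2L, 3L),
    eocm2_mode = "avg",
    eocm3_mode = "avg",
    edge_threshold = 0,
    orientation_bin = 1L,
    laws_k = 1,
    ga_population = 20L,
    ga_generations = 20L,
    ga_crossover = 0.6,
    ga_mutation = 0.033,
    ga_seed = 1L,
    ig_top_k = 10L,
    ig_positive_only = TRUE,
    classifiers = c("svm_poly3", "mlp", "adaboost_svm", "adaboost_mlp"),
    cv_folds = 5L,
    seed = 1L,
    mlp_epochs = 500L,
    model_bins = 16L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop_validation("unknown config fields: %s",
                    paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  validate_config(structure(cfg, class = "hotex_config"))
}

#' Validate a run configuration
#'
#' @param config A `hotex_config` list.
#' @return The config, invisibly, after checking every field.
#' @export
validate_config <- function(config) {
  with(config, {
    if (denoise_kernel < 1L || denoise_kernel %% 2L == 0L)
      stop_validation("denoise_kernel must be odd and positive")
    if (quant_L < 2L || quant_L > 256L)
      stop_validation("quant_L must be in [2, 256]")
    if (d2 < 1L || d_high < 1L)
      stop_validation("displacement magnitudes must be positive")
    if (!all(glcm_orders %in% c(2L, 3L, 5L)))
      stop_validation("glcm_orders must be a subset of {2, 3, 5}")
    if (!all(eocm_orders %in% c(2L, 3L)))
      stop_validation("eocm_orders must be a subset of {2, 3}")
    if (edge_threshold < 0)
      stop_validation("edge_threshold must be nonnegative")
    if (orientation_bin < 1L || 180L %% orientation_bin != 0L)
      stop_validation("orientation_bin must divide 180")
    if (ga_crossover < 0 || ga_crossover > 1 ||
        ga_mutation < 0 || ga_mutation > 1)
      stop_validation("GA probabilities must be in [0, 1]")
    if (ga_population < 2L || ga_generations < 1L)
      stop_validation("GA population/generations too small")
    if (ig_top_k < 0L) stop_validation("ig_top_k must be nonnegative")
    if (!all(classifiers %in%
             c("svm_poly3", "mlp", "adaboost_svm", "adaboost_mlp")))
      stop_validation(
        "classifiers must be among svm_poly3, mlp, adaboost_svm, adaboost_mlp")
    if (cv_folds < 2L) stop_validation("cv_folds must be at least 2")
  })
  invisible(config)
}

#' Write a configuration to YAML
#'
#' @param config A `hotex_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Missing fields take their defaults, so a config round-trips losslessly
#' through [write_config()].
#'
#' @param path YAML path.
#' @return A `hotex_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  keep <- intersect(names(raw), names(cfg))
  int_fields <- c("version", "denoise_kernel", "quant_L", "d2", "d_high",
                  "glcm_orders", "eocm_orders", "orientation_bin",
                  "ga_population", "ga_generations", "ga_seed", "ig_top_k",
                  "cv_folds", "seed", "mlp_epochs", "model_bins")
  for (f in keep) {
    cfg[[f]] <- if (f %in% int_fields) as.integer(raw[[f]])
                else if (f %in% c("ig_positive_only")) as.logical(raw[[f]])
                else raw[[f]]
  }
  validate_config(structure(cfg, class = "hotex_config"))
}

#' Extract features for every ROI in a manifest
#'
#' Loads each image, cuts the ROI, denoises it with the averaging filter
#' and computes the full feature vector.  ROIs whose image cannot be read
#' are skipped with a warning; if every row fails, an error is raised.
#'
#' @param manifest Manifest data.frame (see [read_roi_manifest()]) or a
#'   path to a manifest CSV.
#' @param config A `hotex_config`.
#' @param out_csv Optional path: write the feature table as CSV (feature
#'   columns plus a final `class` column).
#' @param quiet Suppress progress messages.
#' @return Feature table data.frame.
#' @export
run_extract <- function(manifest, config = default_config(),
                        out_csv = NULL, quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_roi_manifest(manifest)
  validate_config(config)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    fv <- tryCatch({
      img <- load_image(r$image_path)
      roi <- extract_roi(img, r$x0, r$y0, r$width, r$height)
      roi <- mean_filter(roi, config$denoise_kernel)
      compute_feature_vector(roi, config)
    }, error = function(e) {
      warning(sprintf("skipping ROI %d (%s): %s", i, r$image_path,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(fv)) {
      rows[[i]] <- data.frame(as.list(fv), class = r$class_label,
                              stringsAsFactors = FALSE, check.names = FALSE)
    }
    if (!quiet && i %% 50L == 0L)
      message(sprintf("extracted %d/%d ROIs", i, nrow(manifest)))
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    stop("feature extraction failed for every manifest row", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv))
    utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Run feature selection on a feature table
#'
#' @param features Feature table data.frame or path to a feature CSV.
#' @param config A `hotex_config`.
#' @param out_json Optional path for the selection JSON.
#' @return A `selection_result`.
#' @export
run_select <- function(features, config = default_config(),
                       out_json = NULL) {
  if (is.character(features))
    features <- utils::read.csv(features, check.names = FALSE)
  validate_config(config)
  if (length(feature_columns(features)) == 1L) {
    warning("single-feature table: skipping CFS, using IG ranking only",
            call. = FALSE)
    disc <- discretize_table(features)
    f <- feature_columns(features)
    sel <- structure(list(
      cfs_subset = character(0), cfs_merit = 0,
      ig_ranking = data.frame(feature = f,
                              info_gain = info_gain(disc$features[[1L]],
                                                    disc$class)),
      ig_top = f, final_set = f, ig_top_k = 1L),
      class = "selection_result")
  } else {
    sel <- select_union(features, ig_top_k = config$ig_top_k,
                        ig_positive_only = config$ig_positive_only,
                        population = config$ga_population,
                        generations = config$ga_generations,
                        crossover = config$ga_crossover,
                        mutation = config$ga_mutation,
                        seed = config$ga_seed)
  }
  if (!is.null(out_json)) write_selection(sel, out_json)
  sel
}

#' Evaluate classifiers on selected features
#'
#' Runs every configured classifier under stratified cross-validation and
#' returns the reports plus a summary table in the standard layout
#' (classifier, recognition rate, TP rate, TN rate, AUC, time).
#'
#' @param features Feature table data.frame or path to a feature CSV.
#' @param selection A `selection_result`, a path to a selection JSON, or
#'   `NULL` for all features.
#' @param config A `hotex_config`.
#' @param out_csv Optional path for the summary CSV.
#' @return List with `reports` (named list of `texture_eval`) and
#'   `summary` (data.frame).
#' @export
run_evaluate <- function(features, selection = NULL,
                         config = default_config(), out_csv = NULL) {
  if (is.character(features))
    features <- utils::read.csv(features, check.names = FALSE)
  if (is.character(selection)) selection <- read_selection(selection)
  validate_config(config)
  folds <- stratified_folds(features, config$cv_folds, config$seed)
  reports <- lapply(config$classifiers, function(cl)
    evaluate(features, selection, classifier = cl, folds = folds,
             seed = config$seed, mlp_epochs = config$mlp_epochs))
  names(reports) <- config$classifiers
  summary <- eval_summary(reports)
  if (!is.null(out_csv))
    utils::write.csv(summary, out_csv, row.names = FALSE)
  list(reports = reports, summary = summary)
}
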