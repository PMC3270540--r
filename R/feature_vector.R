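## Per-ROI feature vector assembly.
##
## Direction handling follows the method's protocol: features (not
## matrices) are averaged across the direction sets of a family, or a
## single named direction combination is used (e.g. "0_270" for the
## order-3 GLCM).

haralick_names <- c("energy", "entropy", "contrast", "homogeneity",
                    "correlation", "variance", "max_probability")

# Average extended Haralick features over a list of direction sets,
# skipping degenerate (zero-count) sets.  Returns NA features when every
# set is degenerate (e.g. EOCM of an edge-free image).
haralick_over_sets <- function(map, sets, prefix) {
  acc <- matrix(NA_real_, length(sets), length(haralick_names))
  for (i in seq_along(sets)) {
    tensor <- count_cooccurrence(map, sets[[i]])
    if (length(tensor$values) == 0L || tensor$total <= 0) next
    acc[i, ] <- extended_haralick(to_probability(tensor))
  }
  ok <- stats::complete.cases(acc)
  vals <- if (any(ok)) colMeans(acc[ok, , drop = FALSE])
          else rep(NA_real_, length(haralick_names))
  stats::setNames(vals, paste0(prefix, "_", haralick_names))
}

# Resolve a direction mode ("avg" or a set name) to the sets to use and
# the tag embedded in the feature names.
resolve_direction_mode <- function(sets, mode, what) {
  if (identical(mode, "avg")) return(list(sets = sets, tag = "avg"))
  if (!mode %in% names(sets))
    stop_validation("unknown %s direction mode '%s' (valid: avg, %s)",
                    what, mode, paste(names(sets), collapse = ", "))
  list(sets = sets[mode], tag = mode)
}

#' Compute the full feature vector of a ROI
#'
#' Assembles, per the configuration: mean grey level; extended Haralick
#' features of the order-2/3/5 grey-level cooccurrence matrices and the
#' order-2/3 edge-orientation cooccurrence matrices (averaged over
#' direction sets or at a single named combination); edge-orientation
#' variability; gradient statistics; Laws microstructure frequency and
#' density; and the 20 Haar-wavelet subband entropies.  Degenerate
#' sub-features (e.g. EOCM statistics of an edge-free ROI) are recorded as
#' `NA`, so the feature schema is identical for every ROI under one
#' configuration.
#'
#' @param image A denoised ROI (integer intensity matrix).
#' @param config A configuration from [default_config()].
#' @return Named numeric vector of features.
#' @export
compute_feature_vector <- function(image, config = default_config()) {
  check_image(image, min_dim = 5L)
  out <- c(mean_grey = mean_grey(image))

  qmap <- quantize(image, config$quant_L)
  if (2L %in% config$glcm_orders) {
    sets <- standard_direction_sets(2L, "glcm", d2 = config$d2)
    out <- c(out, haralick_over_sets(qmap, sets, "glcm2_avg"))
  }
  if (3L %in% config$glcm_orders) {
    sets <- standard_direction_sets(3L, "glcm", d_high = config$d_high)
    r <- resolve_direction_mode(sets, config$glcm3_mode, "order-3 GLCM")
    out <- c(out, haralick_over_sets(qmap, r$sets, paste0("glcm3_", r$tag)))
  }
  if (5L %in% config$glcm_orders) {
    sets <- standard_direction_sets(5L, "glcm", d_high = config$d_high)
    r <- resolve_direction_mode(sets, config$glcm5_mode, "order-5 GLCM")
    out <- c(out, haralick_over_sets(qmap, r$sets, paste0("glcm5_", r$tag)))
  }

  grads <- sobel_gradients(image)
  omap <- orientation_map(grads$gx, grads$gy,
                          magnitude_threshold = config$edge_threshold,
                          bin_width = config$orientation_bin)
  emap <- orientation_labels(omap)
  if (2L %in% config$eocm_orders) {
    sets <- standard_direction_sets(2L, "eocm", d2 = config$d2)
    r <- resolve_direction_mode(sets, config$eocm2_mode, "order-2 EOCM")
    out <- c(out, haralick_over_sets(emap, r$sets, paste0("eocm2_", r$tag)))
  }
  if (3L %in% config$eocm_orders) {
    sets <- standard_direction_sets(3L, "eocm", d_high = config$d_high)
    r <- resolve_direction_mode(sets, config$eocm3_mode, "order-3 EOCM")
    out <- c(out, haralick_over_sets(emap, r$sets, paste0("eocm3_", r$tag)))
  }

  out <- c(out,
           edge_orientation_variability =
             edge_orientation_variability(omap),
           gradient_statistics(image, config$edge_threshold),
           laws_features(image, config$laws_k),
           wavelet_entropies(image))
  out
}
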