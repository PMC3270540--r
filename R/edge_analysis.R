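## Sobel gradients, edge-orientation maps and edge/gradient statistics.
##
## Edge orientation is the arctangent of Gy/Gx folded into [0, 180) degrees
## (edges are undirected, so orientations 180 degrees apart are identified).

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
sobel_y <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L, byrow = TRUE)

#' Sobel gradients
#'
#' Applies the standard 3x3 Sobel kernels with edge replication.  `gx` is
#' the horizontal gradient (x increasing rightwards), `gy` the vertical
#' gradient (y increasing downward).
#'
#' @param image Integer intensity matrix, at least 3x3.
#' @return List with numeric matrices `gx` and `gy`.
#' @export
sobel_gradients <- function(image) {
  check_image(image, min_dim = 3L)
  list(gx = filter2_replicate(image, sobel_x),
       gy = filter2_replicate(image, sobel_y))
}

#' Edge-orientation map
#'
#' Orientation is `round(atan2(gy, gx))` in degrees, folded into
#' `[0, 180)`.  A pixel is an edge pixel when its gradient magnitude
#' `sqrt(gx^2 + gy^2)` strictly exceeds `magnitude_threshold`; pixels with
#' zero gradient are never edges.
#'
#' @param gx,gy Gradient matrices from [sobel_gradients()].
#' @param magnitude_threshold Edge threshold (default 0: any nonzero
#'   gradient marks an edge).
#' @param bin_width Orientation bin width in degrees (default 1).
#' @return An `orientation_map`: list with `orientation` (integer degrees,
#'   `NA` off edges), `edge_mask`, `gx`, `gy` and `bin_width`.
#' @export
orientation_map <- function(gx, gy, magnitude_threshold = 0,
                            bin_width = 1L) {
  if (!all(dim(gx) == dim(gy)))
    stop_validation("gx and gy must have the same shape")
  bin_width <- as.integer(bin_width)
  if (bin_width < 1L || 180L %% bin_width != 0L)
    stop_validation("bin_width must divide 180, got %d", bin_width)
  mag <- sqrt(gx^2 + gy^2)
  edge <- mag > magnitude_threshold
  deg <- round(atan2(gy, gx) * 180 / pi) %% 180
  ori <- matrix(NA_integer_, nrow(gx), ncol(gx))
  ori[edge] <- as.integer(deg[edge]) %/% bin_width * bin_width
  structure(list(orientation = ori, edge_mask = edge, gx = gx, gy = gy,
                 bin_width = bin_width),
            class = "orientation_map")
}

#' Quantized map of edge orientations
#'
#' Converts an orientation map into the label-map form consumed by
#' [count_cooccurrence()], with the edge mask as validity mask and
#' `L = 180 / bin_width` levels (label = orientation / bin_width).
#'
#' @param omap An `orientation_map`.
#' @return A `quantized_map` over orientation labels.
#' @export
orientation_labels <- function(omap) {
  stopifnot(inherits(omap, "orientation_map"))
  labels <- omap$orientation %/% omap$bin_width
  quantized_map(labels, L = 180L %/% omap$bin_width,
                valid_mask = omap$edge_mask)
}

#' Edge-orientation variability
#'
#' Dispersion of the edge-orientation distribution, computed as the
#' circular (angular) standard deviation on doubled angles — the standard
#' treatment for axial data, where orientations o and o + 180 are the same
#' edge.  With mean resultant length `R` of the doubled angles, the value
#' is `sqrt(2 (1 - R))` radians, reported in degrees: 0 when all edge
#' orientations coincide, up to `sqrt(2)` rad (about 81.03 degrees) for a
#' fully dispersed distribution.
#'
#' @param omap An `orientation_map`.
#' @return Variability in degrees, or `NA` when fewer than 2 edge pixels
#'   exist.
#' @export
edge_orientation_variability <- function(omap) {
  stopifnot(inherits(omap, "orientation_map"))
  o <- omap$orientation[omap$edge_mask]
  if (length(o) < 2L) return(NA_real_)
  doubled <- 2 * o * pi / 180
  R <- sqrt(mean(cos(doubled))^2 + mean(sin(doubled))^2)
  R <- min(R, 1)
  sqrt(2 * (1 - R)) * 180 / pi
}

#' Edge and gradient statistics
#'
#' Classical first-order gradient descriptors: mean and standard deviation
#' of the Sobel gradient magnitude and the fraction of edge pixels.
#'
#' @param image Integer intensity matrix, at least 3x3.
#' @param magnitude_threshold Edge threshold (default 0).
#' @return Named numeric vector `gradient_mean`, `gradient_std`,
#'   `edge_density`.
#' @export
gradient_statistics <- function(image, magnitude_threshold = 0) {
  g <- sobel_gradients(image)
  mag <- sqrt(g$gx^2 + g$gy^2)
  sdv <- stats::sd(as.numeric(mag))
  c(gradient_mean = mean(mag),
    gradient_std = if (is.na(sdv)) 0 else sdv,
    edge_density = mean(mag > magnitude_threshold))
}
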