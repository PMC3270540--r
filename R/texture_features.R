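## Extended Haralick features on order-n cooccurrence tensors, plus the
## classic first-order, Laws and wavelet descriptors.
##
## The order-2 Haralick statistics generalize to n-tuples via the pairwise
## mean squared level difference
##   D2(t) = 2 / (n (n - 1)) * sum_{i<j} (g_i - g_j)^2
## and positional marginal moments; at n = 2 every formula reduces to its
## classical counterpart on a symmetric GLCM.

#' Extended Haralick features of a cooccurrence distribution
#'
#' For a normalized order-n tensor with tuples `t = (g1, ..., gn)` and
#' probabilities `p(t)`:
#' \itemize{
#'   \item energy = sum p^2
#'   \item entropy = -sum p ln p (natural log)
#'   \item contrast = sum p D2(t), with D2 the pairwise mean squared
#'     difference of the tuple components
#'   \item homogeneity = sum p / (1 + D2(t))
#'   \item variance = sum p mean_i (g_i - mu)^2, mu the probability-weighted
#'     mean component level
#'   \item correlation = sum p prod_i (g_i - mu_i) / prod_i sigma_i, over
#'     positional marginal means/sds; reported 0 when any sigma_i is 0
#'   \item max_probability = max p
#' }
#'
#' @param p A normalized `cooc_tensor` (see [to_probability()]).
#' @return Named numeric vector with the seven statistics.
#' @export
extended_haralick <- function(p) {
  stopifnot(inherits(p, "cooc_tensor"))
  if (!p$normalized)
    stop_validation("extended_haralick needs a normalized tensor")
  if (!length(p$values))
    stop_validation("extended_haralick needs a nonempty tensor")
  G <- p$tuples
  w <- p$values
  n <- ncol(G)
  energy <- sum(w^2)
  entropy <- -sum(w * log(w))
  # pairwise mean squared difference per tuple
  if (n >= 2L) {
    d2 <- numeric(nrow(G))
    npairs <- n * (n - 1) / 2
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d2 <- d2 + (G[, i] - G[, j])^2
      }
    }
    d2 <- d2 / npairs
  } else {
    d2 <- numeric(nrow(G))
  }
  contrast <- sum(w * d2)
  homogeneity <- sum(w / (1 + d2))
  mu <- sum(w * rowMeans(G))
  variance <- sum(w * rowMeans((G - mu)^2))
  mu_i <- colSums(w * G)
  sd_i <- sqrt(colSums(w * sweep(G, 2L, mu_i)^2))
  if (any(sd_i < 1e-12)) {
    correlation <- 0
  } else {
    centered <- sweep(G, 2L, mu_i)
    correlation <- sum(w * apply(centered, 1L, prod)) / prod(sd_i)
  }
  c(energy = energy, entropy = entropy, contrast = contrast,
    homogeneity = homogeneity, correlation = correlation,
    variance = variance, max_probability = max(w))
}

#' Mean grey level
#'
#' @param image Integer intensity matrix.
#' @return Arithmetic mean of all pixel values.
#' @export
mean_grey <- function(image) {
  check_image(image)
  mean(image)
}

## Laws texture energy -------------------------------------------------------

laws_vectors <- list(
  level  = c(1, 4, 6, 4, 1),
  edge   = c(-1, -2, 0, 2, 1),
  spot   = c(-1, 0, 2, 0, -1),
  wave   = c(-1, 2, 0, -2, 1),
  ripple = c(1, -4, 6, -4, 1)
)

#' Laws microstructure frequency and density
#'
#' Convolves the image with the separable 5x5 Laws kernels.  For each of
#' the five kernel classes (level, edge, spot, wave, ripple) an energy map
#' is formed from the symmetric kernel pair `v x L5` / `L5 x v` (mean
#' absolute response), normalized pixelwise by the `L5 x L5` response so
#' the detection is contrast-relative; the level class uses the raw
#' `L5 x L5` energy itself.  A pixel is a microstructure hit when its
#' energy strictly exceeds `mean + threshold_k * sd` of its map;
#' `frequency` is the hit count and `density` the hit fraction.
#'
#' @param image Integer intensity matrix, at least 5x5.
#' @param threshold_k Detection threshold in standard deviations above the
#'   map mean (default 1).
#' @return Named numeric vector `laws_<class>_frequency` and
#'   `laws_<class>_density` for the five classes.
#' @export
laws_features <- function(image, threshold_k = 1) {
  check_image(image, min_dim = 5L)
  L5 <- laws_vectors$level
  base <- abs(filter2_replicate(image, outer(L5, L5)))
  out <- numeric(0)
  for (cls in names(laws_vectors)) {
    v <- laws_vectors[[cls]]
    if (cls == "level") {
      emap <- base
    } else {
      resp <- (abs(filter2_replicate(image, outer(v, L5))) +
                 abs(filter2_replicate(image, outer(L5, v)))) / 2
      emap <- ifelse(base > 0, resp / base, 0)
    }
    thr <- mean(emap) + threshold_k * stats::sd(as.numeric(emap))
    hits <- sum(emap > thr)
    out <- c(out, stats::setNames(
      c(hits, hits / length(emap)),
      paste0("laws_", cls, c("_frequency", "_density"))))
  }
  out
}

## Haar wavelet subband entropies --------------------------------------------

# Single-level 2-D Haar DWT with orthonormal filters; odd trailing
# rows/columns are truncated.
haar_dwt2 <- function(m) {
  h <- nrow(m) %/% 2L * 2L
  w <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  odd_r <- seq(1L, h, by = 2L); evn_r <- odd_r + 1L
  lo_r <- (m[odd_r, , drop = FALSE] + m[evn_r, , drop = FALSE]) / sqrt(2)
  hi_r <- (m[odd_r, , drop = FALSE] - m[evn_r, , drop = FALSE]) / sqrt(2)
  odd_c <- seq(1L, w, by = 2L); evn_c <- odd_c + 1L
  list(
    LL = (lo_r[, odd_c, drop = FALSE] + lo_r[, evn_c, drop = FALSE]) / sqrt(2),
    LH = (lo_r[, odd_c, drop = FALSE] - lo_r[, evn_c, drop = FALSE]) / sqrt(2),
    HL = (hi_r[, odd_c, drop = FALSE] + hi_r[, evn_c, drop = FALSE]) / sqrt(2),
    HH = (hi_r[, odd_c, drop = FALSE] - hi_r[, evn_c, drop = FALSE]) / sqrt(2)
  )
}

# Shannon entropy (nats) of the normalized squared-coefficient distribution.
subband_entropy <- function(coefs) {
  e <- as.numeric(coefs)^2
  tot <- sum(e)
  if (tot <= 0) return(0)
  p <- e[e > 0] / tot
  -sum(p * log(p))
}

#' Two-level Haar wavelet subband entropies
#'
#' Applies the 2-D Haar wavelet transform, then applies it again to each
#' of the four level-1 subbands, and computes the Shannon entropy (natural
#' log) of the normalized squared-coefficient distribution of every
#' subband: 4 level-1 + 16 level-2 = 20 features, named `wl1_LL`, ...,
#' `wl2_LL_HH`, ...
#'
#' @param image Integer intensity matrix with both dimensions at least 4.
#' @return Named numeric vector of 20 entropies.
#' @export
wavelet_entropies <- function(image) {
  check_image(image)
  if (nrow(image) < 4L || ncol(image) < 4L)
    stop_validation("wavelet_entropies needs at least a 4x4 image")
  l1 <- haar_dwt2(image)
  out <- stats::setNames(vapply(l1, subband_entropy, numeric(1L)),
                         paste0("wl1_", names(l1)))
  for (parent in names(l1)) {
    l2 <- haar_dwt2(l1[[parent]])
    out <- c(out, stats::setNames(
      vapply(l2, subband_entropy, numeric(1L)),
      paste0("wl2_", parent, "_", names(l2))))
  }
  out
}
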