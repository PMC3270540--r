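#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

## input checking helpers ----------------------------------------------------

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_image <- function(image, min_dim = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_validation("image must be a numeric matrix")
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop_validation("image must be at least %dx%d, got %dx%d",
                    min_dim, min_dim, nrow(image), ncol(image))
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop_validation("image values must lie in [0, 255]")
  invisible(image)
}

## replicate-padded 2-D convolution ------------------------------------------

# Pad a matrix by replicating its border rows/columns.
pad_replicate <- function(m, top, bottom = top, left = top, right = top) {
  ri <- c(rep(1L, top), seq_len(nrow(m)), rep(nrow(m), bottom))
  ci <- c(rep(1L, left), seq_len(ncol(m)), rep(ncol(m), right))
  m[ri, ci, drop = FALSE]
}

# Correlation-style 2-D filtering with edge replication: each output pixel is
# sum(kernel * neighborhood).  Kernel dimensions must be odd.
filter2_replicate <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  ry <- (kh - 1L) %/% 2L
  rx <- (kw - 1L) %/% 2L
  p <- pad_replicate(m, top = ry, bottom = ry, left = rx, right = rx)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kernel[i, j] == 0) next
      out <- out + kernel[i, j] * p[i:(i + h - 1L), j:(j + w - 1L)]
    }
  }
  out
}
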