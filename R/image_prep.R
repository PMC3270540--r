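## Image loading, ROI extraction, denoising and grey-level quantization.
##
## Images are plain integer matrices with values in [0, 255], indexed
## [row, col] with the origin at the top-left corner (row = y, col = x,
## both 0-based in the user-facing ROI coordinates).

#' Load a greyscale image
#'
#' Reads an 8-bit PNG, TIFF or BMP file into an integer intensity matrix.
#' RGB input is collapsed to luminance (0.299 R + 0.587 G + 0.114 B) and
#' rounded; an alpha channel, if present, is ignored.
#'
#' @param path Path to a PNG, TIFF or BMP file.
#' @return An integer matrix (height x width) with values in `[0, 255]`.
#' @export
#' @examples
#' img <- matrix(0L, 10, 10)
#' f <- tempfile(fileext = ".png")
#' png::writePNG(img / 255, f)
#' all(load_image(f) == 0L)
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_validation("path must be a single file path")
  if (!file.exists(path))
    stop(sprintf("cannot read image file '%s': no such file", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    bmp  = read_bmp(path),
    stop(sprintf("cannot read image file '%s': unsupported extension '%s'",
                 path, ext), call. = FALSE)
  )
  if (is.matrix(arr)) {
    img <- round(arr * 255)
  } else if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      img <- round(255 * (0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] +
                            0.114 * arr[, , 3L]))
    } else {
      img <- round(255 * arr[, , 1L])
    }
  } else {
    stop(sprintf("cannot interpret image file '%s'", path), call. = FALSE)
  }
  if (length(img) == 0L)
    stop_validation("image '%s' has zero area", path)
  storage.mode(img) <- "integer"
  check_image(img)
  img
}

# Minimal decoder for uncompressed 8-bit palette / 24-bit BMP files.
# Returns values scaled to [0, 1] to match png::readPNG conventions.
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop(sprintf("cannot read image file '%s': not a BMP", path),
         call. = FALSE)
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  data_off <- u32(10L)
  width  <- u32(18L)
  height <- u32(22L)
  bpp    <- u16(28L)
  compression <- u32(30L)
  if (compression != 0L)
    stop(sprintf("BMP '%s': only uncompressed files are supported", path),
         call. = FALSE)
  if (width == 0L || height == 0L)
    stop_validation("image '%s' has zero area", path)
  if (bpp == 8L) {
    hdr_size <- u32(14L)
    n_colors <- u32(46L)
    if (n_colors == 0L) n_colors <- 256L
    pal_off <- 14L + hdr_size
    # palette entries are BGRA quads
    pal <- matrix(as.integer(raw[pal_off + seq_len(4L * n_colors)]),
                  nrow = 4L)
    grey <- round(0.299 * pal[3L, ] + 0.587 * pal[2L, ] + 0.114 * pal[1L, ])
    stride <- ((width + 3L) %/% 4L) * 4L
    out <- matrix(0, height, width)
    for (r in seq_len(height)) {
      row_raw <- raw[data_off + (r - 1L) * stride + seq_len(width)]
      out[height - r + 1L, ] <- grey[as.integer(row_raw) + 1L]
    }
  } else if (bpp == 24L) {
    stride <- ((3L * width + 3L) %/% 4L) * 4L
    out <- matrix(0, height, width)
    for (r in seq_len(height)) {
      row_raw <- as.integer(raw[data_off + (r - 1L) * stride +
                                  seq_len(3L * width)])
      b <- row_raw[seq(1L, by = 3L, length.out = width)]
      g <- row_raw[seq(2L, by = 3L, length.out = width)]
      rr <- row_raw[seq(3L, by = 3L, length.out = width)]
      out[height - r + 1L, ] <- round(0.299 * rr + 0.587 * g + 0.114 * b)
    }
  } else {
    stop(sprintf("BMP '%s': %d bits per pixel not supported", path, bpp),
         call. = FALSE)
  }
  out / 255
}

#' Extract a rectangular region of interest
#'
#' Coordinates are 0-based with the origin at the top-left corner; `x0`
#' indexes columns and `y0` rows.
#'
#' @param image Integer intensity matrix.
#' @param x0,y0 0-based top-left corner of the ROI.
#' @param width,height ROI size in pixels (default 50, the standard ROI
#'   size for tissue analysis).
#' @return The `height` x `width` sub-image.
#' @export
extract_roi <- function(image, x0, y0, width = 50L, height = 50L) {
  check_image(image)
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L)
    stop_validation("ROI size must be positive, got %dx%d", width, height)
  if (x0 < 0L || y0 < 0L ||
      x0 + width > ncol(image) || y0 + height > nrow(image))
    stop_validation(
      "ROI (x0=%d, y0=%d, %dx%d) exceeds image bounds (%dx%d)",
      x0, y0, width, height, ncol(image), nrow(image))
  image[y0 + seq_len(height), x0 + seq_len(width), drop = FALSE]
}

#' Denoise with an averaging filter
#'
#' Replaces every pixel by the rounded arithmetic mean of its
#' `kernel` x `kernel` neighborhood, with edge replication at the borders.
#'
#' @param image Integer intensity matrix.
#' @param kernel Odd window size (default 3).
#' @return Filtered integer matrix, same dimensions.
#' @export
mean_filter <- function(image, kernel = 3L) {
  check_image(image)
  kernel <- as.integer(kernel)
  if (length(kernel) != 1L || is.na(kernel) || kernel < 1L ||
      kernel %% 2L == 0L)
    stop_validation("kernel must be an odd positive integer, got %s",
                    deparse(kernel))
  if (kernel == 1L) return(image)
  k <- matrix(1 / kernel^2, kernel, kernel)
  out <- round(filter2_replicate(image, k))
  storage.mode(out) <- "integer"
  out
}

#' Quantize grey levels
#'
#' Uniform binning of `[0, 255]` intensities into `L` levels:
#' `label = floor(value * L / 256)`.
#'
#' @param image Integer intensity matrix.
#' @param L Number of grey levels, `2 <= L <= 256`.
#' @return A `quantized_map`: list with integer matrix `labels` in
#'   `[0, L-1]`, level count `L`, and logical matrix `valid_mask`.
#' @export
quantize <- function(image, L = 256L) {
  check_image(image)
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 2L || L > 256L)
    stop_validation("L must be in [2, 256], got %s", deparse(L))
  labels <- matrix(as.integer(floor(as.numeric(image) * L / 256)),
                   nrow(image), ncol(image))
  quantized_map(labels, L)
}

#' Construct a quantized label map
#'
#' Low-level constructor used both for grey-level maps and for
#' edge-orientation maps (where `valid_mask` marks edge pixels).
#'
#' @param labels Integer matrix with values in `[0, L-1]` (masked cells may
#'   hold `NA`).
#' @param L Number of levels.
#' @param valid_mask Logical matrix, same shape; defaults to all-`TRUE`.
#' @return A `quantized_map` object.
#' @export
quantized_map <- function(labels, L, valid_mask = NULL) {
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, nrow(labels), ncol(labels))
  stopifnot(is.matrix(labels), is.matrix(valid_mask),
            all(dim(labels) == dim(valid_mask)))
  L <- as.integer(L)
  if (L < 2L || L > 256L)
    stop_validation("L must be in [2, 256], got %d", L)
  lv <- labels[valid_mask]
  if (length(lv) && (anyNA(lv) || min(lv) < 0L || max(lv) >= L))
    stop_validation("unmasked labels must lie in [0, L-1]")
  structure(list(labels = labels, L = L, valid_mask = valid_mask),
            class = "quantized_map")
}

#' Read a ROI manifest
#'
#' The manifest is a CSV with header
#' `image_path,x0,y0,width,height,class_label`.  Relative image paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with the manifest columns.
#' @export
read_roi_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read manifest '%s': no such file", path),
         call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "x0", "y0", "width", "height", "class_label")
  if (!all(need %in% names(m)))
    stop_validation("manifest '%s' must have columns %s", path,
                    paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$image_path)
  m$image_path[rel] <- file.path(dirname(path), m$image_path[rel])
  m
}
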