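#' CLAHE radiograph preprocessing
#'
#' Contrast-limited adaptive histogram equalization, the enhancement step
#' applied to hand radiographs in place of background segmentation. The
#' defaults are a clip limit of 2.0 on an 8x8 tile grid. Input must be a
#' single-channel image; the output has the same shape and value range
#' convention as the input (images on a 0-255 or 0-65535 scale are
#' rescaled internally and mapped back).
#'
#' @param image Numeric matrix (grayscale) or single-channel
#'   `EBImage::Image`.
#' @param clip_limit Contrast clip limit; default 2.0.
#' @param tile_grid Integer pair, tiles in x and y; default `c(8, 8)`.
#' @return Enhanced image of the same class and shape as the input.
#' @export
preprocess_image <- function(image, clip_limit = 2.0, tile_grid = c(8, 8)) {
  tile_grid <- rep_len(as.integer(tile_grid), 2L)
  was_image <- inherits(image, "Image")
  m <- if (was_image) EBImage::imageData(image) else image
  if (length(dim(m)) > 2L && any(dim(m)[-(1:2)] > 1L)) {
    stop("image error: CLAHE expects a single-channel image", call. = FALSE)
  }
  m <- array(m, dim = dim(m)[1:2])
  if (any(dim(m) < tile_grid)) {
    stop("image error: image smaller than the tile grid", call. = FALSE)
  }
  scale <- if (max(m) > 1) {
    if (max(m) > 255) 65535 else 255
  } else 1
  if (max(m) == min(m)) {
    # constant image: nothing to equalize
    return(if (was_image) EBImage::Image(m, colormode = "Grayscale") else m)
  }
  x <- EBImage::Image(m / scale, colormode = "Grayscale")
  y <- EBImage::clahe(x, nx = tile_grid[1], ny = tile_grid[2],
                      limit = clip_limit, keep.range = TRUE)
  out <- EBImage::imageData(y) * scale
  if (was_image) EBImage::Image(out, colormode = "Grayscale") else out
}

#' Resize to the detector input size and normalize to \[0, 1\]
#'
#' Stretches the image to a `target_size` x `target_size` square (the
#' detector-family presets are 640 for YOLOv5-style inputs and 416 for
#' PP-PicoDet / NanoDet-style inputs) and scales pixel values into
#' \[0, 1\].
#'
#' @param image Numeric matrix or single-channel `EBImage::Image`.
#' @param target_size Output side in pixels; 640 or 416 presets, any
#'   positive integer accepted.
#' @return `target_size` x `target_size` numeric matrix with values in
#'   \[0, 1\].
#' @export
resize_normalize <- function(image, target_size = 640) {
  stopifnot(length(target_size) == 1L, target_size >= 1)
  m <- if (inherits(image, "Image")) EBImage::imageData(image) else image
  if (length(dim(m)) > 2L && any(dim(m)[-(1:2)] > 1L)) {
    stop("image error: expected a single-channel image", call. = FALSE)
  }
  m <- array(m, dim = dim(m)[1:2])
  if (any(dim(m) == 0L)) stop("image error: zero-size image", call. = FALSE)
  scale <- if (max(m) > 1) {
    if (max(m) > 255) 65535 else 255
  } else 1
  x <- EBImage::Image(m / scale, colormode = "Grayscale")
  y <- EBImage::resize(x, w = target_size, h = target_size)
  out <- EBImage::imageData(y)
  pmin(pmax(array(out, dim = dim(out)[1:2]), 0), 1)
}
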