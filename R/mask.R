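#' Foreground masks
#'
#' A foreground mask is an integer matrix `[H, W]` partitioning an image into
#' the inner region (1 = leaves and trunk, where pasted targets may land)
#' and the outer region (0 = background removed by segmentation). The outer
#' region's pixel count is the denominator of the outer-overlap rate used by
#' the copy-paste placement constraint.
#'
#' @param values a numeric or logical matrix; non-zero entries become inner.
#' @return An integer 0/1 matrix.
#' @export
foreground_mask <- function(values) {
  if (!is.matrix(values)) stopf("mask values must be a matrix")
  m <- matrix(as.integer(values != 0), nrow(values), ncol(values))
  m
}

mask_outer_area <- function(mask) sum(mask == 0L)
mask_inner_area <- function(mask) sum(mask != 0L)

validate_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  if (!all(mask %in% c(0L, 1L))) stopf("mask must be binary (0/1)")
  if (!is.null(image) &&
      (nrow(mask) != dim(image)[[1]] || ncol(mask) != dim(image)[[2]]))
    stopf("mask dimensions (%dx%d) do not match the image (%dx%d)",
          ncol(mask), nrow(mask), dim(image)[[2]], dim(image)[[1]])
  invisible(mask)
}

#' @rdname foreground_mask
#' @param path PNG file path; pixels with value >= 0.5 are inner.
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  foreground_mask(px >= 0.5)
}

#' @rdname foreground_mask
#' @param mask a 0/1 mask matrix.
#' @export
write_mask_png <- function(mask, path) {
  validate_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Segment the foreground (leaves and trunk) of a scene
#'
#' Splits an image into the inner region that can host pasted targets and
#' the outer background. Segmentation is a pluggable interface: a
#' user-supplied `mask` always wins; otherwise `segmenter` (any function
#' mapping an image to a 0/1 matrix) is called. The default segmenter is a
#' deterministic colour rule: a pixel is inner iff its excess-green index
#' `2G - R - B` exceeds 0.05 (vegetation) or it is a bright brown-ish pixel
#' (`R >= G >= B`, `R > 0.2`, `R - B > 0.1`; trunk and branches). A uniform
#' green image is therefore all-inner and a black image all-outer.
#'
#' @param image pixel array `[H, W, 3]` with values in `[0, 1]`.
#' @param mask optional precomputed mask; returned as-is after validation.
#' @param segmenter function `image -> mask` used when `mask` is `NULL`.
#' @return A 0/1 integer matrix of the image's height and width. Warns if the
#'   result is all-outer (no paste location exists).
#' @export
segment_foreground <- function(image, mask = NULL,
                               segmenter = threshold_segmenter) {
  if (is.null(dim(image)) || any(dim(image)[1:2] == 0L))
    stopf("cannot segment an empty image")
  out <- if (!is.null(mask)) {
    validate_mask(foreground_mask(mask), image)
  } else {
    foreground_mask(segmenter(image))
  }
  validate_mask(out, image)
  if (all(out == 0L))
    warnf("segmentation produced an all-background mask; no paste locations exist")
  out
}

#' @rdname segment_foreground
#' @export
threshold_segmenter <- function(image) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  green <- (2 * g - r - b) > 0.05
  brown <- (r >= g) & (g >= b) & (r > 0.2) & ((r - b) > 0.1)
  foreground_mask(green | brown)
}
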