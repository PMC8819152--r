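#' Nine-block tiling grid
#'
#' Partitions a `width x height` frame into a `rows x cols` grid of disjoint
#' tiles whose union is the full frame. Non-divisible dimensions are
#' floor-divided, with the last row/column absorbing the remainder.
#'
#' @param width,height parent image dimensions in pixels.
#' @param rows,cols grid shape; the high-resolution pipeline uses 3 x 3
#'   (nine blocks).
#' @return A list of class `tile_grid` with the parent size and a list of
#'   tile boxes in row-major order.
#' @export
tile_grid <- function(width, height, rows = 3L, cols = 3L) {
  if (width < cols || height < rows)
    stopf("image (%dx%d) is smaller than the %dx%d grid", width, height, rows, cols)
  xs <- c(seq(0L, by = width %/% cols, length.out = cols), width)
  ys <- c(seq(0L, by = height %/% rows, length.out = rows), height)
  tiles <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols))
    tiles[[(r - 1L) * cols + c]] <-
      c(x0 = xs[[c]], y0 = ys[[r]], x1 = xs[[c + 1L]], y1 = ys[[r + 1L]])
  structure(list(width = width, height = height, rows = rows, cols = cols,
                 tiles = tiles), class = "tile_grid")
}

#' Crop a high-resolution image into tiles with annotation remapping
#'
#' High-resolution frames lose small targets when compressed to network
#' input size, so they are cropped into nine blocks before training. Parent
#' boxes are translated into tile coordinates and clipped to the tile; a
#' clipped box is kept iff it retains positive area and its clipped area is
#' at least `keep_fraction` of the original area (targets mostly outside a
#' tile are dropped rather than kept as slivers).
#'
#' @param image pixel array `[H, W, 3]` (or `[H, W]`).
#' @param anns an [annotations()] data frame in parent coordinates.
#' @param grid a [tile_grid()]; defaults to 3 x 3 over the image.
#' @param keep_fraction minimum retained area fraction in `[0, 1]`.
#' @return A list of `rows * cols` elements in row-major order, each with
#'   `image` (tile pixels), `annotations` (tile coordinates) and `offset`
#'   (tile origin in the parent frame).
#' @export
tile_image <- function(image, anns = annotations(), grid = NULL,
                       keep_fraction = 0.5) {
  h <- dim(image)[[1]]; w <- dim(image)[[2]]
  if (is.null(grid)) grid <- tile_grid(w, h)
  if (grid$width != w || grid$height != h)
    stopf("grid was built for %dx%d but the image is %dx%d",
          grid$width, grid$height, w, h)
  validate_annotations(anns, w, h)
  lapply(grid$tiles, function(tb) {
    timg <- if (length(dim(image)) == 3L)
      image[(tb[[2]] + 1):tb[[4]], (tb[[1]] + 1):tb[[3]], , drop = FALSE]
    else
      image[(tb[[2]] + 1):tb[[4]], (tb[[1]] + 1):tb[[3]], drop = FALSE]
    keep <- anns[0, , drop = FALSE]
    for (i in seq_len(nrow(anns))) {
      b <- ann_box(anns, i)
      cl <- clip_box(c(b[1] - tb[[1]], b[2] - tb[[2]],
                       b[3] - tb[[1]], b[4] - tb[[2]]),
                     tb[[3]] - tb[[1]], tb[[4]] - tb[[2]])
      if (is.null(cl)) next
      if ((cl[[3]] - cl[[1]]) * (cl[[4]] - cl[[2]]) <
          keep_fraction * box_area(b)) next
      row <- anns[i, , drop = FALSE]
      row[, c("x0", "y0", "x1", "y1")] <- as.list(cl)
      keep <- rbind(keep, row)
    }
    rownames(keep) <- NULL
    list(image = timg, annotations = keep,
         offset = c(x = tb[[1]], y = tb[[2]]))
  })
}

#' Reassemble tiles into the parent image
#'
#' Inverse of [tile_image()] for the pixel content; used to check that
#' tiling partitions the frame exactly.
#'
#' @param tiles output of [tile_image()].
#' @param grid the [tile_grid()] used to produce them.
#' @return The parent pixel array.
#' @export
reassemble_tiles <- function(tiles, grid) {
  nd <- length(dim(tiles[[1]]$image))
  out <- if (nd == 3L)
    array(0, c(grid$height, grid$width, dim(tiles[[1]]$image)[[3]]))
  else
    matrix(0, grid$height, grid$width)
  for (i in seq_along(grid$tiles)) {
    tb <- grid$tiles[[i]]
    if (nd == 3L)
      out[(tb[[2]] + 1):tb[[4]], (tb[[1]] + 1):tb[[3]], ] <- tiles[[i]]$image
    else
      out[(tb[[2]] + 1):tb[[4]], (tb[[1]] + 1):tb[[3]]] <- tiles[[i]]$image
  }
  out
}

#' Multiscale training scales
#'
#' @param scales list of `(long-side cap, short-side target)` pairs; the
#'   defaults are the two training scales `(1500, 1000)` and `(1333, 800)`.
#' @return A list of class `scale_spec`.
#' @export
scale_spec <- function(scales = list(c(1500, 1000), c(1333, 800))) {
  if (!length(scales)) stopf("scale spec must contain at least one pair")
  for (s in scales)
    if (length(s) != 2L || s[[1]] < s[[2]] || s[[2]] <= 0)
      stopf("each scale pair must satisfy long >= short > 0")
  structure(list(scales = scales), class = "scale_spec")
}

#' Randomly-chosen multiscale resize
#'
#' Picks one `(long cap, short target)` pair uniformly at random, then
#' resizes so the short side equals the short target — unless that would
#' push the long side past the cap, in which case the long side is set to
#' the cap. Aspect ratio is preserved; boxes are scaled by the same factor.
#'
#' @param image pixel array `[H, W, 3]`.
#' @param anns an [annotations()] data frame.
#' @param spec a [scale_spec()].
#' @param seed optional RNG seed.
#' @return A list with `image` (bilinearly resized), `annotations` (scaled,
#'   fractional coordinates allowed), `scale` (the chosen pair) and
#'   `factor` (the applied scale factor).
#' @export
multiscale_resize <- function(image, anns = annotations(), spec = scale_spec(),
                              seed = NULL) {
  stopifnot(inherits(spec, "scale_spec"))
  h <- dim(image)[[1]]; w <- dim(image)[[2]]
  validate_annotations(anns, w, h)
  chosen <- with_seed_or_current(seed,
    spec$scales[[sample.int(length(spec$scales), 1L)]])
  long_cap <- chosen[[1]]; short_target <- chosen[[2]]
  short_side <- min(w, h); long_side <- max(w, h)
  f <- short_target / short_side
  if (round_half_up(long_side * f) > long_cap) f <- long_cap / long_side
  new_w <- as.integer(round_half_up(w * f))
  new_h <- as.integer(round_half_up(h * f))
  resized <- resize_image(image, new_w, new_h)
  out_ann <- anns
  out_ann[, c("x0", "y0", "x1", "y1")] <- anns[, c("x0", "y0", "x1", "y1")] * f
  list(image = resized, annotations = out_ann, scale = chosen, factor = f)
}

# bilinear resize via EBImage (stores images x-major, so transpose in/out)
resize_image <- function(image, new_w, new_h) {
  img_xy <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img_xy, w = new_w, h = new_h)
  aperm(as.array(out), c(2, 1, 3))
}

#' Random right-angle rotation
#'
#' With probability `p` rotates the image by an angle drawn uniformly from
#' 90, 180 or 270 degrees (clockwise) and remaps boxes exactly; right
#' angles keep boxes axis-aligned so the remap is lossless. Otherwise the
#' input is returned unchanged.
#'
#' @param image pixel array `[H, W, 3]` or matrix.
#' @param anns an [annotations()] data frame.
#' @param p rotation probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return A list with `image`, `annotations`, `applied` (logical) and
#'   `angle` (0, 90, 180 or 270).
#' @export
random_rotate <- function(image, anns = annotations(), p = 0.5, seed = NULL) {
  if (!is.numeric(p) || p < 0 || p > 1) stopf("p must lie in [0, 1]")
  h <- dim(image)[[1]]; w <- dim(image)[[2]]
  validate_annotations(anns, w, h)
  draw <- with_seed_or_current(seed,
    list(u = runif(1), angle = sample(c(90L, 180L, 270L), 1L)))
  if (draw$u >= p)
    return(list(image = image, annotations = anns, applied = FALSE, angle = 0L))
  k <- draw$angle %/% 90L
  out_img <- image
  out_ann <- anns
  for (i in seq_len(k)) {
    out_ann <- rotate_annotations_90cw(out_ann, dim(out_img)[[2]], dim(out_img)[[1]])
    out_img <- rotate_image_90cw(out_img)
  }
  list(image = out_img, annotations = out_ann, applied = TRUE, angle = draw$angle)
}

#' @rdname random_rotate
#' @export
rotate_image_90cw <- function(image) {
  h <- dim(image)[[1]]
  if (length(dim(image)) == 3L)
    aperm(image[h:1, , , drop = FALSE], c(2, 1, 3))
  else
    t(image[h:1, , drop = FALSE])
}

# pixel (x, y) in a WxH frame maps to (H - 1 - y, x) under 90-degree
# clockwise rotation; in half-open coordinates a box maps as below
rotate_annotations_90cw <- function(anns, width, height) {
  out <- anns
  out$x0 <- height - anns$y1
  out$y0 <- anns$x0
  out$x1 <- height - anns$y0
  out$y1 <- anns$x1
  out
}
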