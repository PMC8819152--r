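#' Axis-aligned bounding boxes
#'
#' Boxes are length-4 numeric vectors `c(x0, y0, x1, y1)` in 0-based,
#' half-open pixel coordinates: pixel column `x` belongs to the box iff
#' `x0 <= x < x1`, and likewise for rows. A valid box has positive extent on
#' both axes, so its area `(x1 - x0) * (y1 - y0)` is strictly positive.
#' Annotation boxes are integer-valued; boxes produced inside the detector
#' (regression outputs, scaled boxes) may be fractional.
#'
#' @param x0,y0,x1,y1 box edges in pixels.
#' @return A named numeric vector of length 4.
#' @examples
#' b <- box(0, 0, 10, 10)
#' box_area(b)
#' @export
box <- function(x0, y0, x1, y1) {
  b <- c(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
  validate_box(b)
  b
}

validate_box <- function(b) {
  if (length(b) != 4L || !is.numeric(b) || any(!is.finite(b)))
    stopf("a box must be 4 finite numbers (x0, y0, x1, y1)")
  if (b[[3]] <= b[[1]] || b[[4]] <= b[[2]])
    stopf("invalid box (%s): x1 > x0 and y1 > y0 required",
          paste(format(b), collapse = ", "))
  invisible(b)
}

#' @rdname box
#' @param b a box.
#' @export
box_area <- function(b) {
  validate_box(b)
  (b[[3]] - b[[1]]) * (b[[4]] - b[[2]])
}

#' Intersection area and IoU of two boxes
#'
#' `box_intersection_area()` returns the area of the overlap of two boxes in
#' pixels (0 for disjoint boxes; half-open coordinates make edge-adjacent
#' boxes disjoint). `box_iou()` returns intersection over union, which is 1
#' exactly for identical boxes and 0 exactly for disjoint ones.
#'
#' @param a,b valid boxes (see [box()]).
#' @return A single non-negative number.
#' @examples
#' box_intersection_area(box(0, 0, 10, 10), box(5, 5, 15, 15)) # 25
#' box_iou(box(0, 0, 10, 10), box(5, 5, 15, 15))              # 25 / 175
#' @export
box_intersection_area <- function(a, b) {
  validate_box(a); validate_box(b)
  w <- min(a[[3]], b[[3]]) - max(a[[1]], b[[1]])
  h <- min(a[[4]], b[[4]]) - max(a[[2]], b[[2]])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' @rdname box_intersection_area
#' @export
box_iou <- function(a, b) {
  inter <- box_intersection_area(a, b)
  inter / (box_area(a) + box_area(b) - inter)
}

# IoU of one box against each row of an n x 4 matrix; vectorised hot path for
# matching and NMS.
box_iou_many <- function(b, m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 4L)
  if (nrow(m) == 0L) return(numeric(0))
  w <- pmin(b[[3]], m[, 3]) - pmax(b[[1]], m[, 1])
  h <- pmin(b[[4]], m[, 4]) - pmax(b[[2]], m[, 2])
  inter <- pmax(w, 0) * pmax(h, 0)
  areas <- (m[, 3] - m[, 1]) * (m[, 4] - m[, 2])
  inter / (box_area(b) + areas - inter)
}

# clip a box to [0, width) x [0, height); may return NULL if nothing remains
clip_box <- function(b, width, height) {
  x0 <- max(b[[1]], 0); y0 <- max(b[[2]], 0)
  x1 <- min(b[[3]], width); y1 <- min(b[[4]], height)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

box_in_bounds <- function(b, width, height) {
  b[[1]] >= 0 && b[[2]] >= 0 && b[[3]] <= width && b[[4]] <= height
}

#' Annotation tables
#'
#' Annotations are plain data frames with one row per labelled target and
#' columns `x0, y0, x1, y1` (0-based half-open box, see [box()]), `class_id`
#' (integer category: 0 = citrus psyllid, 1 = fruit fly by default) and
#' `source` (`"original"` for field labels, `"pasted"` for boxes added by
#' copy-paste augmentation).
#'
#' @param x0,y0,x1,y1 numeric vectors of box edges.
#' @param class_id integer vector of category ids.
#' @param source character vector, `"original"` or `"pasted"`.
#' @return A data frame with the columns above.
#' @export
annotations <- function(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                        y1 = numeric(), class_id = integer(),
                        source = rep("original", length(x0))) {
  ann <- data.frame(x0 = as.numeric(x0), y0 = as.numeric(y0),
                    x1 = as.numeric(x1), y1 = as.numeric(y1),
                    class_id = as.integer(class_id),
                    source = as.character(source),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann, width = NULL, height = NULL,
                                 categories = NULL) {
  need <- c("x0", "y0", "x1", "y1", "class_id", "source")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    stopf("annotation table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(ann) == 0L) return(invisible(ann))
  bad <- which(ann$x1 <= ann$x0 | ann$y1 <= ann$y0)
  if (length(bad))
    stopf("annotation %d has non-positive extent", bad[[1]])
  if (!is.null(width)) {
    out <- which(ann$x0 < 0 | ann$y0 < 0 | ann$x1 > width | ann$y1 > height)
    if (length(out))
      stopf("annotation %d lies outside the %dx%d image bounds",
            out[[1]], width, height)
  }
  if (!is.null(categories)) {
    unknown <- setdiff(unique(ann$class_id), as.integer(names(categories)))
    if (length(unknown))
      stopf("annotation uses undeclared category id %d", unknown[[1]])
  }
  if (!all(ann$source %in% c("original", "pasted")))
    stopf("annotation source must be 'original' or 'pasted'")
  invisible(ann)
}

ann_boxes <- function(ann) {
  if (nrow(ann) == 0L) return(matrix(numeric(), ncol = 4L))
  as.matrix(ann[, c("x0", "y0", "x1", "y1")])
}

ann_box <- function(ann, i) {
  c(x0 = ann$x0[[i]], y0 = ann$y0[[i]], x1 = ann$x1[[i]], y1 = ann$y1[[i]])
}
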