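#' Detection datasets
#'
#' A `detection_dataset` bundles image records with their annotations and an
#' id-to-name category map. Each record is a list with fields:
#' \describe{
#'   \item{id}{integer record id, unique within the dataset.}
#'   \item{file_name}{image file name (may be `NA` for in-memory records).}
#'   \item{width, height}{image dimensions in pixels.}
#'   \item{annotations}{an [annotations()] data frame.}
#'   \item{image}{optional in-memory pixel array `[H, W, 3]` in `[0, 1]`.}
#'   \item{mask}{optional foreground mask, see [foreground_mask()].}
#'   \item{mask_file}{optional mask file name.}
#' }
#'
#' @param records list of records as described above.
#' @param categories named character vector mapping category id (name of the
#'   element, e.g. `"0"`) to category name. Defaults to the two pest classes.
#' @return An object of class `detection_dataset`.
#' @export
detection_dataset <- function(records = list(),
                              categories = c("0" = "psyllid", "1" = "fruit_fly")) {
  ds <- structure(list(records = records, categories = categories),
                  class = "detection_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  ids <- vapply(ds$records, function(r) as.integer(r$id), integer(1))
  if (anyDuplicated(ids))
    stopf("duplicate record id %d", ids[duplicated(ids)][[1]])
  for (r in ds$records) {
    if (is.null(r$width) || is.null(r$height))
      stopf("record %s has no image dimensions", format(r$id))
    validate_annotations(r$annotations, r$width, r$height, ds$categories)
  }
  invisible(ds)
}

#' @export
print.detection_dataset <- function(x, ...) {
  n_ann <- sum(vapply(x$records, function(r) nrow(r$annotations), integer(1)))
  cat(sprintf("<detection_dataset> %d record(s), %d annotation(s), classes: %s\n",
              length(x$records), n_ann,
              paste(sprintf("%s=%s", names(x$categories), x$categories),
                    collapse = ", ")))
  invisible(x)
}

#' Number of original (field-labelled) samples in a record
#'
#' Counts annotations with `source == "original"`; this is the sample count
#' `n` that the copy-paste overlap-rate denominator is built from.
#'
#' @param record a dataset record.
#' @return Integer count.
#' @export
n_original_samples <- function(record) {
  sum(record$annotations$source == "original")
}

#' Read and write COCO-style annotation JSON
#'
#' The on-disk dialect is COCO: a JSON object with `images` (id, file_name,
#' width, height), `annotations` (id, image_id, category_id, bbox as
#' `[x, y, w, h]`) and `categories` (id, name). Internally boxes are 0-based
#' half-open `(x0, y0, x1, y1)`; the conversion `x1 = x + w` is lossless for
#' integer coordinates, so write followed by read is the identity on integer
#' datasets. Pasted-source annotations carry a non-standard `"source"` field
#' that round-trips; absent fields default to `"original"`.
#'
#' @param path JSON file path.
#' @return `read_coco()` returns a [detection_dataset()].
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("images", "annotations", "categories"))
    if (is.null(j[[key]]))
      stopf("COCO file %s is missing the '%s' list", path, key)

  cats <- character()
  for (ct in j$categories) {
    if (is.null(ct$id) || is.null(ct$name))
      stopf("category record without id/name in %s", path)
    cats[as.character(ct$id)] <- ct$name
  }

  records <- list()
  for (im in j$images) {
    for (key in c("id", "width", "height"))
      if (is.null(im[[key]]))
        stopf("image record (file_name=%s) is missing '%s'",
              im$file_name %||% "?", key)
    records[[as.character(im$id)]] <- list(
      id = as.integer(im$id),
      file_name = im$file_name %||% NA_character_,
      width = as.integer(im$width), height = as.integer(im$height),
      annotations = annotations(),
      mask_file = im$mask_file %||% NULL)
  }

  for (an in j$annotations) {
    for (key in c("image_id", "category_id", "bbox"))
      if (is.null(an[[key]]))
        stopf("annotation record id=%s is missing '%s'",
              format(an$id %||% NA), key)
    key <- as.character(an$image_id)
    if (is.null(records[[key]]))
      stopf("annotation id=%s references unknown image_id %s",
            format(an$id %||% NA), key)
    bb <- as.numeric(unlist(an$bbox))
    if (length(bb) != 4L || bb[[3]] <= 0 || bb[[4]] <= 0)
      stopf("annotation id=%s has a degenerate bbox [%s]",
            format(an$id %||% NA), paste(bb, collapse = ", "))
    rec <- records[[key]]
    rec$annotations <- rbind(rec$annotations, data.frame(
      x0 = bb[[1]], y0 = bb[[2]], x1 = bb[[1]] + bb[[3]], y1 = bb[[2]] + bb[[4]],
      class_id = as.integer(an$category_id),
      source = an$source %||% "original",
      stringsAsFactors = FALSE))
    records[[key]] <- rec
  }

  detection_dataset(unname(records), categories = cats)
}

#' @rdname read_coco
#' @param dataset a [detection_dataset()].
#' @export
write_coco <- function(dataset, path) {
  validate_dataset(dataset)
  images <- lapply(dataset$records, function(r) {
    im <- list(id = r$id, width = r$width, height = r$height,
               file_name = r$file_name)
    if (!is.null(r$mask_file)) im$mask_file <- r$mask_file
    im
  })
  anns <- list()
  aid <- 0L
  for (r in dataset$records) {
    a <- r$annotations
    if (nrow(a) == 0L) next
    for (i in seq_len(nrow(a))) {
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = r$id, category_id = a$class_id[[i]],
        bbox = c(a$x0[[i]], a$y0[[i]], a$x1[[i]] - a$x0[[i]],
                 a$y1[[i]] - a$y0[[i]]),
        area = (a$x1[[i]] - a$x0[[i]]) * (a$y1[[i]] - a$y0[[i]]),
        iscrowd = 0L, source = a$source[[i]])
    }
  }
  cats <- lapply(seq_along(dataset$categories), function(i) list(
    id = as.integer(names(dataset$categories)[[i]]),
    name = unname(dataset$categories[[i]])))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write COCO detection-results JSON
#'
#' Detection results use the standard COCO results dialect: a JSON array of
#' objects with `image_id`, `category_id`, `bbox` (`[x, y, w, h]`) and
#' `score`. Internally detections are a data frame with half-open box
#' columns plus `image_id`, `class_id` and `score`.
#'
#' @param path JSON file path.
#' @return `read_detections()` returns a data frame.
#' @export
read_detections <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(j) == 0L)
    return(data.frame(image_id = integer(), class_id = integer(),
                      x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), score = numeric()))
  do.call(rbind, lapply(j, function(d) {
    bb <- as.numeric(unlist(d$bbox))
    data.frame(image_id = as.integer(d$image_id),
               class_id = as.integer(d$category_id),
               x0 = bb[[1]], y0 = bb[[2]],
               x1 = bb[[1]] + bb[[3]], y1 = bb[[2]] + bb[[4]],
               score = as.numeric(d$score), stringsAsFactors = FALSE)
  }))
}

#' @rdname read_detections
#' @param detections detection data frame (columns `image_id`, `class_id`,
#'   `x0`, `y0`, `x1`, `y1`, `score`).
#' @export
write_detections <- function(detections, path) {
  out <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    list(image_id = d$image_id, category_id = d$class_id,
         bbox = c(d$x0, d$y0, d$x1 - d$x0, d$y1 - d$y0), score = d$score)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
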