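#' Overlap rates of a candidate paste location
#'
#' For a candidate copy box this computes, at pixel granularity, the two
#' overlap rates that govern constrained copy-paste placement:
#' \describe{
#'   \item{u_outer}{area of the copy box falling on the outer (background)
#'     region, divided by the total outer-region area. Zero exactly when the
#'     box lies entirely in the inner (leaf/trunk) region.}
#'   \item{u_samples}{area of the copy box intersecting the union of the
#'     existing sample boxes, divided by the summed area of those samples
#'     (`Area_samples = sum(area(sample_i))`). Zero exactly when the box is
#'     disjoint from every existing sample.}
#' }
#' A paste location is admissible iff both rates are exactly 0.
#'
#' @param copy_box candidate box, integer coordinates, within image bounds.
#' @param mask foreground mask (see [foreground_mask()]).
#' @param existing list of existing sample boxes (or an annotation data
#'   frame, whose boxes are used).
#' @return A list of class `overlap_report` with fields `u_outer`,
#'   `u_samples`, `area_copy`, `area_outer`, `area_samples`, and logical
#'   flags `outer_undefined` / `samples_undefined` set when the respective
#'   denominator is zero (the rate is then reported as 0).
#' @export
overlap_report <- function(copy_box, mask, existing = list()) {
  validate_box(copy_box)
  validate_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (!box_in_bounds(copy_box, w, h))
    stopf("copy box must lie within the %dx%d image", w, h)
  if (is.data.frame(existing))
    existing <- lapply(seq_len(nrow(existing)), function(i) ann_box(existing, i))

  area_copy <- box_area(copy_box)
  area_outer <- mask_outer_area(mask)

  sub <- mask[(copy_box[[2]] + 1):copy_box[[4]],
              (copy_box[[1]] + 1):copy_box[[3]], drop = FALSE]
  inter_outer <- sum(sub == 0L)

  area_samples <- if (length(existing)) sum(vapply(existing, box_area, numeric(1))) else 0
  inter_samples <- 0
  if (length(existing)) {
    # rasterise the union of existing boxes over the copy-box extent only
    cw <- copy_box[[3]] - copy_box[[1]]
    ch <- copy_box[[4]] - copy_box[[2]]
    hit <- matrix(FALSE, ch, cw)
    for (b in existing) {
      x0 <- max(b[[1]], copy_box[[1]]); x1 <- min(b[[3]], copy_box[[3]])
      y0 <- max(b[[2]], copy_box[[2]]); y1 <- min(b[[4]], copy_box[[4]])
      if (x1 > x0 && y1 > y0)
        hit[(y0 - copy_box[[2]] + 1):(y1 - copy_box[[2]]),
            (x0 - copy_box[[1]] + 1):(x1 - copy_box[[1]])] <- TRUE
    }
    inter_samples <- sum(hit)
  }

  structure(list(
    u_outer = if (area_outer > 0) inter_outer / area_outer else 0,
    u_samples = if (area_samples > 0) inter_samples / area_samples else 0,
    area_copy = area_copy,
    area_outer = area_outer,
    area_samples = area_samples,
    outer_undefined = area_outer == 0,
    samples_undefined = area_samples == 0
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> u_outer=%.4g u_samples=%.4g (copy=%g px, outer=%g px, samples=%g px)\n",
              x$u_outer, x$u_samples, x$area_copy, x$area_outer, x$area_samples))
  invisible(x)
}

# fast admissibility check equivalent to u_outer == 0 && u_samples == 0
paste_location_ok <- function(b, mask, existing_mat) {
  sub <- mask[(b[[2]] + 1):b[[4]], (b[[1]] + 1):b[[3]], drop = FALSE]
  if (any(sub == 0L)) return(FALSE)
  if (nrow(existing_mat)) {
    w <- pmin(b[[3]], existing_mat[, 3]) - pmax(b[[1]], existing_mat[, 1])
    h <- pmin(b[[4]], existing_mat[, 4]) - pmax(b[[2]], existing_mat[, 2])
    if (any(w > 0 & h > 0)) return(FALSE)
  }
  TRUE
}

#' Propose an admissible paste location by rejection sampling
#'
#' Draws candidate top-left corners uniformly over all positions keeping the
#' box inside the image, and accepts the first candidate whose outer-region
#' overlap and sample overlap are both exactly zero (the placement
#' constraint of segmentation-guided copy-paste).
#'
#' @param sample_box the source sample's box; only its width/height are used.
#' @param mask foreground mask.
#' @param existing list of boxes (or annotation data frame) the proposal
#'   must not intersect; pass originals plus previously pasted boxes.
#' @param max_attempts rejection-sampling budget (>= 1).
#' @param seed optional RNG seed; `NULL` uses the ambient RNG stream.
#' @return A list with `status` (`"ok"`, `"infeasible"` when the inner
#'   region has fewer pixels than the box needs — a guaranteed failure — or
#'   `"exhausted"` after `max_attempts` rejections), `box` (on success) and
#'   `attempts`.
#' @export
propose_paste_location <- function(sample_box, mask, existing = list(),
                                   max_attempts = 100L, seed = NULL) {
  validate_box(sample_box)
  validate_mask(mask)
  if (!is_count(max_attempts, 1L)) stopf("max_attempts must be >= 1")
  h <- nrow(mask); w <- ncol(mask)
  bw <- sample_box[[3]] - sample_box[[1]]
  bh <- sample_box[[4]] - sample_box[[2]]
  if (bw > w || bh > h)
    stopf("sample box (%gx%g) does not fit in the %dx%d image", bw, bh, w, h)
  if (mask_inner_area(mask) < bw * bh)
    return(list(status = "infeasible", box = NULL, attempts = 0L))
  if (is.data.frame(existing))
    existing <- lapply(seq_len(nrow(existing)), function(i) ann_box(existing, i))
  existing_mat <- if (length(existing)) do.call(rbind, existing) else
    matrix(numeric(), ncol = 4L)

  with_seed_or_current(seed, {
    result <- list(status = "exhausted", box = NULL, attempts = max_attempts)
    for (attempt in seq_len(max_attempts)) {
      x0 <- floor(runif(1, 0, w - bw + 1)); x0 <- min(x0, w - bw)
      y0 <- floor(runif(1, 0, h - bh + 1)); y0 <- min(y0, h - bh)
      cand <- c(x0 = x0, y0 = y0, x1 = x0 + bw, y1 = y0 + bh)
      if (paste_location_ok(cand, mask, existing_mat)) {
        result <- list(status = "ok", box = cand, attempts = attempt)
        break
      }
    }
    result
  })
}

#' Copy-paste configuration
#'
#' @param copies_per_image explicit number of pastes per image, or `NULL` to
#'   paste until the image holds `min_targets` annotations.
#' @param min_targets target minimum per-image annotation count used when
#'   `copies_per_image` is `NULL` (default 10).
#' @param max_attempts rejection-sampling budget per paste.
#' @param harmonize match the pasted patch's mean/sd intensity to its
#'   destination neighbourhood (automatic stand-in for manual colour
#'   harmonisation; off by default and not equivalent to manual editing).
#' @param seed RNG seed threaded through placement sampling.
#' @return A list of class `paste_config`.
#' @export
paste_config <- function(copies_per_image = NULL, min_targets = 10L,
                         max_attempts = 100L, harmonize = FALSE, seed = NULL) {
  if (!is.null(copies_per_image) && !is_count(copies_per_image, 0L))
    stopf("copies_per_image must be a non-negative integer or NULL")
  if (!is_count(max_attempts, 1L)) stopf("max_attempts must be >= 1")
  if (!is_count(min_targets, 0L)) stopf("min_targets must be >= 0")
  structure(list(copies_per_image = copies_per_image,
                 min_targets = as.integer(min_targets),
                 max_attempts = as.integer(max_attempts),
                 harmonize = isTRUE(harmonize), seed = seed),
            class = "paste_config")
}

#' Constrained copy-paste target enhancement
#'
#' Increases the number of small targets in a scene by copying existing
#' sample patches to new positions on the leaf/trunk foreground. Every
#' accepted location satisfies the zero-overlap constraint — outer-region
#' overlap rate and sample overlap rate both exactly 0 — evaluated against
#' the original samples *and* all previously pasted boxes, so pasted copies
#' can neither touch the background nor stack on any target. Pixels are
#' copied hard (no blending); optional harmonisation rescales the patch's
#' intensity statistics to its destination neighbourhood.
#'
#' @param image pixel array `[H, W, 3]` in `[0, 1]`.
#' @param anns an [annotations()] data frame for `image`.
#' @param mask foreground mask matching `image`.
#' @param config a [paste_config()].
#' @return A list with `image` (augmented pixels), `annotations` (originals
#'   unchanged and first, pasted rows appended with `source = "pasted"`),
#'   and `reports` (one [overlap_report()] per successful paste, computed
#'   against the sample set in force at that paste). If no paste succeeds a
#'   warning is raised and the inputs are returned unchanged.
#' @export
copy_paste_augment <- function(image, anns, mask, config = paste_config()) {
  validate_annotations(anns, dim(image)[[2]], dim(image)[[1]])
  validate_mask(mask, image)
  stopifnot(inherits(config, "paste_config"))
  originals <- anns[anns$source == "original", , drop = FALSE]
  n_req <- config$copies_per_image %||% max(0L, config$min_targets - nrow(anns))
  if (n_req == 0L || nrow(originals) == 0L)
    return(list(image = image, annotations = anns, reports = list()))

  with_seed_or_current(config$seed, {
    out_img <- image
    out_ann <- anns
    reports <- list()
    for (k in seq_len(n_req)) {
      src_i <- sample.int(nrow(originals), 1L)
      src_box <- ann_box(originals, src_i)
      existing <- lapply(seq_len(nrow(out_ann)), function(i) ann_box(out_ann, i))
      prop <- propose_paste_location(src_box, mask, existing,
                                     max_attempts = config$max_attempts)
      if (prop$status != "ok") next
      dst <- prop$box
      reports[[length(reports) + 1L]] <- overlap_report(dst, mask, existing)
      patch <- image[(src_box[[2]] + 1):src_box[[4]],
                     (src_box[[1]] + 1):src_box[[3]], , drop = FALSE]
      if (config$harmonize)
        patch <- harmonize_patch(patch, out_img, dst)
      out_img[(dst[[2]] + 1):dst[[4]], (dst[[1]] + 1):dst[[3]], ] <- patch
      out_ann <- rbind(out_ann, data.frame(
        x0 = dst[[1]], y0 = dst[[2]], x1 = dst[[3]], y1 = dst[[4]],
        class_id = originals$class_id[[src_i]], source = "pasted",
        stringsAsFactors = FALSE))
    }
    if (length(reports) == 0L) {
      warnf("no valid paste location found for any sample; returning input unchanged")
      list(image = image, annotations = anns, reports = list())
    } else {
      list(image = out_img, annotations = out_ann, reports = reports)
    }
  })
}

# match patch mean/sd intensity to a neighbourhood around the destination box
harmonize_patch <- function(patch, image, dst, margin = 8L) {
  h <- dim(image)[[1]]; w <- dim(image)[[2]]
  y0 <- max(dst[[2]] - margin, 0); y1 <- min(dst[[4]] + margin, h)
  x0 <- max(dst[[1]] - margin, 0); x1 <- min(dst[[3]] + margin, w)
  neigh <- image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  m_p <- mean(patch); s_p <- stats::sd(patch)
  m_n <- mean(neigh); s_n <- stats::sd(neigh)
  if (!is.finite(s_p) || s_p < 1e-8) s_p <- 1
  out <- (patch - m_p) / s_p * s_n + m_n
  pmin(pmax(out, 0), 1)
}

#' Offline resampling of a dataset
#'
#' Replicates every record `factor` times under fresh record ids, so that
#' per-record stochastic preprocessing (multiscale resize, random rotation)
#' later turns the duplicates into distinct training samples. The source
#' record's id is retained in a `source_id` field.
#'
#' @param dataset a [detection_dataset()].
#' @param factor integer replication factor (>= 1); the study design uses 2.
#' @return A [detection_dataset()] with `factor * length(records)` records.
#' @export
offline_resample <- function(dataset, factor = 2L) {
  if (!is_count(factor, 1L)) stopf("resampling factor must be an integer >= 1")
  validate_dataset(dataset)
  records <- list()
  new_id <- 0L
  for (rep_i in seq_len(factor)) {
    for (r in dataset$records) {
      new_id <- new_id + 1L
      r2 <- r
      r2$source_id <- r$id
      r2$id <- new_id
      records[[new_id]] <- r2
    }
  }
  detection_dataset(records, categories = dataset$categories)
}
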