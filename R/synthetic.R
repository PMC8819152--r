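#' Synthetic scene configuration
#'
#' Parameters of the synthetic orchard-scene generator used to exercise the
#' whole pipeline without field data. Scenes emulate the statistical
#' structure of field imagery of citrus pests: a textured background, an
#' irregular leaf/trunk foreground region (recorded exactly in the mask),
#' small dark elliptical targets placed only on the foreground — psyllid-like
#' targets at 4-12 px and fly-like targets at roughly twice that (8-24 px),
#' matching the 2.5 mm vs 5 mm body sizes at the default 512 x 512 scene
#' scale — plus unannotated low-contrast distractor blobs that share the
#' targets' colouring (the stems/dead-leaf lookalikes that motivate
#' hard-example mining).
#'
#' @param width,height scene size in pixels.
#' @param coverage approximate foreground area fraction in (0, 1).
#' @param n_psyllid,n_fly exact per-class target counts, or `NULL` to draw
#'   from right-skewed (geometric) distributions under which most images
#'   contain at most a few targets.
#' @param count_prob geometric success probabilities used when counts are
#'   drawn, named `psyllid` and `fly`.
#' @param psyllid_size,fly_size inclusive pixel ranges for target extents.
#' @param n_distractors number of unannotated distractor blobs.
#' @param seed RNG seed (mandatory; scenes are deterministic given it).
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 512L, height = 512L, coverage = 0.6,
                         n_psyllid = NULL, n_fly = NULL,
                         count_prob = c(psyllid = 0.45, fly = 0.6),
                         psyllid_size = c(4L, 12L), fly_size = c(8L, 24L),
                         n_distractors = 4L, seed) {
  if (missing(seed) || is.null(seed)) stopf("scene_config requires a seed")
  if (coverage <= 0 || coverage >= 1) stopf("coverage must lie in (0, 1)")
  if (any(psyllid_size < 1L) || any(fly_size < 1L))
    stopf("target size ranges must be positive")
  structure(list(width = as.integer(width), height = as.integer(height),
                 coverage = coverage, n_psyllid = n_psyllid, n_fly = n_fly,
                 count_prob = count_prob,
                 psyllid_size = as.integer(psyllid_size),
                 fly_size = as.integer(fly_size),
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# pixel-centre membership of a rotated ellipse, as row/col index matrix
ellipse_pixels <- function(cx, cy, a, b, theta, width, height) {
  x0 <- max(0L, floor(cx - max(a, b))); x1 <- min(width - 1L, ceiling(cx + max(a, b)))
  y0 <- max(0L, floor(cy - max(a, b))); y1 <- min(height - 1L, ceiling(cy + max(a, b)))
  if (x1 < x0 || y1 < y0) return(cbind(row = integer(), col = integer()))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs + 0.5, length(ys), length(xs), byrow = TRUE) - cx
  gy <- matrix(ys + 0.5, length(ys), length(xs)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  inside <- which((u / a)^2 + (v / b)^2 <= 1, arr.ind = TRUE)
  cbind(row = ys[inside[, 1]] + 1L, col = xs[inside[, 2]] + 1L)
}

paint_pixels <- function(image, px, color, noise_sd = 0.015) {
  if (nrow(px) == 0L) return(image)
  for (ch in 1:3)
    image[cbind(px, ch)] <- pmin(pmax(
      color[[ch]] + rnorm(nrow(px), sd = noise_sd), 0), 1)
  image
}

# smooth multiplicative texture field in [1-amp, 1+amp]
texture_field <- function(height, width, amp = 0.12, sigma = 6) {
  noise <- matrix(rnorm(height * width), height, width)
  brush <- EBImage::makeBrush(2L * ceiling(3 * sigma) + 1L, "Gaussian",
                              sigma = sigma)
  sm <- EBImage::filter2(noise, brush)
  1 + amp * sm / max(abs(sm))
}

#' Generate one synthetic pest scene
#'
#' Renders a scene per its [scene_config()]: background and foreground
#' textures, the exact foreground mask, annotated elliptical targets of the
#' two classes (each annotation is the tight bounding box of the pixels the
#' target actually painted), and unannotated distractors. All target boxes
#' lie fully on the foreground and are pairwise disjoint; distractors never
#' overlap a target box. Output pixels are quantised to 8 bits so a PNG
#' round trip is lossless. Deterministic given `config$seed`.
#'
#' @param config a [scene_config()].
#' @return A list with `image` (`[H, W, 3]` in `[0, 1]`), `mask`
#'   (foreground 0/1 matrix) and `annotations`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  w <- config$width; h <- config$height
  withr::with_seed(config$seed, {
    # counts first so the draw order is stable
    n_psy <- config$n_psyllid %||% rgeom(1, config$count_prob[["psyllid"]])
    n_fly <- config$n_fly %||% rgeom(1, config$count_prob[["fly"]])

    tex <- texture_field(h, w)
    bg <- c(0.40, 0.40, 0.44)
    fg <- c(0.20, 0.42, 0.16)
    image <- array(0, c(h, w, 3))
    for (ch in 1:3) image[, , ch] <- pmin(pmax(bg[[ch]] * tex, 0), 1)

    # irregular foreground: union of random rotated ellipses up to coverage
    mask <- matrix(0L, h, w)
    for (blob in seq_len(400L)) {
      if (mean(mask) >= config$coverage) break
      px <- ellipse_pixels(runif(1, 0, w), runif(1, 0, h),
                           runif(1, 0.10, 0.30) * w, runif(1, 0.08, 0.22) * h,
                           runif(1, 0, pi), w, h)
      mask[px] <- 1L
    }
    fg_idx <- which(mask == 1L)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[fg_idx] <- pmin(pmax(fg[[ch]] * tex[fg_idx], 0), 1)
      image[, , ch] <- plane
    }

    place_box <- function(bw, bh, taken, max_attempts = 300L) {
      if (mask_inner_area(mask) < bw * bh)
        stopf("foreground too small for the requested targets")
      for (a in seq_len(max_attempts)) {
        x0 <- floor(runif(1, 0, w - bw + 1)); y0 <- floor(runif(1, 0, h - bh + 1))
        cand <- c(x0 = x0, y0 = y0, x1 = x0 + bw, y1 = y0 + bh)
        if (paste_location_ok(cand, mask, taken)) return(cand)
      }
      stopf("could not place a %dx%d target on the foreground; lower the target count or raise coverage", bw, bh)
    }

    anns <- annotations()
    taken <- matrix(numeric(), ncol = 4L)
    specs <- c(rep(0L, n_psy), rep(1L, n_fly))
    for (class_id in specs) {
      rng <- if (class_id == 0L) config$psyllid_size else config$fly_size
      bw <- sample(rng[[1]]:rng[[2]], 1L)
      bh <- sample(rng[[1]]:rng[[2]], 1L)
      bx <- place_box(bw, bh, taken)
      px <- ellipse_pixels(bx[[1]] + bw / 2, bx[[2]] + bh / 2,
                           bw / 2, bh / 2, 0, w, h)
      image <- paint_pixels(image, px, c(0.12, 0.11, 0.09))
      tight <- c(x0 = min(px[, "col"]) - 1L, y0 = min(px[, "row"]) - 1L,
                 x1 = max(px[, "col"]), y1 = max(px[, "row"]))
      taken <- rbind(taken, bx)
      anns <- rbind(anns, data.frame(
        x0 = tight[[1]], y0 = tight[[2]], x1 = tight[[3]], y1 = tight[[4]],
        class_id = class_id, source = "original", stringsAsFactors = FALSE))
    }

    # distractors: target-like colouring, slightly brighter, never annotated
    for (d in seq_len(config$n_distractors)) {
      bw <- sample(6:20, 1L); bh <- sample(4:12, 1L)
      bx <- tryCatch(place_box(bw, bh, taken, 100L), error = function(e) NULL)
      if (is.null(bx)) next
      px <- ellipse_pixels(bx[[1]] + bw / 2, bx[[2]] + bh / 2,
                           bw / 2, bh / 2, runif(1, 0, pi), w, h)
      image <- paint_pixels(image, px, c(0.30, 0.28, 0.24))
      taken <- rbind(taken, bx)
    }

    image <- round(image * 255) / 255  # 8-bit grid: PNG round trip is exact
    list(image = image, mask = mask, annotations = anns)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` scenes (seeded `config$seed`, `config$seed + 1`, ...)
#' as PNG images and PNG masks plus one COCO-style annotation file, and
#' returns the corresponding in-memory [detection_dataset()] (records carry
#' the pixel arrays and masks). Re-reading `annotations.json` with
#' [read_coco()] reproduces the dataset structure exactly.
#'
#' @param config a [scene_config()]; per-image seeds are derived from its
#'   seed.
#' @param n_images number of scenes (>= 1).
#' @param dir output directory (created if needed).
#' @return A [detection_dataset()]; the annotation file is
#'   `file.path(dir, "annotations.json")`.
#' @export
generate_dataset <- function(config, n_images, dir) {
  if (!is_count(n_images, 1L)) stopf("n_images must be >= 1")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create output directory %s", dir)
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    scene <- generate_scene(cfg_i)
    img_name <- sprintf("images/img_%04d.png", i)
    mask_name <- sprintf("masks/mask_%04d.png", i)
    png::writePNG(scene$image, file.path(dir, img_name))
    write_mask_png(scene$mask, file.path(dir, mask_name))
    records[[i]] <- list(id = i, file_name = img_name,
                         width = config$width, height = config$height,
                         annotations = scene$annotations,
                         image = scene$image, mask = scene$mask,
                         mask_file = mask_name)
  }
  ds <- detection_dataset(records)
  write_coco(ds, file.path(dir, "annotations.json"))
  ds
}
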