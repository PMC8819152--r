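test_that("scene generation is deterministic and honours explicit counts", {
  cfg <- scene_config(width = 96, height = 96, n_psyllid = 2, n_fly = 1,
                      seed = 7)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$annotations, b$annotations)
  expect_equal(sum(a$annotations$class_id == 0L), 2)
  expect_equal(sum(a$annotations$class_id == 1L), 1)

  none <- generate_scene(scene_config(width = 64, height = 64, n_psyllid = 0,
                                      n_fly = 0, seed = 1))
  expect_equal(nrow(none$annotations), 0)
  expect_equal(dim(none$image), c(64, 64, 3))
})

test_that("a seed is mandatory and infeasible target counts error", {
  expect_error(scene_config(width = 64, height = 64), "seed")
  expect_error(generate_scene(
    scene_config(width = 48, height = 48, coverage = 0.1,
                 n_psyllid = 0, n_fly = 40, seed = 3)),
    "place|foreground")
})

test_that("annotations are tight boxes of painted targets on the foreground", {
  for (seed in 1:15) {
    sc <- generate_scene(scene_config(width = 96, height = 96, seed = seed))
    ann <- sc$annotations
    for (i in seq_len(nrow(ann))) {
      # every interior pixel of the box lies on the foreground mask
      sub_mask <- sc$mask[(ann$y0[i] + 1):ann$y1[i],
                          (ann$x0[i] + 1):ann$x1[i], drop = FALSE]
      expect_true(all(sub_mask == 1L))
      # re-extract the target from the raster: targets are much darker than
      # foreground or distractors, so thresholding the box recovers it tightly
      brightness <- apply(sc$image[(ann$y0[i] + 1):ann$y1[i],
                                   (ann$x0[i] + 1):ann$x1[i], , drop = FALSE],
                          c(1, 2), mean)
      dark <- which(brightness < 0.18, arr.ind = TRUE)
      expect_gt(nrow(dark), 0)
      expect_equal(min(dark[, 2]), 1)                 # touches left edge
      expect_equal(max(dark[, 2]), ncol(brightness))  # right
      expect_equal(min(dark[, 1]), 1)                 # top
      expect_equal(max(dark[, 1]), nrow(brightness))  # bottom
    }
  }
})

test_that("drawn per-image counts are right-skewed (few targets per image)", {
  counts <- vapply(1:50, function(i)
    nrow(generate_scene(scene_config(width = 128, height = 128,
                                     n_distractors = 0,
                                     seed = 1000 + i))$annotations),
    numeric(1))
  # geometric draws: most scenes carry at most 3 targets, but not all zero
  expect_gt(mean(counts <= 3), 0.6)
  expect_gt(sum(counts), 0)
  # chi-square sanity against the configured geometric mixture
  p_psy <- stats::dgeom(0:2, 0.45); p_fly <- stats::dgeom(0:2, 0.6)
  p_total <- sapply(0:3, function(k)
    sum(sapply(0:k, function(j)
      stats::dgeom(j, 0.45) * stats::dgeom(k - j, 0.6))))
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
           sum(counts >= 3))
  expected_p <- c(p_total[1:3], 1 - sum(p_total[1:3]))
  chi <- suppressWarnings(stats::chisq.test(obs, p = expected_p))
  expect_gt(chi$p.value, 0.001)
})

test_that("foreground mask and painted foreground agree pixel-for-pixel", {
  sc <- generate_scene(scene_config(width = 96, height = 96, n_psyllid = 1,
                                    n_fly = 1, n_distractors = 0, seed = 9))
  # foreground pixels are green-dominant, background is not; exclude the
  # (dark) target boxes from the check
  exg <- 2 * sc$image[, , 2] - sc$image[, , 1] - sc$image[, , 3]
  target_px <- matrix(FALSE, 96, 96)
  a <- sc$annotations
  for (i in seq_len(nrow(a)))
    target_px[(a$y0[i] + 1):a$y1[i], (a$x0[i] + 1):a$x1[i]] <- TRUE
  free <- !target_px
  expect_true(all((exg[free] > 0.05) == (sc$mask[free] == 1L)))
})

test_that("datasets written to disk reload identically", {
  dir <- withr::local_tempdir()
  cfg <- scene_config(width = 64, height = 64, seed = 20)
  ds <- generate_dataset(cfg, n_images = 5, dir = dir)
  expect_length(ds$records, 5)
  expect_true(file.exists(file.path(dir, "annotations.json")))
  for (r in ds$records) {
    img_back <- png::readPNG(file.path(dir, r$file_name))
    expect_identical(img_back, r$image)  # 8-bit quantisation makes this exact
    expect_identical(read_mask_png(file.path(dir, r$mask_file)), r$mask)
  }
  total_ann <- sum(vapply(ds$records, function(r) nrow(r$annotations),
                          integer(1)))
  back <- read_coco(file.path(dir, "annotations.json"))
  expect_equal(sum(vapply(back$records, function(r) nrow(r$annotations),
                          integer(1))), total_ann)

  # regeneration with the same seed yields a byte-identical annotation file
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, n_images = 5, dir = dir2)
  expect_identical(readLines(file.path(dir2, "annotations.json")),
                   readLines(file.path(dir, "annotations.json")))
})
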