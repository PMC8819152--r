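test_that("segmentation interface: stored masks pass through, thresholds apply", {
  sc <- make_fixture_scene(seed = 3)
  expect_identical(segment_foreground(sc$image, mask = sc$mask), sc$mask)

  green <- array(rep(c(0.1, 0.8, 0.1), each = 16 * 16), c(16, 16, 3))
  expect_true(all(segment_foreground(green) == 1L))

  black <- array(0, c(16, 16, 3))
  expect_warning(m <- segment_foreground(black), "all-background")
  expect_true(all(m == 0L))

  expect_error(segment_foreground(array(0, c(0, 4, 3))), "empty image")
})

test_that("overlap rates match the stated boundary cases", {
  mask <- matrix(1L, 64, 64)
  mask[, 1:20] <- 0L  # outer region on the left
  existing <- list(box(30, 30, 40, 40))

  # fully inner, disjoint from samples: the paste-admissibility condition
  rep0 <- overlap_report(box(45, 5, 55, 15), mask, existing)
  expect_equal(rep0$u_outer, 0)
  expect_equal(rep0$u_samples, 0)

  # 10x10 box fully in the outer region of an all-outer 100x100 mask
  all_outer <- matrix(0L, 100, 100)
  rep1 <- overlap_report(box(10, 10, 20, 20), all_outer, list())
  expect_equal(rep1$u_outer, 100 / 10000)
  expect_true(rep1$samples_undefined)

  # copy box identical to the single existing sample
  rep2 <- overlap_report(box(30, 30, 40, 40), mask, existing)
  expect_equal(rep2$u_samples, 1.0)

  # zero denominators are flagged, not silent
  all_inner <- matrix(1L, 32, 32)
  rep3 <- overlap_report(box(0, 0, 4, 4), all_inner, list())
  expect_true(rep3$outer_undefined)
  expect_equal(rep3$u_outer, 0)
})

test_that("overlap rates agree with per-pixel counting on random 32x32 cases", {
  withr::local_seed(99)
  for (i in 1:200) {
    mask <- matrix(as.integer(runif(32 * 32) < runif(1, 0.2, 0.9)), 32, 32)
    existing <- lapply(seq_len(sample(0:4, 1)), function(k)
      random_int_box(32, 32, max_side = 12))
    cb <- random_int_box(32, 32, max_side = 16)
    got <- overlap_report(cb, mask, existing)
    want <- oracle_overlap(cb, mask, existing)
    expect_identical(got$u_outer, want$u_outer)
    expect_identical(got$u_samples, want$u_samples)
  }
})

test_that("paste proposals respect the zero-overlap constraint", {
  all_inner <- matrix(1L, 32, 32)
  p <- propose_paste_location(box(0, 0, 6, 6), all_inner, list(), seed = 1)
  expect_equal(p$status, "ok")
  expect_equal(p$attempts, 1L)

  all_outer <- matrix(0L, 32, 32)
  p2 <- propose_paste_location(box(0, 0, 6, 6), all_outer, list(), seed = 1)
  expect_equal(p2$status, "infeasible")

  # single 20x20 inner patch in a 64x64 mask, 6x6 sample, 50 seeded trials:
  # every accepted box re-verified against the per-pixel oracle
  mask <- matrix(0L, 64, 64)
  mask[21:40, 21:40] <- 1L
  existing <- list(box(25, 25, 31, 31))
  withr::local_seed(5)
  for (trial in 1:50) {
    p3 <- propose_paste_location(box(0, 0, 6, 6), mask, existing,
                                 max_attempts = 500)
    if (p3$status != "ok") next
    o <- oracle_overlap(p3$box, mask, existing)
    expect_identical(o$u_outer, 0)
    expect_identical(o$u_samples, 0)
  }
})

test_that("copy-paste augmentation obeys the placement constraint cumulatively", {
  sc <- make_fixture_scene(seed = 1, width = 256, height = 256,
                           n_psyllid = 3, n_fly = 2)
  out <- copy_paste_augment(sc$image, sc$annotations, sc$mask,
                            paste_config(copies_per_image = 10, seed = 1))
  n_pasted <- sum(out$annotations$source == "pasted")
  expect_gt(n_pasted, 0)
  expect_equal(nrow(out$annotations), 5 + n_pasted)
  expect_lte(n_pasted, 10)
  expect_length(out$reports, n_pasted)
  # originals retained unchanged, first
  expect_equal(out$annotations[1:5, ], sc$annotations)

  # every pasted box satisfies the constraint against originals AND
  # earlier-pasted boxes, re-verified with the per-pixel oracle
  for (k in seq_len(n_pasted)) {
    pasted <- out$annotations[5 + k, ]
    earlier <- out$annotations[seq_len(5 + k - 1), ]
    o <- oracle_overlap(c(pasted$x0, pasted$y0, pasted$x1, pasted$y1),
                        sc$mask,
                        lapply(seq_len(nrow(earlier)), function(i)
                          as.numeric(earlier[i, c("x0", "y0", "x1", "y1")])))
    expect_identical(o$u_outer, 0)
    expect_identical(o$u_samples, 0)
  }

  # pixels outside pasted boxes are bit-identical to the input
  changed <- out$image != sc$image
  pasted_mask <- matrix(FALSE, 256, 256)
  pa <- out$annotations[out$annotations$source == "pasted", ]
  for (i in seq_len(nrow(pa)))
    pasted_mask[(pa$y0[i] + 1):pa$y1[i], (pa$x0[i] + 1):pa$x1[i]] <- TRUE
  expect_true(all(!changed | array(pasted_mask, dim(changed))))
})

test_that("copy-paste is deterministic given the seed and a no-op at 0 copies", {
  sc <- make_fixture_scene(seed = 2)
  cfg <- paste_config(copies_per_image = 5, seed = 42)
  a <- copy_paste_augment(sc$image, sc$annotations, sc$mask, cfg)
  b <- copy_paste_augment(sc$image, sc$annotations, sc$mask, cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)

  z <- copy_paste_augment(sc$image, sc$annotations, sc$mask,
                          paste_config(copies_per_image = 0))
  expect_identical(z$image, sc$image)
  expect_identical(z$annotations, sc$annotations)
})

test_that("harmonisation rescales patch statistics but keeps the constraint", {
  sc <- make_fixture_scene(seed = 4)
  out <- copy_paste_augment(sc$image, sc$annotations, sc$mask,
                            paste_config(copies_per_image = 3, seed = 1,
                                         harmonize = TRUE))
  for (r in out$reports) {
    expect_equal(r$u_outer, 0)
    expect_equal(r$u_samples, 0)
  }
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("offline resampling replicates records exactly factor times", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(scene_config(width = 64, height = 64, seed = 8),
                         n_images = 7, dir = dir)
  expect_error(offline_resample(ds, 0), ">= 1")

  same <- offline_resample(ds, 1)
  expect_length(same$records, 7)

  doubled <- offline_resample(ds, 2)
  expect_length(doubled$records, 14)

  tripled <- offline_resample(ds, 3)
  expect_length(tripled$records, 21)
  src <- vapply(tripled$records, function(r) r$source_id, integer(1))
  expect_true(all(table(src) == 3))
  # ids are fresh and unique; annotations equal the source record's
  ids <- vapply(tripled$records, function(r) r$id, integer(1))
  expect_false(anyDuplicated(ids) > 0)
  for (r in tripled$records)
    expect_equal(r$annotations, ds$records[[r$source_id]]$annotations)
})
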