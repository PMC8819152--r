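test_that("nine-block tiling partitions the frame and remaps interior boxes", {
  img <- matrix(runif(300 * 300), 300, 300)
  ann <- annotations(10, 10, 20, 20, 0L)
  tiles <- tile_image(img, ann)
  expect_length(tiles, 9)
  expect_equal(dim(tiles[[1]]$image), c(100, 100))
  # interior box appears only in tile (0,0), untranslated
  expect_equal(nrow(tiles[[1]]$annotations), 1)
  expect_equal(as.numeric(tiles[[1]]$annotations[1, c("x0", "y0", "x1", "y1")]),
               c(10, 10, 20, 20))
  for (k in 2:9) expect_equal(nrow(tiles[[k]]$annotations), 0)
  # exact reassembly
  grid <- tile_grid(300, 300)
  expect_identical(reassemble_tiles(tiles, grid), img)
})

test_that("boxes straddling tile borders clip with exact area bookkeeping", {
  img <- matrix(0, 300, 300)
  ann <- annotations(90, 90, 110, 110, 0L)
  tiles <- tile_image(img, ann, keep_fraction = 0)
  clipped <- do.call(rbind, lapply(tiles, function(t) t$annotations))
  expect_equal(nrow(clipped), 4)  # box straddles four tiles
  areas <- (clipped$x1 - clipped$x0) * (clipped$y1 - clipped$y0)
  expect_equal(sum(areas), 400)
  # with the default keep fraction the two small 10x10 slivers survive only
  # if >= half the box remains; here every part is 100/400 < 0.5, all dropped
  tiles_half <- tile_image(img, ann, keep_fraction = 0.5)
  expect_equal(sum(vapply(tiles_half, function(t) nrow(t$annotations),
                          integer(1))), 0)
})

test_that("non-divisible dimensions put the remainder in the last row/column", {
  img <- matrix(seq_len(100 * 100) / 1e4, 100, 100)
  grid <- tile_grid(100, 100)
  widths <- vapply(grid$tiles, function(b) b[["x1"]] - b[["x0"]], numeric(1))
  expect_equal(widths[1:3], c(33, 33, 34))
  tiles <- tile_image(img, annotations(), grid)
  expect_identical(reassemble_tiles(tiles, grid), img)
  expect_error(tile_grid(2, 300), "smaller than")
})

test_that("multiscale resize follows the short-target/long-cap rule", {
  # 2000 wide x 1000 high at (1333, 800): short side 1000 -> factor 0.8
  # would give a 1600 long side > 1333, so the long side is capped
  img <- array(runif(1000 * 2000 * 3), c(1000, 2000, 3))
  ann <- annotations(0, 0, 2000, 1000, 0L)
  out <- multiscale_resize(img, ann, scale_spec(list(c(1333, 800))))
  expect_equal(dim(out$image)[1:2], c(667, 1333))
  expect_equal(out$factor, 1333 / 2000)
  expect_equal(as.numeric(out$annotations[1, c("x0", "y0", "x1", "y1")]),
               c(0, 0, 2000, 1000) * 1333 / 2000)

  # short-side rule applies when the cap is not hit
  img2 <- array(runif(96 * 128 * 3), c(96, 128, 3))
  out2 <- multiscale_resize(img2, spec = scale_spec(list(c(64, 48))))
  expect_equal(dim(out2$image)[1:2], c(48, 64))
})

test_that("each training scale is chosen about half the time", {
  img <- array(0.5, c(32, 32, 3))
  spec <- scale_spec(list(c(15, 10), c(13, 8)))  # miniature two-scale spec
  withr::local_seed(123)
  picks <- vapply(1:2000, function(i)
    multiscale_resize(img, spec = spec)$scale[[1]], numeric(1))
  frac <- mean(picks == 15)
  expect_gt(frac, 0.46)
  expect_lt(frac, 0.54)
})

test_that("right-angle rotation remaps boxes exactly", {
  img <- array(runif(100 * 100 * 3), c(100, 100, 3))
  ann <- annotations(0, 0, 10, 10, 0L)

  # p = 0 is always the identity
  out0 <- random_rotate(img, ann, p = 0, seed = 1)
  expect_false(out0$applied)
  expect_identical(out0$image, img)

  # 180 degrees maps the origin box to the opposite corner
  r180 <- img; a180 <- ann
  for (i in 1:2) {
    a180 <- psyllidet:::rotate_annotations_90cw(a180, dim(r180)[2], dim(r180)[1])
    r180 <- rotate_image_90cw(r180)
  }
  expect_equal(as.numeric(a180[1, c("x0", "y0", "x1", "y1")]),
               c(90, 90, 100, 100))

  # four quarter turns are the identity on pixels and boxes
  r <- img; a <- ann
  for (i in 1:4) {
    a <- psyllidet:::rotate_annotations_90cw(a, dim(r)[2], dim(r)[1])
    r <- rotate_image_90cw(r)
  }
  expect_identical(r, img)
  expect_equal(a, ann)
})

test_that("box remapping commutes with raster rotation for random boxes", {
  withr::local_seed(21)
  for (i in 1:25) {
    w <- sample(20:60, 1); h <- sample(20:60, 1)
    b <- random_int_box(w, h)
    painted <- matrix(0, h, w)
    painted[(b[[2]] + 1):b[[4]], (b[[1]] + 1):b[[3]]] <- 1
    k <- sample(1:3, 1)
    ann <- annotations(b[[1]], b[[2]], b[[3]], b[[4]], 0L)
    for (q in seq_len(k)) {
      ann <- psyllidet:::rotate_annotations_90cw(ann, dim(painted)[2],
                                                dim(painted)[1])
      painted <- rotate_image_90cw(painted)
    }
    idx <- which(painted == 1, arr.ind = TRUE)
    expect_equal(as.numeric(ann[1, c("x0", "y0", "x1", "y1")]),
                 c(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
                   max(idx[, 2]), max(idx[, 1])))
  }
})

test_that("rotation frequency tracks p and is seed-deterministic", {
  img <- array(0.5, c(16, 16, 3))
  withr::local_seed(17)
  applied <- vapply(1:2000, function(i) random_rotate(img, p = 0.3)$applied,
                    logical(1))
  expect_gt(mean(applied), 0.26)
  expect_lt(mean(applied), 0.34)
  a <- random_rotate(img, p = 0.5, seed = 9)
  b <- random_rotate(img, p = 0.5, seed = 9)
  expect_identical(a$angle, b$angle)
  expect_identical(a$image, b$image)
})
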