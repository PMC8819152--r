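# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: everything is
# computed by exhaustive per-pixel rasterisation or explicit enumeration.

# rasterise a half-open box onto an h x w logical grid
raster_box <- function(b, w, h) {
  g <- matrix(FALSE, h, w)
  x0 <- max(floor(b[[1]]), 0); y0 <- max(floor(b[[2]]), 0)
  x1 <- min(ceiling(b[[3]]), w); y1 <- min(ceiling(b[[4]]), h)
  if (x1 > x0 && y1 > y0) g[(y0 + 1):y1, (x0 + 1):x1] <- TRUE
  g
}

# per-pixel intersection area of two integer boxes on a shared grid
oracle_intersection_area <- function(a, b, w = 64, h = 64) {
  sum(raster_box(a, w, h) & raster_box(b, w, h))
}

oracle_iou <- function(a, b, w = 64, h = 64) {
  ra <- raster_box(a, w, h); rb <- raster_box(b, w, h)
  sum(ra & rb) / sum(ra | rb)
}

# per-pixel counting version of the two paste-placement overlap rates
oracle_overlap <- function(copy_box, mask, existing) {
  h <- nrow(mask); w <- ncol(mask)
  copy_r <- raster_box(copy_box, w, h)
  outer_r <- mask == 0L
  union_r <- matrix(FALSE, h, w)
  area_samples <- 0
  for (b in existing) {
    rb <- raster_box(b, w, h)
    union_r <- union_r | rb
    area_samples <- area_samples + sum(rb)
  }
  list(
    u_outer = if (sum(outer_r) > 0) sum(copy_r & outer_r) / sum(outer_r) else 0,
    u_samples = if (area_samples > 0) sum(copy_r & union_r) / area_samples else 0)
}

# hard-example selection by repeated extraction of the current maximum
# (ties resolved toward the smaller stable index)
oracle_ohem <- function(loss, positive, n_pos, n_neg) {
  pick_polarity <- function(idx, cap) {
    chosen <- integer()
    remaining <- idx
    while (length(chosen) < cap && length(remaining)) {
      best <- remaining[[1]]
      for (i in remaining) if (loss[[i]] > loss[[best]]) best <- i
      chosen <- c(chosen, best)
      remaining <- setdiff(remaining, best)
    }
    chosen
  }
  c(pick_polarity(which(positive), n_pos), pick_polarity(which(!positive), n_neg))
}

# threshold-enumeration average precision: scan every score threshold,
# collect (recall, precision) points, integrate the staircase by taking at
# each recall level the best precision achievable at or beyond it.
# Assumes distinct scores.
oracle_ap <- function(scores, tp, n_gt) {
  stopifnot(n_gt > 0)
  if (length(scores) == 0) return(0)
  pts_r <- c(); pts_p <- c()
  for (t in sort(unique(scores))) {
    keep <- scores >= t
    tp_k <- sum(tp[keep])
    pts_r <- c(pts_r, tp_k / n_gt)
    pts_p <- c(pts_p, tp_k / sum(keep))
  }
  rs <- sort(unique(pts_r))
  ap <- 0
  prev <- 0
  for (r in rs) {
    if (r == 0) next
    best_p <- max(pts_p[pts_r >= r])
    ap <- ap + (r - prev) * best_p
    prev <- r
  }
  ap
}

# small fixture scene shared across tests
make_fixture_scene <- function(seed = 1, width = 128, height = 128,
                               n_psyllid = 2, n_fly = 1) {
  generate_scene(scene_config(width = width, height = height,
                              n_psyllid = n_psyllid, n_fly = n_fly,
                              n_distractors = 2, seed = seed))
}

random_int_box <- function(w, h, max_side = NULL) {
  max_side <- max_side %||% w
  x0 <- sample(0:(w - 2), 1)
  y0 <- sample(0:(h - 2), 1)
  x1 <- sample((x0 + 1):min(w, x0 + max_side), 1)
  y1 <- sample((y0 + 1):min(h, y0 + max_side), 1)
  c(x0 = as.numeric(x0), y0 = as.numeric(y0),
    x1 = as.numeric(x1), y1 = as.numeric(y1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
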