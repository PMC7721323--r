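# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately avoid the package's own region code paths:
# shapes are generated as coordinate lists and counted exhaustively.

make_mask <- function(labels, scheme = "C") {
  seg_mask(labels, scheme)
}

# A solid rectangle region inside an h x w grid, returned as both a logical
# matrix and the coordinate list used to build it.
rect_region <- function(h, w, r0, r1, c0, c1) {
  fg <- matrix(FALSE, h, w)
  fg[r0:r1, c0:c1] <- TRUE
  list(fg = fg,
       coords = expand.grid(row = r0:r1, col = c0:c1))
}

# Rasterized disk: pixel centers within radius of (cy, cx).
disk_region <- function(h, w, cy, cx, radius) {
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  inside <- (rr - cy)^2 + (cc - cx)^2 <= radius^2
  fg <- matrix(inside, h, w)
  list(fg = fg, coords = data.frame(row = rr[inside], col = cc[inside]))
}

# Random blob: union of a few random rectangles and disks.
random_blob <- function(h = 24, w = 24, n_parts = 3) {
  fg <- matrix(FALSE, h, w)
  for (i in seq_len(n_parts)) {
    if (stats::runif(1) < 0.5) {
      r0 <- sample.int(h - 4, 1); c0 <- sample.int(w - 4, 1)
      r1 <- min(h, r0 + sample.int(8, 1)); c1 <- min(w, c0 + sample.int(8, 1))
      fg[r0:r1, c0:c1] <- TRUE
    } else {
      cy <- stats::runif(1, 4, h - 3); cx <- stats::runif(1, 4, w - 3)
      fg <- fg | disk_region(h, w, cy, cx, stats::runif(1, 2, 5))$fg
    }
  }
  fg
}

mask_from_region <- function(fg, label = 1L, scheme = "A") {
  seg_mask(matrix(as.integer(fg) * label, nrow(fg), ncol(fg)), scheme)
}

# Exhaustive-count morphometric oracle: area, bbox, extent from the raw
# pixel coordinates.
oracle_basic_traits <- function(fg) {
  pts <- which(fg, arr.ind = TRUE)
  bb_h <- diff(range(pts[, 1])) + 1
  bb_w <- diff(range(pts[, 2])) + 1
  list(area = nrow(pts), bbox_area = bb_h * bb_w,
       extent = nrow(pts) / (bb_h * bb_w))
}

# Brute-force convex-membership oracle: a pixel center q lies in the hull
# of the region's pixel centers iff adding q does not enlarge the hull
# polygon area (shoelace on chull vertices).
oracle_convex_area <- function(fg) {
  pts <- which(fg, arr.ind = TRUE)
  if (nrow(pts) <= 2) return(nrow(pts))
  shoelace <- function(p) {
    hv <- grDevices::chull(p[, 2], p[, 1])
    x <- p[hv, 2]; y <- p[hv, 1]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  base_area <- shoelace(pts)
  rr <- seq(min(pts[, 1]), max(pts[, 1]))
  cc <- seq(min(pts[, 2]), max(pts[, 2]))
  count <- 0L
  for (r in rr) for (c in cc) {
    if (shoelace(rbind(pts, c(r, c))) <= base_area + 1e-9) {
      count <- count + 1L
    }
  }
  count
}

# Brute-force mean-IoU oracle on a single mask pair: per-class set
# intersection over union, averaged over classes present in either mask.
oracle_mean_iou <- function(pred, truth) {
  labs <- unname(pred$scheme$labels)
  ious <- c()
  for (l in labs) {
    p <- which(pred$labels == l)
    t <- which(truth$labels == l)
    uni <- length(union(p, t))
    if (uni > 0) ious <- c(ious, length(intersect(p, t)) / uni)
  }
  mean(ious)
}

random_scheme_c_mask <- function(h = 16, w = 16) {
  seg_mask(matrix(sample(0:3, h * w, replace = TRUE), h, w), "C")
}

small_scene <- function(seed = 1, ...) {
  generate_rosette(scene_params(width = 128L, height = 128L, seed = seed,
                                ...))
}
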