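# Pixel-grid region utilities shared by morphometrics and the baseline
# segmenter. Regions are logical matrices; connectivity conventions are
# 8-connected foreground, 4-connected background (complementary pair).

# Linear-index neighbors within an h x w grid for a set of offsets.
# Returns the valid neighbor indices (deduplicated by the caller's visited
# bookkeeping, not here).
neighbor_indices <- function(idx, h, w, diagonal = FALSE) {
  r <- ((idx - 1L) %% h) + 1L
  out <- c(
    idx[r > 1L] - 1L,       # up
    idx[r < h] + 1L,        # down
    idx[idx > h] - h,       # left
    idx[idx <= h * (w - 1L)] + h  # right
  )
  if (diagonal) {
    up_ok <- r > 1L; dn_ok <- r < h
    lf_ok <- idx > h; rt_ok <- idx <= h * (w - 1L)
    out <- c(out,
             idx[up_ok & lf_ok] - 1L - h, idx[up_ok & rt_ok] - 1L + h,
             idx[dn_ok & lf_ok] + 1L - h, idx[dn_ok & rt_ok] + 1L + h)
  }
  out
}

# Flood fill from seed indices across `open` pixels. Returns the logical
# matrix of reached pixels. Frontier expansion is vectorized per wave.
flood_reach <- function(open, seeds, diagonal = FALSE) {
  h <- nrow(open); w <- ncol(open)
  reached <- matrix(FALSE, h, w)
  seeds <- seeds[open[seeds]]
  reached[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier) > 0L) {
    nb <- unique(neighbor_indices(frontier, h, w, diagonal = diagonal))
    nb <- nb[open[nb] & !reached[nb]]
    reached[nb] <- TRUE
    frontier <- nb
  }
  reached
}

# 8-connected component labeling of a logical matrix. Returns an integer
# matrix with 0 for background and 1..k for components.
label_components <- function(fg, diagonal = TRUE) {
  h <- nrow(fg); w <- ncol(fg)
  labels <- matrix(0L, h, w)
  todo <- which(fg)
  k <- 0L
  while (length(todo) > 0L) {
    seed <- todo[1L]
    comp <- flood_reach(fg & labels == 0L, seed, diagonal = diagonal)
    k <- k + 1L
    labels[comp] <- k
    todo <- todo[!comp[todo]]
  }
  labels
}

# Fill holes: background not 4-connected to the image border becomes
# foreground.
fill_holes <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  border <- unique(c(seq_len(h), (w - 1L) * h + seq_len(h),
                     (seq_len(w) - 1L) * h + 1L, (seq_len(w) - 1L) * h + h))
  outside <- flood_reach(!fg, border, diagonal = FALSE)
  fg | !outside
}

# Count of pixel centers inside or on the convex hull of the region's pixel
# centers. Degenerate hulls (<= 2 distinct vertices, collinear sets) fall
# back to the pixel count itself.
convex_hull_area <- function(fg) {
  pts <- which(fg, arr.ind = TRUE)
  n <- nrow(pts)
  if (n <= 2L) return(n)
  x <- pts[, 2]; y <- pts[, 1]
  hull <- grDevices::chull(x, y)  # clockwise vertex order
  if (length(hull) < 3L) return(n)
  hx <- x[hull]; hy <- y[hull]
  rr <- seq(min(y), max(y)); cc <- seq(min(x), max(x))
  qx <- rep(cc, each = length(rr)); qy <- rep(rr, times = length(cc))
  inside <- rep(TRUE, length(qx))
  eps <- 1e-9
  m <- length(hull)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (qy - hy[i]) - (hy[j] - hy[i]) * (qx - hx[i])
    inside <- inside & cross <= eps  # clockwise: interior on the right
    if (!any(inside)) break
  }
  sum(inside)
}

# Perimeter of the region: weighted steps along the traced outer contour of
# each 8-connected component (straight step 1, diagonal step sqrt(2)).
region_perimeter <- function(fg) {
  if (!any(fg)) return(0)
  labels <- label_components(fg)
  contours <- EBImage::ocontour(labels)
  sum(vapply(contours, function(p) {
    if (nrow(p) < 2L) return(0)
    d <- rbind(diff(p), p[1L, ] - p[nrow(p), ])
    sum(sqrt(rowSums(d^2)))
  }, numeric(1)))
}

# Row/col bounding box of a region as c(rmin, rmax, cmin, cmax).
region_bbox <- function(fg) {
  pts <- which(fg, arr.ind = TRUE)
  c(min(pts[, 1]), max(pts[, 1]), min(pts[, 2]), max(pts[, 2]))
}
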