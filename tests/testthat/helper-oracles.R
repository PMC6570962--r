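# Independent oracles used to validate the geometric kernels. These are
# deliberately naive (BFS flood fill, exhaustive pairs, fine angle grids)
# and share no code with the implementations they check.

# Naive BFS connected-component labelling; labels assigned in row-major
# raster-scan order of each component's first pixel.
flood_fill_oracle <- function(mask, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nxt <- 0L
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- nxt
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        nr <- cur[1L] + o[1L]; nc <- cur[2L] + o[2L]
        if (nr >= 1L && nr <= H && nc >= 1L && nc <= W &&
            mask[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- nxt
          queue <- c(queue, list(c(nr, nc)))
        }
      }
    }
  }
  lab
}

# Exhaustive maximum pairwise distance between polygon vertices.
brute_feret_max <- function(poly) {
  d <- as.matrix(dist(poly))
  max(d)
}

# Minimum projection width over a fine grid of orientations.
brute_feret_min <- function(poly, step_deg = 0.05) {
  angles <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(angles, function(a) {
    proj <- poly[, 1L] * cos(a) + poly[, 2L] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  min(widths)
}

# O(n^3) brute-force convex hull: a directed pair (i, j) is a hull edge iff
# every other point lies on or to the left of it. Returns vertices in order.
brute_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  verts <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (pts[j, 1L] - pts[i, 1L]) * (pts[, 2L] - pts[i, 2L]) -
          (pts[j, 2L] - pts[i, 2L]) * (pts[, 1L] - pts[i, 1L])
    if (all(cr >= 0)) { verts[i] <- TRUE; verts[j] <- TRUE }
  }
  hp <- pts[verts, , drop = FALSE]
  cen <- colMeans(hp)
  hp[order(atan2(hp[, 2L] - cen[2L], hp[, 1L] - cen[1L])), , drop = FALSE]
}

shoelace_oracle <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x); j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Pixel set of a plus-sign / cross of two centred perpendicular bars.
cross_pixels <- function(bar_len, bar_w, origin = c(0L, 0L)) {
  half <- (bar_len - bar_w) / 2
  px <- rbind(
    as.matrix(expand.grid(row = (half + 1):(half + bar_w), col = 1:bar_len)),
    as.matrix(expand.grid(row = 1:bar_len, col = (half + 1):(half + bar_w))))
  px <- unique(px)
  px[, 1L] <- px[, 1L] + origin[1L]
  px[, 2L] <- px[, 2L] + origin[2L]
  colnames(px) <- NULL
  px
}

random_mask <- function(H, W, p = 0.4) {
  matrix(runif(H * W) < p, H, W)
}

# A random convex polygon: hull of n uniform points.
random_hull <- function(n) {
  pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  idx <- grDevices::chull(pts)
  h <- pts[idx, , drop = FALSE]
  if (nrow(h) < 3) return(random_hull(n))
  h
}

write_scene_png <- function(record, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(record$raster / 255, path)
  path
}
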