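#' Label connected foreground particles
#'
#' Finds maximal connected components of foreground pixels under 4- or
#' 8-connectivity (8 by default, matching the usual particle-analysis
#' convention) and returns them as particle records. Indices are assigned
#' 1..N in raster-scan order of each component's first pixel, so numbering is
#' reproducible and matches the QC overlays and CSV rows.
#'
#' @param mask Logical matrix, `TRUE` = fungal material.
#' @param connectivity 4 or 8.
#' @param trace If `TRUE`, each particle also carries its traced outline and
#'   convex hull (see [trace_outline()]); set `FALSE` to defer tracing, e.g.
#'   until border-touching particles have been dropped.
#' @param source Path of the source image, carried through to reports.
#' @return List of `mpd_particle` records: `index`, `pixels` (two-column
#'   matrix of row/col coordinates), `pixel_count`, `touches_border`,
#'   `source`, and when traced `outline` and `hull` (two-column x/y matrices
#'   of pixel-corner vertices).
#' @export
label_particles <- function(mask, connectivity = 8, trace = TRUE,
                            source = NA_character_) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  lab <- label_components_cpp(mask, as.integer(connectivity))
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(list())
  labs <- lab[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  by_lab <- split(seq_along(idx), labs)
  particles <- vector("list", length(by_lab))
  for (i in seq_along(by_lab)) {
    sel <- by_lab[[i]]
    px <- cbind(row = rows[sel], col = cols[sel])
    p <- structure(list(
      index = i,
      pixels = px,
      pixel_count = nrow(px),
      touches_border = any(px[, 1L] == 1L | px[, 1L] == H |
                           px[, 2L] == 1L | px[, 2L] == W),
      source = source,
      connectivity = connectivity
    ), class = "mpd_particle")
    if (trace) p <- trace_particle(p)
    particles[[i]] <- p
  }
  particles
}

#' Apply the image-border policy
#'
#' Under `exclude_all`, particles touching the first or last row or column
#' are removed: they are only partially captured, so their descriptors would
#' be biased low. Under `keep_all` nothing is removed. Surviving particles
#' keep their original indices, so CSV/overlay cross-references stay valid.
#'
#' @param particles List of `mpd_particle` records.
#' @param policy `"exclude_all"` or `"keep_all"`.
#' @return Filtered particle list.
#' @export
apply_border_policy <- function(particles,
                                policy = c("exclude_all", "keep_all")) {
  policy <- match.arg(policy)
  if (policy == "keep_all") return(particles)
  Filter(function(p) !p$touches_border, particles)
}

# Add outline and hull to a particle record.
trace_particle <- function(p) {
  p$outline <- trace_outline(p$pixels, connectivity = p$connectivity %||% 8)
  p$hull <- convex_hull(p$outline)
  p
}

#' Trace the outer boundary of a particle as a pixel-corner polygon
#'
#' Walks the boundary edges between foreground and background along pixel
#' edges, producing a closed rectilinear polygon whose vertices are pixel
#' corners. A single pixel yields the unit square, so polygon area equals
#' pixel count for hole-free particles. Where the particle touches itself
#' diagonally, the walk keeps the component together under 8-connectivity and
#' splits it under 4-connectivity, consistent with the labelling. Interior
#' hole boundaries are traced but not returned; only the outer loop (the one
#' with the largest enclosed area) is.
#'
#' @param pixels Two-column matrix of row/col pixel coordinates forming one
#'   connected component.
#' @param connectivity Connectivity under which the pixels form one
#'   component; used only to verify connectedness of the input.
#' @return Two-column matrix of x/y vertex coordinates (x = column axis,
#'   y = row axis, pixel `(r, c)` spanning `[c-1, c] x [r-1, r]`), ordered
#'   with positive shoelace area, first vertex not repeated. Attributes:
#'   `signed_area`, `n_holes`.
#' @export
trace_outline <- function(pixels, connectivity = 8) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2L)
  r <- pixels[, 1L]; c <- pixels[, 2L]
  r0 <- min(r) - 1L; c0 <- min(c) - 1L
  lr <- r - r0; lc <- c - c0            # local 1-based pixel coords
  Hl <- max(lr); Wl <- max(lc)
  M <- matrix(FALSE, Hl, Wl)
  M[cbind(lr, lc)] <- TRUE

  has_nb <- function(dr, dc) {
    nr <- lr + dr; nc <- lc + dc
    ok <- nr >= 1L & nr <= Hl & nc >= 1L & nc <= Wl
    out <- logical(length(lr))
    out[ok] <- M[cbind(nr[ok], nc[ok])]
    out
  }
  # Boundary edges, oriented so traversal yields positive shoelace area for
  # the outer loop. dir codes: 0 = +x, 1 = +y, 2 = -x, 3 = -y.
  fx <- integer(0); fy <- integer(0); tx <- integer(0); ty <- integer(0)
  dr <- integer(0)
  add <- function(sel, x1, y1, x2, y2, d) {
    fx <<- c(fx, x1[sel]); fy <<- c(fy, y1[sel])
    tx <<- c(tx, x2[sel]); ty <<- c(ty, y2[sel])
    dr <<- c(dr, rep.int(d, sum(sel)))
  }
  add(!has_nb(-1L, 0L), lc - 1L, lr - 1L, lc, lr - 1L, 0L)      # top
  add(!has_nb(0L, 1L),  lc, lr - 1L, lc, lr, 1L)                # right
  add(!has_nb(1L, 0L),  lc, lr, lc - 1L, lr, 2L)                # bottom
  add(!has_nb(0L, -1L), lc - 1L, lr, lc - 1L, lr - 1L, 3L)      # left

  key <- function(x, y) y * (Wl + 1L) + x + 1L
  nv <- (Wl + 1L) * (Hl + 1L)
  from_key <- key(fx, fy); to_key <- key(tx, ty)
  out1 <- integer(nv); out2 <- integer(nv)
  for (e in seq_along(from_key)) {
    k <- from_key[e]
    if (out1[k] == 0L) out1[k] <- e else out2[k] <- e
  }

  used <- logical(length(from_key))
  # At a diagonal pinch two outgoing edges exist. The left turn wraps the
  # walk around the background pixel shared with the incoming edge, which
  # keeps each boundary loop attached to a single background region; the
  # right turn would jump to the other background region and split the loop.
  loops <- list(); areas <- numeric(0)
  for (start in seq_along(from_key)) {
    if (used[start]) next
    cur <- start
    vx <- integer(0); vy <- integer(0)
    repeat {
      used[cur] <- TRUE
      vx <- c(vx, fx[cur]); vy <- c(vy, fy[cur])
      k <- to_key[cur]
      e1 <- out1[k]; e2 <- out2[k]
      cand <- c(if (e1 != 0L && !used[e1]) e1, if (e2 != 0L && !used[e2]) e2)
      if (length(cand) == 0L) break
      if (length(cand) == 1L) { cur <- cand } else {
        want <- (dr[cur] + 3L) %% 4L
        cur <- if (dr[cand[1L]] == want) cand[1L] else cand[2L]
      }
    }
    a <- .shoelace(vx, vy)
    loops[[length(loops) + 1L]] <- cbind(x = vx, y = vy)
    areas <- c(areas, a)
  }
  if (sum(areas > 0) > 1L) {
    cc <- label_components_cpp(M, as.integer(connectivity))
    if (max(cc) > 1L)
      stop("trace_outline: input pixels are not a single connected component",
           call. = FALSE)
  }
  outer <- which.max(areas)
  poly <- loops[[outer]]
  poly[, 1L] <- poly[, 1L] + c0
  poly[, 2L] <- poly[, 2L] + r0
  structure(poly, signed_area = areas[outer],
            n_holes = sum(areas < 0))
}

# Signed shoelace area of a polygon given as open vertex vectors.
.shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area (shoelace formula)
#'
#' @param poly Two-column matrix of vertices, first vertex not repeated.
#' @return Absolute enclosed area in squared vertex units.
#' @export
polygon_area <- function(poly) {
  abs(.shoelace(poly[, 1L], poly[, 2L]))
}

#' Convex hull of an outline polygon
#'
#' Minimal convex polygon containing all outline vertices; its vertices are a
#' subset of the input vertices, ordered with positive shoelace area.
#'
#' @param outline Two-column matrix of x/y vertices.
#' @return Two-column matrix of hull vertices.
#' @export
convex_hull <- function(outline) {
  idx <- chull(outline[, 1L], outline[, 2L])
  h <- outline[idx, , drop = FALSE]
  if (.shoelace(h[, 1L], h[, 2L]) < 0) h <- h[rev(seq_len(nrow(h))), ,
                                              drop = FALSE]
  h
}
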