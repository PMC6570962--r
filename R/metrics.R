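#' Calibrated particle area
#'
#' Area is the count of foreground pixels times the calibrated pixel area;
#' interior holes are not filled and therefore not counted.
#'
#' @param particle An `mpd_particle` record.
#' @param cal An [mpd_calibration()].
#' @return Area in um^2.
#' @export
area_um2 <- function(particle, cal) {
  particle$pixel_count * cal$um_per_px^2
}

# Drop collinear vertices from a convex polygon (defensive: chull already
# returns extreme points, but exact collinearity on integer corners is cheap
# to guard against).
.strip_collinear <- function(h) {
  n <- nrow(h)
  if (n <= 3L) return(h)
  prev <- h[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- h[c(2:n, 1L), , drop = FALSE]
  cross <- (h[, 1L] - prev[, 1L]) * (nxt[, 2L] - h[, 2L]) -
           (h[, 2L] - prev[, 2L]) * (nxt[, 1L] - h[, 1L])
  keep <- cross != 0
  if (!any(keep)) return(h)
  h[keep, , drop = FALSE]
}

#' Maximum and minimum Feret (caliper) diameters
#'
#' The maximum Feret diameter is the largest distance between two parallel
#' supporting lines of the particle — equivalently the maximum pairwise
#' distance between convex-hull vertices, found here by rotating calipers
#' (antipodal-pair sweep, linear in hull size). The minimum Feret diameter is
#' the smallest such caliper width, attained at an orientation parallel to a
#' hull edge: for each edge, the projection width of all vertices onto the
#' edge normal is taken and the minimum over edges returned.
#'
#' @param hull Two-column matrix of convex-hull vertices in pixel-corner
#'   coordinates, positively oriented.
#' @param cal An [mpd_calibration()]; both outputs are scaled to um.
#' @return Named numeric vector `c(feret_max =, feret_min =)`.
#' @export
feret_extremes <- function(hull, cal) {
  h <- .strip_collinear(hull)
  n <- nrow(h)
  if (n < 3L)
    stop("degenerate hull: need at least 3 non-collinear vertices",
         call. = FALSE)
  if (.shoelace(h[, 1L], h[, 2L]) < 0)        # normalise to CCW
    h <- h[rev(seq_len(n)), , drop = FALSE]
  x <- h[, 1L]; y <- h[, 2L]
  nxt <- c(2:n, 1L)

  # rotating calipers for the diameter: for each edge advance the vertex
  # farthest from it; the visited (edge, vertex) pairs cover all antipodal
  # pairs of the polygon
  cross_h <- function(i, j, k) {
    (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
  }
  d2 <- function(i, k) (x[i] - x[k])^2 + (y[i] - y[k])^2
  k <- 2L
  best <- 0
  for (i in seq_len(n)) {
    j <- nxt[i]
    repeat {
      k2 <- nxt[k]
      if (cross_h(i, j, k2) > cross_h(i, j, k)) k <- k2 else break
    }
    best <- max(best, d2(i, k), d2(j, k))
  }
  feret_max <- sqrt(best)

  # minimum caliper width over hull-edge orientations
  ex <- x[nxt] - x; ey <- y[nxt] - y
  len <- sqrt(ex^2 + ey^2)
  nxn <- -ey / len; nyn <- ex / len            # unit edge normals
  proj <- outer(nxn, x) + outer(nyn, y)        # edges x vertices
  widths <- apply(proj, 1L, max) - apply(proj, 1L, min)
  feret_min <- min(widths)

  c(feret_max = feret_max * cal$um_per_px,
    feret_min = feret_min * cal$um_per_px)
}

#' Aspect ratio
#'
#' Maximum divided by minimum Feret diameter; 1 for isotropic shapes and
#' increasing with elongation. Note this is the caliper-based definition,
#' not a fitted-ellipse axis ratio.
#'
#' @param feret_max,feret_min Caliper diameters in um, `feret_min > 0`.
#' @return Dimensionless ratio, >= 1.
#' @export
aspect_ratio <- function(feret_max, feret_min) {
  if (feret_min <= 0) stop("feret_min must be positive", call. = FALSE)
  feret_max / feret_min
}

#' Solidity
#'
#' Observed particle area divided by its convex-hull area: a surface-
#' integrity measure that is 1 for convex, smooth particles and decreases
#' toward 0 with increasing boundary irregularity. The observed area is the
#' calibrated pixel area and the hull area the shoelace area of the hull
#' polygon; since the hull contains the whole pixel region, the ratio is
#' capped at 1 up to rasterization.
#'
#' @param particle_area Observed area, um^2.
#' @param hull_area Convex-hull area, um^2.
#' @return Dimensionless solidity in (0, 1].
#' @export
solidity <- function(particle_area, hull_area) {
  if (!(particle_area > 0)) stop("particle area must be positive",
                                 call. = FALSE)
  if (hull_area < particle_area)
    stop("hull area smaller than particle area: inconsistent geometry",
         call. = FALSE)
  particle_area / hull_area
}

#' Dimensionless morphology number
#'
#' Composite descriptor combining area, solidity, maximum Feret diameter and
#' aspect ratio:
#' \deqn{MN = \frac{2 \sqrt{A} \, S}{\sqrt{\pi} \, F \, AR}}
#' It equals 1 for a perfect circle and tends to 0 for a vanishing-width
#' line, compressing particle size-free shape information into one number.
#' Values marginally above 1 can arise from rasterization and are reported
#' unclamped.
#'
#' @param area Particle area, um^2.
#' @param solidity Solidity, dimensionless, in (0, 1].
#' @param feret_max Maximum Feret diameter, um.
#' @param aspect_ratio Aspect ratio, dimensionless, >= 1.
#' @return The morphology number (dimensionless, > 0).
#' @export
morphology_number <- function(area, solidity, feret_max, aspect_ratio) {
  if (any(c(area, solidity, feret_max, aspect_ratio) <= 0))
    stop("all morphology-number inputs must be strictly positive",
         call. = FALSE)
  2 * sqrt(area) * solidity / (sqrt(pi) * feret_max * aspect_ratio)
}

#' All shape descriptors for one particle
#'
#' Convenience wrapper computing area, Feret extremes, aspect ratio,
#' solidity and morphology number in calibrated units, plus the area class
#' when a classification config is supplied.
#'
#' @param particle A traced `mpd_particle` (with `hull`).
#' @param cal An [mpd_calibration()].
#' @param config Optional [mpd_class_config()] for the class label.
#' @return A one-row data frame of metrics.
#' @export
particle_metrics <- function(particle, cal, config = NULL) {
  if (is.null(particle$hull)) particle <- trace_particle(particle)
  area <- area_um2(particle, cal)
  fer <- feret_extremes(particle$hull, cal)
  ar <- aspect_ratio(fer[["feret_max"]], fer[["feret_min"]])
  hull_area <- polygon_area(particle$hull) * cal$um_per_px^2
  sol <- solidity(area, hull_area)
  mn <- morphology_number(area, sol, fer[["feret_max"]], ar)
  cls <- if (is.null(config)) NA_character_ else classify_area(area, config)
  data.frame(index = particle$index,
             class = cls,
             area_um2 = area,
             feret_max_um = fer[["feret_max"]],
             feret_min_um = fer[["feret_min"]],
             aspect_ratio = ar,
             solidity = sol,
             morphology_number = mn,
             stringsAsFactors = FALSE)
}
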