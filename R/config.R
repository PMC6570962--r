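#' Spatial calibration of a micrograph
#'
#' Converts pixel geometry to physical units. Lengths scale by `um_per_px`
#' and areas by `um_per_px^2` exactly.
#'
#' @param um_per_px Physical edge length of one pixel, in micrometres.
#'   Strictly positive.
#' @return An object of class `mpd_calibration`.
#' @examples
#' cal <- mpd_calibration(1.5)
#' cal$um_per_px^2   # area conversion factor, um^2 per pixel
#' @export
mpd_calibration <- function(um_per_px) {
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L ||
      !is.finite(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be a single strictly positive number", call. = FALSE)
  structure(list(um_per_px = as.numeric(um_per_px)),
            class = "mpd_calibration")
}

#' Area-based particle classification rules
#'
#' Particles are labelled by calibrated area: `pellet` at or above
#' `pellet_min_area`, `dispersed` between `dispersed_min_area` (inclusive)
#' and `pellet_min_area` (exclusive), and `artefact` below
#' `dispersed_min_area`. Artefacts are excluded from all analyses and
#' reports; only their count and total area are logged. The defaults
#' (500 and 95 um^2) suit ~10x magnification; at higher magnification a
#' lower dispersed bound (e.g. 20 um^2 at 50x) resolves small hyphal
#' fragments.
#'
#' @param pellet_min_area Minimum pellet area, um^2. Default 500.
#' @param dispersed_min_area Minimum dispersed-mycelium area, um^2
#'   (anything smaller is an artefact). Default 95.
#' @param mode Which morphology classes to analyse: `"pellets"`,
#'   `"dispersed"` or `"both"`.
#' @return An object of class `mpd_class_config`.
#' @export
mpd_class_config <- function(pellet_min_area = 500,
                             dispersed_min_area = 95,
                             mode = c("both", "pellets", "dispersed")) {
  mode <- match.arg(mode)
  if (!is.numeric(pellet_min_area) || !is.numeric(dispersed_min_area) ||
      length(pellet_min_area) != 1L || length(dispersed_min_area) != 1L)
    stop("area cut-offs must be single numbers", call. = FALSE)
  if (!(dispersed_min_area > 0 && dispersed_min_area < pellet_min_area))
    stop("need 0 < dispersed_min_area < pellet_min_area", call. = FALSE)
  structure(list(pellet_min_area = as.numeric(pellet_min_area),
                 dispersed_min_area = as.numeric(dispersed_min_area),
                 mode = mode),
            class = "mpd_class_config")
}

#' @export
print.mpd_calibration <- function(x, ...) {
  cat(sprintf("Calibration: %g um/pixel (%g um^2/pixel)\n",
              x$um_per_px, x$um_per_px^2))
  invisible(x)
}

#' @export
print.mpd_class_config <- function(x, ...) {
  cat(sprintf(
    "Classification: pellet >= %g um^2, dispersed [%g, %g) um^2, mode = %s\n",
    x$pellet_min_area, x$dispersed_min_area, x$pellet_min_area, x$mode))
  invisible(x)
}
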