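#' Classify a particle by calibrated area
#'
#' Pure threshold rule on area in um^2: `pellet` at or above the pellet
#' cut-off, `artefact` strictly below the dispersed cut-off, `dispersed` in
#' between. Both bounds are inclusive on their lower side, exactly as the
#' defaults are defined (>= 500 um^2 pellet, >= 95 um^2 dispersed).
#'
#' @param area Particle area(s), um^2. Vectorised.
#' @param config An [mpd_class_config()].
#' @return Character vector of `"pellet"`, `"dispersed"`, `"artefact"`.
#' @export
classify_area <- function(area, config) {
  stopifnot(inherits(config, "mpd_class_config"))
  ifelse(area >= config$pellet_min_area, "pellet",
         ifelse(area >= config$dispersed_min_area, "dispersed", "artefact"))
}

#' Pelleted fraction of total fungal area
#'
#' Heterogeneity readout for one directory of images: the percentage of total
#' fungal area (pellets + dispersed mycelium, pooled over all images; the
#' pooling makes the statistic invariant to how the culture is split across
#' photographs) contributed by pellets. Artefacts are excluded from the
#' denominator.
#'
#' @param rows Data frame of per-particle rows (columns `class`,
#'   `area_um2`), already free of artefacts.
#' @return Percentage in \[0, 100\], or `NA` (with a warning) if there is no
#'   fungal area.
#' @export
pellet_fraction <- function(rows) {
  pel <- sum(rows$area_um2[rows$class == "pellet"])
  disp <- sum(rows$area_um2[rows$class == "dispersed"])
  total <- pel + disp
  if (total <= 0) {
    warning("no fungal area: pelleted fraction undefined")
    return(NA_real_)
  }
  100 * pel / total
}

#' Remove visually rejected particle calls
#'
#' The QC overlays let the user spot wrong pellet/dispersed calls; this
#' re-entry point removes the flagged particles from the result rows before
#' reports are (re)written. Flags may be given as a data frame or as the
#' path of a CSV with columns `image`, `index`.
#'
#' @param rows Data frame of per-particle rows with `image` and `index`
#'   columns.
#' @param flags Data frame or CSV path with columns `image`, `index`.
#' @return The rows with flagged particles removed; the number removed is
#'   attached as attribute `n_dropped`.
#' @export
drop_flagged <- function(rows, flags) {
  if (is.character(flags)) flags <- read.csv(flags, stringsAsFactors = FALSE)
  stopifnot(all(c("image", "index") %in% names(flags)))
  if (nrow(flags) == 0L) {
    attr(rows, "n_dropped") <- 0L
    return(rows)
  }
  key_rows <- paste(rows$image, rows$index, sep = "\r")
  key_flags <- paste(flags$image, flags$index, sep = "\r")
  unknown <- !(key_flags %in% key_rows)
  if (any(unknown))
    stop(sprintf("unknown flagged particle(s): %s",
                 paste(sprintf("%s #%s", flags$image[unknown],
                               flags$index[unknown]), collapse = ", ")),
         call. = FALSE)
  out <- rows[!(key_rows %in% key_flags), , drop = FALSE]
  attr(out, "n_dropped") <- nrow(rows) - nrow(out)
  out
}

#' Ordinary least-squares line and R-squared
#'
#' Utility for correlating morphology summaries (pellet diameter, MN,
#' pelleted fraction, ...) with external scalar measurements such as biomass
#' or secreted protein.
#'
#' @param x,y Numeric vectors of equal length (>= 2 points).
#' @return Named list with `slope`, `intercept` and `r_squared`.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("need at least two (x, y) points", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("x is constant: line of best fit undefined", call. = FALSE)
  fit <- lm(y ~ x)
  if (diff(range(y)) == 0) {
    warning("y is constant: R-squared reported as 0")
    return(list(slope = 0, intercept = y[1L], r_squared = 0))
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = 1 - ss_res / ss_tot)
}
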