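#' Percentile contrast stretch
#'
#' Linearly rescales intensities so that a fixed fraction of pixels saturates,
#' split evenly between the dark and bright tails (the usual "enhance
#' contrast by X%" semantics). With `saturation = 0` this is a plain min-max
#' stretch. The mapping is monotone non-decreasing; a constant raster is
#' returned unchanged with a warning.
#'
#' @param raster Integer matrix (grey) or `height x width x 3` array (RGB)
#'   of 8-bit intensities. RGB channels are stretched jointly so hue
#'   relations are preserved.
#' @param saturation Total fraction of pixels allowed to clip, in `[0, 1)`.
#'   Default 0.05 (5%, i.e. 2.5% per tail). If either percentile collapses
#'   onto the other (sparse foreground), the stretch falls back to min-max.
#' @return Raster of the same kind and dimensions, values in 0..255.
#' @export
enhance_contrast <- function(raster, saturation = 0.05) {
  if (!is.numeric(saturation) || length(saturation) != 1L ||
      saturation < 0 || saturation >= 1)
    stop("saturation must lie in [0, 1)", call. = FALSE)
  v <- as.integer(raster)
  if (length(v) == 0L) stop("empty raster", call. = FALSE)
  # exact percentiles from the 256-bin histogram (8-bit input), then a
  # lookup-table mapping: O(n) with no sort
  counts <- tabulate(v + 1L, 256L)
  need <- max(length(v) * saturation / 2, 1)
  cum <- cumsum(counts)
  upper <- rev(cumsum(rev(counts)))        # pixels at or above intensity i-1
  lo <- which(cum >= need)[1L] - 1L        # s/2 percentile
  hi <- max(which(upper >= need)) - 1L     # 1 - s/2 percentile
  if (hi <= lo) {
    # degenerate percentiles: a sparse foreground (< saturation/2 of the
    # pixels) collapses both tails onto the background mode
    lo <- which(counts > 0)[1L] - 1L
    hi <- max(which(counts > 0)) - 1L
    if (hi <= lo) {
      warning("constant-intensity raster: contrast left unchanged")
      return(raster)
    }
  }
  lut <- as.integer(round(pmin(pmax((0:255 - lo) / (hi - lo), 0), 1) * 255))
  out <- lut[v + 1L]
  array(out, dim(raster) %||% length(raster))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the red channel
#'
#' Reduces an RGB record to a grey raster by keeping the red channel exactly
#' and discarding green and blue. On light-on-dark culture photographs the
#' red channel carries the fungal signal with the least background texture.
#'
#' @param record An `mpd_image` record, or a bare `h x w x 3` array.
#' @return Integer matrix of 8-bit intensities (class `mpd_grey` attributes:
#'   `source` path).
#' @export
to_red_channel <- function(record) {
  raster <- if (inherits(record, "mpd_image")) record$raster else record
  if (length(dim(raster)) != 3L || dim(raster)[3] < 3L)
    stop("expected an RGB raster with three channels", call. = FALSE)
  g <- raster[, , 1L, drop = TRUE]
  attr(g, "source") <- if (inherits(record, "mpd_image")) record$path else NA
  g
}

#' Iterative intermeans (isodata) threshold
#'
#' Chooses the grey level at which the threshold equals the mean of the two
#' class means it induces: tau = (mean(values <= tau) + mean(values > tau))/2,
#' iterated from the global mean to a fixed point on the 256-bin histogram.
#'
#' @param gray Integer matrix of 8-bit intensities.
#' @return The fixed-point cutoff (numeric scalar), or `NA` for a constant
#'   image.
#' @export
isodata_threshold <- function(gray) {
  v <- as.integer(gray)
  h <- tabulate(v + 1L, nbins = 256L)
  lev <- 0:255
  if (sum(h > 0) < 2L) return(NA_real_)
  tau <- sum(h * lev) / sum(h)
  for (i in 1:100) {
    below <- lev <= tau
    m0 <- sum(h[below] * lev[below]) / sum(h[below])
    m1 <- sum(h[!below] * lev[!below]) / sum(h[!below])
    new_tau <- (m0 + m1) / 2
    if (abs(new_tau - tau) < 0.5) { tau <- new_tau; break }
    tau <- new_tau
  }
  tau
}

#' Threshold a grey raster into a foreground mask
#'
#' Pixels strictly brighter than the cutoff become foreground; the cutoff
#' pixel itself is background. With `spec = "auto"` the cutoff is chosen per
#' image by the isodata intermeans rule; a numeric `spec` pins a fixed global
#' cutoff for strict reproduction of a hand-selected standard threshold.
#' Because the cultures are photographed light-on-dark, bright pixels are
#' fungal material, so the mask needs no further polarity handling: foreground
#' always denotes fungus downstream.
#'
#' @param gray Integer matrix of 8-bit intensities.
#' @param spec Either the string `"auto"` or a fixed numeric cutoff in
#'   0..255.
#' @param calibration Optional `mpd_calibration` attached to the mask.
#' @return Logical matrix of the same dimensions (class `mpd_mask`
#'   attributes: `calibration`, `cutoff`).
#' @export
binarize <- function(gray, spec = "auto", calibration = NULL) {
  if (identical(spec, "auto")) {
    cutoff <- isodata_threshold(gray)
    if (is.na(cutoff)) {
      warning("constant image: automatic threshold undefined, mask is empty")
      mask <- array(FALSE, dim(gray))
      attr(mask, "calibration") <- calibration
      attr(mask, "cutoff") <- NA_real_
      return(mask)
    }
  } else if (is.numeric(spec) && length(spec) == 1L) {
    cutoff <- as.numeric(spec)
  } else {
    stop("threshold spec must be \"auto\" or a single number", call. = FALSE)
  }
  mask <- gray > cutoff
  dim(mask) <- dim(gray)
  attr(mask, "calibration") <- calibration
  attr(mask, "cutoff") <- cutoff
  mask
}
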