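# 3x5 bitmap digit glyphs used to stamp particle indices onto overlays
# (kept self-contained so overlay rendering needs no graphics device).
.digit_glyphs <- local({
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(rows, function(g) {
    m <- do.call(rbind, lapply(g, function(s)
      as.integer(strsplit(s, "")[[1]]) == 1L))
    m
  })
})

# Pixel coordinates (row/col offsets from top-left) of a number rendered at
# integer scale `scale`, digits separated by one scaled blank column.
.number_pixels <- function(n, scale = 2L) {
  digits <- strsplit(as.character(n), "")[[1]]
  off <- 0L
  out <- NULL
  sq <- scale * scale
  dr <- rep(0:(scale - 1L), times = scale)
  dc <- rep(0:(scale - 1L), each = scale)
  for (d in digits) {
    g <- .digit_glyphs[[d]]
    hit <- which(g, arr.ind = TRUE)
    px <- cbind(rep((hit[, 1L] - 1L) * scale, each = sq) +
                  rep(dr, times = nrow(hit)),
                rep((hit[, 2L] - 1L) * scale + off, each = sq) +
                  rep(dc, times = nrow(hit)))
    out <- rbind(out, px)
    off <- off + 4L * scale
  }
  out
}

# Boundary pixels of a particle: foreground pixels with at least one
# orthogonal neighbour outside the particle.
.boundary_pixels <- function(pixels) {
  r <- pixels[, 1L]; c <- pixels[, 2L]
  r0 <- min(r) - 1L; c0 <- min(c) - 1L
  lr <- r - r0; lc <- c - c0
  Hl <- max(lr); Wl <- max(lc)
  M <- matrix(FALSE, Hl + 2L, Wl + 2L)   # padded so borders count as outside
  M[cbind(lr + 1L, lc + 1L)] <- TRUE
  interior <- M[cbind(lr, lc + 1L)] & M[cbind(lr + 2L, lc + 1L)] &
              M[cbind(lr + 1L, lc)] & M[cbind(lr + 1L, lc + 2L)]
  pixels[!interior, , drop = FALSE]
}

#' Render indexed quality-control overlays
#'
#' For one raw image, draws each reported particle's outline in red,
#' annotated with its particle index at the centroid, and writes one overlay
#' per analysed class (pellets in one file, dispersed mycelium in the other)
#' so the user can visually audit every automated call against the CSV row
#' carrying the same index.
#'
#' @param record An `mpd_image` record.
#' @param particles List of traced `mpd_particle` records (surviving the
#'   border policy; artefacts excluded).
#' @param classes Character vector of class labels aligned with `particles`.
#' @param out_dir Directory receiving the overlays.
#' @param mode Which overlays to write: `"pellets"`, `"dispersed"` or
#'   `"both"`.
#' @return Character vector of written file paths.
#' @export
render_qc_overlays <- function(record, particles, classes, out_dir,
                               mode = c("both", "pellets", "dispersed")) {
  mode <- match.arg(mode)
  want <- switch(mode, both = c("pellet", "dispersed"),
                 pellets = "pellet", dispersed = "dispersed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- tools::file_path_sans_ext(basename(record$path))
  H <- dim(record$raster)[1L]; W <- dim(record$raster)[2L]
  paths <- character(0)
  for (cls in want) {
    img <- record$raster / 255
    sel <- which(classes == cls)
    for (i in sel) {
      p <- particles[[i]]
      bp <- .boundary_pixels(p$pixels)
      img[cbind(bp[, 1L], bp[, 2L], 1L)] <- 1
      img[cbind(bp[, 1L], bp[, 2L], 2L)] <- 0
      img[cbind(bp[, 1L], bp[, 2L], 3L)] <- 0
      cen <- round(colMeans(p$pixels))
      lab <- .number_pixels(p$index)
      lr <- pmin(pmax(cen[1L] + lab[, 1L] - 5L, 1L), H)
      lc <- pmin(pmax(cen[2L] + lab[, 2L] - 3L, 1L), W)
      img[cbind(lr, lc, 1L)] <- 1
      img[cbind(lr, lc, 2L)] <- 0
      img[cbind(lr, lc, 3L)] <- 0
    }
    suffix <- if (cls == "pellet") "pellets" else "dispersed"
    path <- file.path(out_dir, sprintf("%s_%s.png", base, suffix))
    png::writePNG(img, path)
    paths <- c(paths, path)
  }
  paths
}
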