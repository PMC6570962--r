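#' Synthetic shape specifications
#'
#' Constructors for parametric shapes with analytic ground-truth descriptors,
#' used to build validation scenes that emulate light-on-dark culture
#' photographs. All dimensions and positions are in um. `synth_disc` models a
#' compact pellet, `synth_rect`/`synth_ellipse` elongated fragments,
#' `synth_cross` a concave particle with known hull, and `synth_blob`
#' (a union of overlapping discs) an irregular aggregate whose truth is
#' computed numerically at 10x supersampling rather than analytically.
#'
#' @param r,a,b,w,h,bar_len,bar_w Shape dimensions in um (`a >= b` are
#'   ellipse semi-axes; `w`, `h` rectangle sides; crosses are two centred
#'   perpendicular `bar_len x bar_w` bars).
#' @param centre Length-2 vector, shape centre in um (x, y).
#' @param rotation Rotation in degrees, counter-clockwise.
#' @param intensity 8-bit foreground grey level.
#' @param offsets,radii For blobs: k x 2 matrix of disc-centre offsets from
#'   `centre` and the k disc radii, um.
#' @return An object of class `mpd_shape`.
#' @name synth_shapes
NULL

.shape <- function(kind, params, centre, rotation, intensity) {
  structure(list(kind = kind, params = params,
                 centre = as.numeric(centre),
                 rotation = as.numeric(rotation),
                 intensity = as.integer(intensity)),
            class = "mpd_shape")
}

#' @rdname synth_shapes
#' @export
synth_disc <- function(r, centre, intensity = 200) {
  stopifnot(r > 0)
  .shape("disc", list(r = r), centre, 0, intensity)
}

#' @rdname synth_shapes
#' @export
synth_ellipse <- function(a, b, centre, rotation = 0, intensity = 200) {
  stopifnot(a >= b, b > 0)
  .shape("ellipse", list(a = a, b = b), centre, rotation, intensity)
}

#' @rdname synth_shapes
#' @export
synth_rect <- function(w, h, centre, rotation = 0, intensity = 200) {
  stopifnot(w > 0, h > 0)
  .shape("rect", list(w = w, h = h), centre, rotation, intensity)
}

#' @rdname synth_shapes
#' @export
synth_cross <- function(bar_len, bar_w, centre, rotation = 0,
                        intensity = 200) {
  stopifnot(bar_len > bar_w, bar_w > 0)
  .shape("cross", list(l = bar_len, w = bar_w), centre, rotation, intensity)
}

#' @rdname synth_shapes
#' @export
synth_blob <- function(offsets, radii, centre, intensity = 200) {
  offsets <- matrix(offsets, ncol = 2L)
  stopifnot(nrow(offsets) == length(radii), all(radii > 0))
  .shape("blob", list(offsets = offsets, radii = radii), centre, 0, intensity)
}

# Radius of the bounding circle around a shape's centre, um.
.shape_radius <- function(s) {
  p <- s$params
  switch(s$kind,
         disc = p$r,
         ellipse = p$a,
         rect = sqrt(p$w^2 + p$h^2) / 2,
         cross = sqrt(p$l^2 + p$w^2) / 2,
         blob = max(sqrt(rowSums(p$offsets^2)) + p$radii))
}

# Point-inclusion test in the shape's own frame (centred, unrotated), um.
.shape_inside <- function(s, x, y) {
  p <- s$params
  switch(s$kind,
         disc = x^2 + y^2 <= p$r^2,
         ellipse = (x / p$a)^2 + (y / p$b)^2 <= 1,
         rect = abs(x) <= p$w / 2 & abs(y) <= p$h / 2,
         cross = (abs(x) <= p$l / 2 & abs(y) <= p$w / 2) |
                 (abs(x) <= p$w / 2 & abs(y) <= p$l / 2),
         blob = {
           inside <- rep(FALSE, length(x))
           for (k in seq_along(p$radii))
             inside <- inside | ((x - p$offsets[k, 1L])^2 +
                                 (y - p$offsets[k, 2L])^2 <= p$radii[k]^2)
           inside
         })
}

#' Ground-truth descriptors of a synthetic shape
#'
#' Analytic (disc, ellipse, rectangle, cross) or 10x-supersampled numeric
#' (blob) values of area, Feret extremes, aspect ratio, solidity and
#' morphology number, plus the expected class under a classification config.
#'
#' @param shape An `mpd_shape`.
#' @param config Optional [mpd_class_config()] for the expected class.
#' @return One-row data frame with a `truth_type` column (`"analytic"` or
#'   `"derived"`).
#' @export
shape_truth <- function(shape, config = NULL) {
  p <- shape$params
  tt <- "analytic"
  if (shape$kind == "disc") {
    area <- pi * p$r^2; fmax <- 2 * p$r; fmin <- 2 * p$r; sol <- 1
  } else if (shape$kind == "ellipse") {
    area <- pi * p$a * p$b; fmax <- 2 * p$a; fmin <- 2 * p$b; sol <- 1
  } else if (shape$kind == "rect") {
    area <- p$w * p$h
    fmax <- sqrt(p$w^2 + p$h^2); fmin <- min(p$w, p$h); sol <- 1
  } else if (shape$kind == "cross") {
    area <- 2 * p$l * p$w - p$w^2
    hull <- p$l^2 - (p$l - p$w)^2 / 2
    fmax <- sqrt(p$l^2 + p$w^2)
    fmin <- (p$l + p$w) / sqrt(2)
    sol <- area / hull
  } else {                      # blob: numeric truth at 10x supersampling
    tt <- "derived"
    fine <- mpd_calibration(0.1)
    R <- .shape_radius(shape)
    n <- ceiling(2 * (R + 1) / fine$um_per_px)
    cc <- ((seq_len(n)) - 0.5) * fine$um_per_px - (R + 1)
    gx <- rep(cc, each = n); gy <- rep(cc, times = n)
    inside <- .shape_inside(shape, gx, gy)
    px <- cbind(row = rep(seq_len(n), times = n)[inside],
                col = rep(seq_len(n), each = n)[inside])
    part <- structure(list(index = 1L, pixels = px, pixel_count = nrow(px),
                           touches_border = FALSE, connectivity = 8),
                      class = "mpd_particle")
    m <- particle_metrics(trace_particle(part), fine)
    area <- m$area_um2; fmax <- m$feret_max_um; fmin <- m$feret_min_um
    sol <- m$solidity
  }
  ar <- fmax / fmin
  mn <- morphology_number(area, sol, fmax, ar)
  cls <- if (is.null(config)) NA_character_ else classify_area(area, config)
  data.frame(kind = shape$kind, area_um2 = area, feret_max_um = fmax,
             feret_min_um = fmin, aspect_ratio = ar, solidity = sol,
             morphology_number = mn, expected_class = cls,
             truth_type = tt, stringsAsFactors = FALSE)
}

#' Rasterize one synthetic shape
#'
#' Pixel-centre inclusion test against the analytic shape: pixel `(r, c)` is
#' foreground iff its centre, in um, lies inside the (rotated, translated)
#' shape. Simple, unbiased, and convergent: measured descriptors approach
#' the analytic truth as resolution grows.
#'
#' @param shape An `mpd_shape`.
#' @param cal An [mpd_calibration()].
#' @param canvas_px Optional `c(H, W)`; pixels outside are clipped.
#' @return Two-column matrix of row/col pixel coordinates.
#' @export
make_shape <- function(shape, cal, canvas_px = NULL) {
  u <- cal$um_per_px
  R <- .shape_radius(shape)
  cx <- shape$centre[1L]; cy <- shape$centre[2L]
  c_lo <- max(1L, floor((cx - R) / u)); c_hi <- ceiling((cx + R) / u) + 1L
  r_lo <- max(1L, floor((cy - R) / u)); r_hi <- ceiling((cy + R) / u) + 1L
  if (!is.null(canvas_px)) {
    r_hi <- min(r_hi, canvas_px[1L]); c_hi <- min(c_hi, canvas_px[2L])
  }
  if (r_hi < r_lo || c_hi < c_lo) return(cbind(row = integer(), col = integer()))
  rs <- r_lo:r_hi; cs <- c_lo:c_hi
  px_x <- (rep(cs, each = length(rs)) - 0.5) * u - cx
  px_y <- (rep(rs, times = length(cs)) - 0.5) * u - cy
  if (shape$rotation != 0) {
    th <- -shape$rotation * pi / 180
    xr <- px_x * cos(th) - px_y * sin(th)
    yr <- px_x * sin(th) + px_y * cos(th)
  } else {
    xr <- px_x; yr <- px_y
  }
  inside <- .shape_inside(shape, xr, yr)
  cbind(row = rep(rs, times = length(cs))[inside],
        col = rep(cs, each = length(rs))[inside])
}

#' Render a synthetic culture scene
#'
#' Rasterizes a set of non-overlapping shapes onto a dark canvas (default
#' background 20, foreground per shape, emulating light-on-dark capture),
#' optionally adds seeded Gaussian noise, and returns the 8-bit RGB record
#' together with a manifest of each shape's ground truth and expected class.
#' Identical spec and seed give a byte-identical raster.
#'
#' @param shapes List of `mpd_shape` objects.
#' @param canvas_px `c(H, W)` canvas size in pixels.
#' @param cal An [mpd_calibration()].
#' @param config Optional [mpd_class_config()] for expected classes.
#' @param background Background grey level (default 20).
#' @param noise_sd Additive Gaussian noise standard deviation in grey
#'   levels (default 0 = none).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param allow_border_overlap If `FALSE` (default), a shape extending past
#'   the canvas is an error; if `TRUE` it is clipped (for border-exclusion
#'   tests).
#' @param allow_overlap If `FALSE` (default), overlapping shapes are an
#'   error.
#' @param path Optional PNG output path; when given, the scene and a JSON
#'   manifest (`<path>.manifest.json`) are written.
#' @return List with `record` (`mpd_image`), `manifest` (data frame, one row
#'   per shape, with `n_pixels` rasterized) and `mask` (the noise-free
#'   foreground mask).
#' @export
render_scene <- function(shapes, canvas_px, cal, config = NULL,
                         background = 20, noise_sd = 0, seed = 1L,
                         allow_border_overlap = FALSE,
                         allow_overlap = FALSE, path = NULL) {
  H <- canvas_px[1L]; W <- canvas_px[2L]
  u <- cal$um_per_px
  grey <- matrix(as.integer(background), H, W)
  covered <- matrix(FALSE, H, W)
  manifest <- NULL
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    R <- .shape_radius(s)
    if (!allow_border_overlap &&
        (s$centre[1L] - R < 0 || s$centre[1L] + R > W * u ||
         s$centre[2L] - R < 0 || s$centre[2L] + R > H * u))
      stop(sprintf("shape %d extends past the canvas; set allow_border_overlap",
                   i), call. = FALSE)
    px <- make_shape(s, cal, canvas_px = c(H, W))
    idx <- cbind(px[, 1L], px[, 2L])
    if (!allow_overlap && any(covered[idx]))
      stop(sprintf("shape %d overlaps an earlier shape", i), call. = FALSE)
    covered[idx] <- TRUE
    grey[idx] <- s$intensity
    tr <- shape_truth(s, config)
    tr$shape_id <- i
    tr$n_pixels <- nrow(px)
    manifest <- rbind(manifest, tr)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    grey <- grey + round(rnorm(H * W, sd = noise_sd))
    grey <- matrix(as.integer(pmin(pmax(grey, 0L), 255L)), H, W)
  }
  raster <- array(0L, c(H, W, 3L))
  raster[, , 1L] <- grey; raster[, , 2L] <- grey; raster[, , 3L] <- grey
  record <- structure(list(path = if (is.null(path)) NA_character_ else path,
                           subdir = ".", raster = raster),
                      class = "mpd_image")
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(raster / 255, path)
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(record = record, manifest = manifest, mask = covered)
}

#' The standard validation scene
#'
#' A fixed scene used across the test suite and documentation: three
#' pellet-sized discs, five dispersed-sized rectangles, two sub-artefact
#' specks and, optionally, one disc straddling the canvas edge. At the
#' default 1 um/px on a 512 x 512 canvas every interior shape classifies
#' unambiguously under the default cut-offs.
#'
#' @param with_border_disc Include the edge-straddling disc (default TRUE).
#' @param cal Calibration, default 1 um/px.
#' @param canvas_px Canvas size, default `c(512, 512)`.
#' @param noise_sd,seed Passed to [render_scene()].
#' @return As [render_scene()].
#' @export
standard_scene <- function(with_border_disc = TRUE, cal = mpd_calibration(1),
                           canvas_px = c(512, 512), noise_sd = 0, seed = 1L) {
  u <- cal$um_per_px
  sc <- function(x, y) c(x * u, y * u)   # positions scale with resolution
  shapes <- list(
    synth_disc(20 * u, sc(80, 80)),            # pellets (area >= 500 um^2
    synth_disc(28 * u, sc(240, 90)),           # at 1 um/px)
    synth_disc(16 * u, sc(420, 70)),
    synth_rect(10 * u, 14 * u, sc(70, 230)),   # dispersed fragments
    synth_rect(20 * u, 11 * u, sc(180, 240), rotation = 30),
    synth_rect(9 * u, 12 * u, sc(300, 230)),
    synth_rect(16 * u, 13 * u, sc(410, 250), rotation = 60),
    synth_rect(11 * u, 10 * u, sc(90, 380)),
    synth_disc(4 * u, sc(220, 400)),           # sub-artefact specks
    synth_disc(3 * u, sc(320, 390)))
  if (with_border_disc)
    shapes <- c(shapes, list(synth_disc(25 * u, sc(505, 440))))
  render_scene(shapes, canvas_px, cal, config = mpd_class_config(),
               noise_sd = noise_sd, seed = seed,
               allow_border_overlap = with_border_disc)
}

#' Generate a nested synthetic input tree
#'
#' Writes a seed-reproducible directory tree of synthetic culture images,
#' exercising the sub-directory traversal of the analysis workflow, together
#' with a JSON manifest of every shape's ground truth and the analytic
#' pelleted fraction expected per sub-directory.
#'
#' @param root Output directory (created if needed).
#' @param n_subdirs,images_per_subdir Tree layout.
#' @param composition Named counts per image, e.g.
#'   `c(pellet = 3, dispersed = 5, artefact = 2)`.
#' @param seed Integer seed; the whole tree is a deterministic function of
#'   it.
#' @param cal Calibration (default 1 um/px).
#' @param canvas_px Canvas size per image (default 512 x 512).
#' @param noise_sd Additive noise level (default 0).
#' @return List with `root`, `manifest` (per-shape data frame with subdir
#'   and image columns) and `expected_fractions` (data frame subdir /
#'   expected pelleted percentage).
#' @export
make_test_tree <- function(root, n_subdirs = 2, images_per_subdir = 3,
                           composition = c(pellet = 3, dispersed = 5,
                                           artefact = 2),
                           seed = 1L, cal = mpd_calibration(1),
                           canvas_px = c(512, 512), noise_sd = 0) {
  if (n_subdirs < 1 || images_per_subdir < 1)
    stop("need at least one sub-directory and one image each", call. = FALSE)
  comp <- composition
  for (nm in c("pellet", "dispersed", "artefact"))
    if (is.na(comp[nm])) comp[nm] <- 0
  n_shapes <- sum(comp)
  # 4 x 4 grid of placement cells keeps shapes apart and off the border
  if (n_shapes > 16)
    stop("at most 16 shapes per image", call. = FALSE)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  u <- cal$um_per_px
  H <- canvas_px[1L]; W <- canvas_px[2L]
  cell_h <- H / 4; cell_w <- W / 4
  manifest <- NULL
  config <- mpd_class_config()
  for (d in seq_len(n_subdirs)) {
    subdir <- sprintf("culture_%02d", d)
    dir.create(file.path(root, subdir), showWarnings = FALSE)
    for (im in seq_len(images_per_subdir)) {
      cells <- sample(16L, n_shapes)
      shapes <- vector("list", n_shapes)
      kinds <- rep(c("pellet", "dispersed", "artefact"),
                   times = c(comp["pellet"], comp["dispersed"],
                             comp["artefact"]))
      for (k in seq_len(n_shapes)) {
        cell <- cells[k] - 1L
        cx <- ((cell %% 4L) + 0.5) * cell_w + runif(1, -8, 8)
        cy <- ((cell %/% 4L) + 0.5) * cell_h + runif(1, -8, 8)
        centre <- c(cx * u, cy * u)
        shapes[[k]] <- switch(kinds[k],
          pellet = synth_disc(runif(1, 15, 30) * u, centre),
          dispersed = synth_rect(runif(1, 12, 20) * u, runif(1, 10, 12) * u,
                                 centre, rotation = runif(1, 0, 90)),
          artefact = synth_disc(runif(1, 2, 4) * u, centre))
      }
      img_name <- sprintf("img_%02d.png", im)
      path <- file.path(root, subdir, img_name)
      sc <- render_scene(shapes, canvas_px, cal, config = config,
                         noise_sd = noise_sd, seed = seed + 97L * d + im,
                         path = path)
      m <- sc$manifest
      m$subdir <- subdir
      m$image <- img_name
      manifest <- rbind(manifest, m)
    }
  }
  keep <- manifest$expected_class != "artefact"
  pel <- manifest$expected_class == "pellet" & keep
  agg_p <- tapply(manifest$area_um2[pel], manifest$subdir[pel], sum)
  agg_t <- tapply(manifest$area_um2[keep], manifest$subdir[keep], sum)
  subs <- sort(unique(manifest$subdir))
  expected <- data.frame(
    subdir = subs,
    expected_pellet_fraction_pct =
      100 * as.numeric(agg_p[subs]) / as.numeric(agg_t[subs]),
    stringsAsFactors = FALSE)
  jsonlite::write_json(list(manifest = manifest,
                            expected_fractions = expected),
                       file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(root = root, manifest = manifest, expected_fractions = expected)
}
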