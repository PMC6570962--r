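make_particle <- function(pixels) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  p <- structure(list(index = 1L, pixels = pixels,
                      pixel_count = nrow(pixels), touches_border = FALSE,
                      connectivity = 8), class = "mpd_particle")
  pelletmorph:::trace_particle(p)
}

disc_pixels <- function(r_px, centre = c(0, 0)) {
  span <- ceiling(r_px) + 1
  g <- as.matrix(expand.grid(row = -span:span, col = -span:span))
  keep <- (g[, 1] - 0.5)^2 + (g[, 2] - 0.5)^2 <= r_px^2
  px <- g[keep, , drop = FALSE] + rep(centre + span + 1, each = sum(keep))
  colnames(px) <- NULL
  px
}

test_that("area scales with the square of the calibration", {
  p <- make_particle(as.matrix(expand.grid(1:10, 1:10)))
  expect_equal(area_um2(p, mpd_calibration(1)), 100)
  expect_equal(area_um2(p, mpd_calibration(2)), 400)
})

test_that("rasterized disc area approaches the analytic circle area", {
  p <- make_particle(disc_pixels(50))
  expect_equal(area_um2(p, mpd_calibration(1)), pi * 50^2, tolerance = 0.02)
})

test_that("Feret extremes match closed forms for simple shapes", {
  cal <- mpd_calibration(1)
  # single pixel: diagonal sqrt(2), width 1
  f1 <- feret_extremes(make_particle(cbind(3L, 3L))$hull, cal)
  expect_equal(unname(f1), c(sqrt(2), 1))

  # 10 x 20 axis-aligned rectangle of pixels
  px <- as.matrix(expand.grid(1:10, 1:20))
  f2 <- feret_extremes(make_particle(px)$hull, cal)
  expect_equal(unname(f2), c(sqrt(10^2 + 20^2), 10))

  # calibration scales both linearly
  f3 <- feret_extremes(make_particle(px)$hull, mpd_calibration(2.5))
  expect_equal(unname(f3), 2.5 * unname(f2))

  # rasterized disc radius 50: diameter within 2%, near-isotropic
  fd <- feret_extremes(make_particle(disc_pixels(50))$hull, cal)
  expect_equal(unname(fd[1]), 100, tolerance = 0.02)
  expect_equal(unname(fd[1] / fd[2]), 1, tolerance = 0.02)
})

test_that("rotating calipers agree with brute force on random hulls", {
  set.seed(100)
  for (i in 1:100) {
    h <- random_hull(sample(5:200, 1))
    f <- feret_extremes(h, mpd_calibration(1))
    expect_equal(unname(f[1]), brute_feret_max(h), tolerance = 1e-12)
    expect_equal(unname(f[2]), brute_feret_min(h), tolerance = 1e-3)
  }
})

test_that("aspect ratio and solidity follow their definitions", {
  expect_equal(aspect_ratio(100, 100), 1)
  expect_equal(aspect_ratio(22.361, 10), 2.2361)
  expect_equal(aspect_ratio(200, 100), 2)
  expect_error(aspect_ratio(10, 0), "positive")

  expect_equal(solidity(6, 6), 1)
  expect_equal(solidity(5, 7), 5 / 7)
  expect_error(solidity(8, 7), "hull")
  expect_error(solidity(0, 7), "positive")

  # cross of two 10x30 bars: area 500, hull 700 (30^2 minus four 50-px^2
  # corner triangles), solidity 5/7
  p <- make_particle(cross_pixels(30, 10))
  expect_equal(p$pixel_count, 500)
  expect_equal(polygon_area(p$hull), 700)
  m <- particle_metrics(p, mpd_calibration(1))
  expect_equal(m$solidity, 5 / 7)
})

test_that("morphology number anchors: circle 1, square, vanishing line 0", {
  # ideal disc, any radius
  for (r in c(0.5, 1, 17, 420)) {
    expect_equal(morphology_number(pi * r^2, 1, 2 * r, 1), 1)
  }
  # ideal square, side s: area s^2, feret s*sqrt(2), AR sqrt(2)
  s <- 100
  mn_square <- morphology_number(s^2, 1, s * sqrt(2), sqrt(2))
  expect_equal(mn_square, 2 / (sqrt(pi) * 2), tolerance = 1e-12)
  expect_equal(round(mn_square, 4), 0.5642)
  # fixed-length rectangle, width -> 0: MN -> 0 monotonically
  L <- 1000
  mn_w <- vapply(c(1e-1, 1e-3, 1e-6), function(w) {
    f <- sqrt(L^2 + w^2)
    morphology_number(L * w, 1, f, f / w)
  }, numeric(1))
  expect_true(all(diff(mn_w) < 0))
  expect_lt(mn_w[3], 1e-10)
  expect_error(morphology_number(0, 1, 1, 1), "positive")
})

test_that("dimensionless descriptors are calibration-invariant", {
  px <- cross_pixels(30, 10)
  p <- make_particle(px)
  m1 <- particle_metrics(p, mpd_calibration(1))
  m2 <- particle_metrics(p, mpd_calibration(2))
  expect_equal(m2$area_um2, 4 * m1$area_um2)
  expect_equal(m2$feret_max_um, 2 * m1$feret_max_um)
  expect_equal(m2$feret_min_um, 2 * m1$feret_min_um)
  expect_equal(m2$aspect_ratio, m1$aspect_ratio)
  expect_equal(m2$solidity, m1$solidity)
  expect_equal(m2$morphology_number, m1$morphology_number)
})

test_that("descriptors are stable under rotation of an ellipse", {
  cal <- mpd_calibration(1)
  ms <- lapply(seq(0, 90, by = 15), function(th) {
    px <- make_shape(synth_ellipse(80, 40, c(120, 120), rotation = th), cal)
    particle_metrics(make_particle(px), cal)
  })
  for (col in c("area_um2", "feret_max_um", "feret_min_um",
                "aspect_ratio", "solidity", "morphology_number")) {
    v <- vapply(ms, `[[`, numeric(1), col)
    expect_lt(diff(range(v)) / mean(v), 0.03)
  }
})

test_that("MN is at most ~1 on convex shapes and maximal for the disc", {
  cal <- mpd_calibration(1)
  shapes <- list(synth_disc(40, c(100, 100)),
                 synth_ellipse(50, 30, c(100, 100), 20),
                 synth_rect(60, 25, c(100, 100), 45),
                 synth_rect(30, 30, c(100, 100)))
  mns <- vapply(shapes, function(s) {
    particle_metrics(make_particle(make_shape(s, cal)), cal)$morphology_number
  }, numeric(1))
  expect_true(all(mns > 0 & mns <= 1.02))
  expect_equal(which.max(mns), 1L)
})
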