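test_that("shape truths match closed forms and expected classes", {
  cfg <- mpd_class_config()
  t1 <- shape_truth(synth_disc(15, c(50, 50)), cfg)
  expect_equal(t1$area_um2, pi * 225, tolerance = 1e-12)
  expect_equal(t1$area_um2, 706.86, tolerance = 1e-4)
  expect_equal(t1$morphology_number, 1)
  expect_equal(t1$expected_class, "pellet")

  t2 <- shape_truth(synth_rect(10, 20, c(50, 50)), cfg)
  expect_equal(t2$area_um2, 200)
  expect_equal(t2$feret_max_um, sqrt(500))
  expect_equal(t2$feret_min_um, 10)
  expect_equal(t2$expected_class, "dispersed")

  t3 <- shape_truth(synth_disc(5, c(50, 50)), cfg)
  expect_equal(t3$area_um2, 78.54, tolerance = 1e-4)
  expect_equal(t3$expected_class, "artefact")

  t4 <- shape_truth(synth_cross(30, 10, c(50, 50)), cfg)
  expect_equal(t4$area_um2, 500)
  expect_equal(t4$solidity, 5 / 7)

  # blob truth is numeric but must satisfy the metric invariants
  t5 <- shape_truth(synth_blob(rbind(c(-8, 0), c(8, 0), c(0, 8)),
                               c(10, 10, 9), c(50, 50)), cfg)
  expect_equal(t5$truth_type, "derived")
  expect_true(t5$solidity > 0 && t5$solidity <= 1)
  expect_gte(t5$aspect_ratio, 1)
})

test_that("rasterized discs converge to analytic truth with radius", {
  cal <- mpd_calibration(1)
  measure_disc <- function(r) {
    px <- make_shape(synth_disc(r, c(r + 5, r + 5)), cal)
    p <- structure(list(index = 1L, pixels = px, pixel_count = nrow(px),
                        touches_border = FALSE, connectivity = 8),
                   class = "mpd_particle")
    particle_metrics(pelletmorph:::trace_particle(p), cal)
  }
  m30 <- measure_disc(30); m150 <- measure_disc(150)
  expect_equal(m30$area_um2, pi * 30^2, tolerance = 0.02)
  expect_equal(m150$area_um2, pi * 150^2, tolerance = 0.005)
  expect_equal(m150$feret_max_um, 300, tolerance = 0.005)
  # the pixel-corner convention overshoots a caliper diameter by about one
  # pixel (half a pixel per side), so the Feret error is ~ 1.2/2r
  expect_equal(m30$feret_max_um, 60, tolerance = 0.021)
  # MN compounds the corner-hull inflation of solidity, Feret and aspect
  # ratio, giving a systematic ~ -1.5 r^-1 relative bias; assert the honest
  # envelope and that the bias shrinks with radius
  expect_equal(m30$morphology_number, 1, tolerance = 0.07)
  expect_equal(m150$morphology_number, 1, tolerance = 0.02)
  expect_lt(abs(m150$morphology_number - 1), abs(m30$morphology_number - 1))
})

test_that("scene rendering is deterministic and guards overlap/border", {
  cal <- mpd_calibration(1)
  shapes <- list(synth_disc(20, c(60, 60)), synth_rect(10, 14, c(130, 60)))
  s1 <- render_scene(shapes, c(200, 200), cal, noise_sd = 3, seed = 5)
  s2 <- render_scene(shapes, c(200, 200), cal, noise_sd = 3, seed = 5)
  expect_identical(s1$record$raster, s2$record$raster)
  s3 <- render_scene(shapes, c(200, 200), cal, noise_sd = 3, seed = 6)
  expect_false(identical(s1$record$raster, s3$record$raster))

  expect_error(render_scene(list(synth_disc(20, c(60, 60)),
                                 synth_disc(20, c(70, 60))),
                            c(200, 200), cal), "overlap")
  expect_error(render_scene(list(synth_disc(20, c(5, 60))),
                            c(200, 200), cal), "border")
  # clipped border shape allowed when requested
  sb <- render_scene(list(synth_disc(20, c(5, 60))), c(200, 200), cal,
                     allow_border_overlap = TRUE)
  expect_lt(sb$manifest$n_pixels, pi * 400)
})

test_that("every rendered shape appears once in the manifest with a class", {
  sc <- standard_scene()
  expect_equal(nrow(sc$manifest), 11)
  expect_equal(sc$manifest$shape_id, 1:11)
  expect_true(all(sc$manifest$expected_class %in%
                    c("pellet", "dispersed", "artefact")))
  expect_equal(sum(sc$manifest$n_pixels), sum(sc$mask))
})

test_that("class counts on the standard scene survive noise up to sd 10", {
  base <- standard_scene()
  count_classes <- function(scene) {
    grey <- to_red_channel(enhance_contrast(scene$record$raster))
    mask <- binarize(grey, "auto")
    ps <- apply_border_policy(label_particles(mask, 8, trace = FALSE),
                              "exclude_all")
    areas <- vapply(ps, function(p) area_um2(p, mpd_calibration(1)),
                    numeric(1))
    table(factor(classify_area(areas, mpd_class_config()),
                 levels = c("pellet", "dispersed", "artefact")))
  }
  ref <- count_classes(base)
  expect_equal(unname(c(ref)), c(3L, 5L, 2L))
  for (sd in c(5, 10)) {
    noisy <- standard_scene(noise_sd = sd, seed = 23)
    expect_equal(count_classes(noisy), ref, info = paste("sd", sd))
  }
})

test_that("test trees are reproducible and carry analytic fractions", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t1 <- make_test_tree(file.path(d1, "t"), 2, 3, seed = 11)
  t2 <- make_test_tree(file.path(d2, "t"), 2, 3, seed = 11)
  f1 <- list.files(t1$root, recursive = TRUE)
  expect_equal(f1, list.files(t2$root, recursive = TRUE))
  expect_equal(sum(grepl("png$", f1)), 6)
  for (f in grep("png$", f1, value = TRUE))
    expect_identical(readBin(file.path(t1$root, f), "raw", 1e6),
                     readBin(file.path(t2$root, f), "raw", 1e6))
  expect_identical(t1$manifest$area_um2, t2$manifest$area_um2)
  expect_equal(nrow(t1$expected_fractions), 2)
  expect_true(all(t1$expected_fractions$expected_pellet_fraction_pct > 0 &
                  t1$expected_fractions$expected_pellet_fraction_pct < 100))

  # all-pellet composition pins the expected fraction at 100%
  t3 <- make_test_tree(file.path(d1, "p"), 1, 1,
                       composition = c(pellet = 4), seed = 2)
  expect_equal(t3$expected_fractions$expected_pellet_fraction_pct, 100)
  expect_error(make_test_tree(file.path(d1, "z"), 0, 1), "at least")
})
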