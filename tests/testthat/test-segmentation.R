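test_that("labelling separates disjoint components and respects connectivity", {
  m <- matrix(FALSE, 20, 20)
  m[3:6, 3:6] <- TRUE
  m[12:16, 10:15] <- TRUE
  ps <- label_particles(m, 8, trace = FALSE)
  expect_length(ps, 2)
  expect_equal(vapply(ps, `[[`, numeric(1), "pixel_count"), c(16, 30))

  # two pixels touching only diagonally
  d <- matrix(FALSE, 4, 4)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_length(label_particles(d, 8, trace = FALSE), 1)
  expect_length(label_particles(d, 4, trace = FALSE), 2)

  expect_length(label_particles(matrix(FALSE, 5, 5)), 0)
})

test_that("labelling matches a naive flood-fill oracle on random masks", {
  set.seed(42)
  for (trial in 1:25) {
    H <- sample(4:16, 1); W <- sample(4:16, 1)
    m <- random_mask(H, W)
    for (conn in c(4, 8)) {
      got <- pelletmorph:::label_components_cpp(m, as.integer(conn))
      expect_identical(got, flood_fill_oracle(m, conn),
                       info = sprintf("trial %d conn %d", trial, conn))
    }
  }
})

test_that("particle pixel counts partition the foreground", {
  set.seed(7)
  m <- random_mask(30, 30, 0.5)
  for (conn in c(4, 8)) {
    ps <- label_particles(m, conn, trace = FALSE)
    expect_equal(sum(vapply(ps, `[[`, numeric(1), "pixel_count")), sum(m))
  }
})

test_that("border policy removes edge-touching particles, keeping indices", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE          # interior
  m[6:8, 10:12] <- TRUE        # touches right edge
  m[1, 6] <- TRUE              # single pixel on the top row
  ps <- label_particles(m, 8, trace = FALSE)
  expect_length(ps, 3)
  kept <- apply_border_policy(ps, "exclude_all")
  expect_length(kept, 1)
  expect_false(kept[[1]]$touches_border)
  # geometry and index of the survivor unchanged
  orig <- Filter(function(p) !p$touches_border, ps)[[1]]
  expect_identical(kept[[1]]$pixels, orig$pixels)
  expect_identical(kept[[1]]$index, orig$index)
  expect_length(apply_border_policy(ps, "keep_all"), 3)
})

test_that("outline tracing follows the pixel-corner convention", {
  # single pixel: unit square
  o1 <- trace_outline(cbind(5L, 7L))
  expect_equal(nrow(o1), 4)
  expect_equal(polygon_area(o1), 1)
  expect_gt(attr(o1, "signed_area"), 0)

  # 2 x 3 rectangle
  px <- as.matrix(expand.grid(row = 4:5, col = 2:4))
  colnames(px) <- NULL
  o2 <- trace_outline(px)
  expect_equal(polygon_area(o2), 6)

  # plus sign of five unit pixels: 12 vertices, area 5 (shoelace oracle)
  plus <- rbind(c(2, 2), c(1, 2), c(3, 2), c(2, 1), c(2, 3))
  o3 <- trace_outline(plus)
  expect_equal(nrow(o3), 12)
  expect_equal(polygon_area(o3), 5)
  expect_equal(polygon_area(o3), shoelace_oracle(o3))

  # disconnected input violates the contract
  expect_error(trace_outline(rbind(c(1, 1), c(5, 5)), connectivity = 8),
               "connected")
})

test_that("outline area accounts for pixel count and holes", {
  # ring with a one-pixel hole: outer polygon spans the full 3x3 block
  ring <- as.matrix(expand.grid(row = 1:3, col = 1:3))
  colnames(ring) <- NULL
  ring <- ring[!(ring[, 1] == 2 & ring[, 2] == 2), ]
  o <- trace_outline(ring)
  expect_equal(polygon_area(o), 9)
  expect_equal(attr(o, "n_holes"), 1)

  # diagonal pair under 8-connectivity: one loop, area 2
  o2 <- trace_outline(rbind(c(1, 1), c(2, 2)), connectivity = 8)
  expect_equal(polygon_area(o2), 2)
})

test_that("convex hull is minimal, idempotent, and matches brute force", {
  # convex rectangle outline is its own hull
  px <- as.matrix(expand.grid(row = 1:2, col = 1:3))
  colnames(px) <- NULL
  o <- trace_outline(px)
  h <- convex_hull(o)
  expect_equal(polygon_area(h), 6)

  # plus sign: octagonal hull of area 7 = 3x3 minus 4 half-cells
  plus <- rbind(c(2, 2), c(1, 2), c(3, 2), c(2, 1), c(2, 3))
  hp <- convex_hull(trace_outline(plus))
  expect_equal(nrow(hp), 8)
  expect_equal(polygon_area(hp), 7)

  # L-shape of three pixels: hull strictly larger than its area 3
  L <- rbind(c(1, 1), c(2, 1), c(2, 2))
  hl <- convex_hull(trace_outline(L))
  expect_gt(polygon_area(hl), 3)

  # idempotence and brute-force vertex agreement on random point sets
  set.seed(9)
  for (i in 1:20) {
    pts <- cbind(sample(0:30, 12, TRUE), sample(0:30, 12, TRUE))
    h1 <- convex_hull(pts)
    expect_equal(polygon_area(h1), shoelace_oracle(brute_hull(pts)))
    h2 <- convex_hull(h1)
    expect_equal(sort(paste(h2[, 1], h2[, 2])), sort(paste(h1[, 1], h1[, 2])))
  }
})

test_that("hull contains the outline and exceeds its area for concave shapes", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_mask(12, 12, 0.55)
    ps <- label_particles(m, 8)
    for (p in ps) {
      expect_gte(polygon_area(p$hull) + 1e-12, polygon_area(p$outline))
      # the outer polygon covers every pixel (holes included), so its area
      # is at least the pixel count, with equality iff the particle is
      # hole-free
      expect_gte(polygon_area(p$outline) + 1e-12, p$pixel_count)
      if (attr(p$outline, "n_holes") == 0 && p$pixel_count > 1)
        expect_equal(polygon_area(p$outline), p$pixel_count)
    }
  }
})
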