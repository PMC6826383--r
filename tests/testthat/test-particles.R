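test_that("labeling respects the chosen connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- m[3, 3] <- TRUE
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
  expect_equal(max(label_components(matrix(FALSE, 4, 4), 8)), 0)
  expect_equal(nrow(measure_particles(matrix(FALSE, 4, 4))), 0)
})

test_that("a field of disjoint disks yields one region per disk", {
  shapes <- list()
  for (i in 1:5) for (j in 1:5)
    shapes[[length(shapes) + 1]] <-
      shape_spec("disk", row = i * 22, col = j * 22, radius = 5)
  fx <- fixture_mask(shapes, dim = c(140, 140))
  expect_equal(max(label_components(fx$mask)), 25)
})

test_that("rectangle measurements match closed-form geometry", {
  p <- measure_particles(digital_rect(10, 5))
  expect_equal(p$area_px, 50)
  expect_equal(p$perimeter_px, 30, tolerance = 0.02)
  expect_equal(p$feret_px, sqrt(125), tolerance = 0.02)
  expect_equal(p$hull_area_px, 50)
  expect_equal(p$solidity, 1.0)
})

test_that("digital disk measurements respect the estimator accuracy bounds", {
  p <- measure_particles(digital_disk(20))
  expect_equal(p$area_px, pi * 400, tolerance = 0.01)
  expect_equal(p$perimeter_px, 2 * pi * 20, tolerance = 0.02)
  expect_gte(p$circularity, 0.95)
  expect_lte(p$circularity, 1.0)
  # the pixel union protrudes beyond the continuous disk, so a containing
  # hull is a few percent larger than pi r^2 and solidity sits near 0.96
  expect_gte(p$solidity, 0.95)
  expect_equal(p$hull_area_px, pi * 400, tolerance = 0.06)
})

test_that("perimeter estimator stays within 2% for disks >= 10 px radius and rectangles", {
  set.seed(9)
  for (r in c(10, 13, 20, 27, 40)) {
    off <- runif(2, -0.5, 0.5)
    p <- measure_particles(digital_disk(r, off = off))
    expect_lt(abs(p$perimeter_px / (2 * pi * r) - 1), 0.02)
  }
  for (wh in list(c(10, 10), c(25, 10), c(60, 14))) {
    p <- measure_particles(digital_rect(wh[1], wh[2]))
    expect_lt(abs(p$perimeter_px / (2 * sum(wh)) - 1), 0.02)
  }
})

test_that("single pixel and plus pentomino match hand-computed values", {
  p1 <- measure_particles({m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE; m})
  expect_equal(p1$area_px, 1)
  expect_equal(p1$circularity, 1.0)      # capped
  expect_equal(p1$feret_px, sqrt(2))
  expect_equal(p1$hull_area_px, 1)
  expect_equal(p1$solidity, 1.0)
  p2 <- measure_particles(plus_pentomino_mask())
  expect_equal(p2$area_px, 5)
  expect_equal(p2$hull_area_px, 7)
  expect_equal(p2$solidity, 5 / 7)
  expect_equal(p2$feret_px, sqrt(10))
})

test_that("circularity formula has the right closed-form anchors", {
  r <- 10
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1.0)    # perfect circle
  s <- 7
  expect_equal(circularity(s^2, 4 * s), pi / 4)           # square
  expect_equal(circularity(100, 202), 4 * pi * 100 / 202^2)  # elongated strip
  expect_lt(circularity(100, 202), 0.031)
  expect_equal(circularity(10, 1), 1.0)                   # capped
  expect_error(circularity(0, 5), "positive")
  expect_error(circularity(5, -1), "positive")
})

test_that("solidity formula is capped and rejects degenerate input", {
  expect_equal(solidity(50, 50), 1.0)
  expect_equal(solidity(5, 7), 5 / 7)
  expect_equal(solidity(8, 7.5), 1.0)   # rasterization tolerance -> capped
  expect_error(solidity(0, 1), "positive")
})

test_that("measured elongated strip has near-zero circularity", {
  m <- matrix(FALSE, 8, 108)
  m[4, 5:104] <- TRUE
  p <- measure_particles(m)
  expect_equal(p$circularity, 4 * pi * 100 / 202^2, tolerance = 0.07)
})

test_that("max_feret equals the exhaustive pairwise maximum", {
  set.seed(13)
  for (rep in 1:10) {
    pts <- matrix(runif(40, 0, 50), ncol = 2)
    d <- as.matrix(dist(pts))
    expect_equal(max_feret(pts), max(d))
  }
  expect_equal(max_feret(matrix(c(1, 1), 1, 2)), 0)
})

test_that("feret diameter is never below the equal-area disk bound", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(runif(400) < 0.45, 20, 20)
    p <- measure_particles(m)
    if (nrow(p)) expect_true(all(p$feret_px >= sqrt(p$area_px / pi) - 1e-9))
  }
})

test_that("filters are inclusive at both bounds and preserve order", {
  parts <- data.frame(particle_id = 1:4, area_px = c(20, 19, 100, 50),
                      circularity = c(0.8, 0.9, 0.79, 1.0))
  f <- apply_filter(parts, filter_spec(circularity_min = 0.8, size_min_px = 20))
  expect_equal(f$particle_id, c(1, 4))     # 0.8 and area 20 are retained
  f2 <- apply_filter(parts, filter_spec(circularity_min = 0, size_min_px = 19,
                                        size_max_px = 50))
  expect_equal(f2$particle_id, c(1, 2, 4)) # order preserved, bounds inclusive
  f3 <- apply_filter(parts, filter_spec(circularity_min = 1.0, size_min_px = 100))
  expect_equal(nrow(f3), 0)
})

test_that("raising filter thresholds never increases the retained count", {
  set.seed(17)
  for (rep in 1:5) {
    m <- matrix(runif(2500) < 0.4, 50, 50)
    parts <- measure_particles(m)
    counts_c <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(cm)
      nrow(apply_filter(parts, filter_spec(circularity_min = cm,
                                           size_min_px = 1))), numeric(1))
    expect_true(all(diff(counts_c) <= 0))
    counts_s <- vapply(c(1, 10, 20, 50, 100), function(sm)
      nrow(apply_filter(parts, filter_spec(size_min_px = sm))), numeric(1))
    expect_true(all(diff(counts_s) <= 0))
    # conservation: no filtered subset exceeds the total foreground area
    expect_lte(sum(apply_filter(parts, filter_spec(size_min_px = 1))$area_px),
               sum(m))
  }
})

test_that("fill_holes closes interior background only", {
  m <- matrix(FALSE, 9, 9)
  m[3:7, 3:7] <- TRUE
  m[5, 5] <- FALSE
  filled <- fill_holes(m)
  expect_equal(sum(filled), 25)
  expect_equal(sum(fill_holes(digital_rect(5, 5))), 25)  # no hole: unchanged
})

test_that("Feret micrometers scale with the physical pixel size", {
  fx <- fixture_mask(shape_spec("rectangle", row = 10, col = 10,
                                width = 20, height = 6),
                     dim = c(40, 50), pixel_size_um = 1.4)
  p <- measure_particles(fx$mask)
  expect_equal(p$feret_um, p$feret_px * 1.4)
  p2 <- measure_particles(fx$mask, pixel_size_um = 2)
  expect_equal(p2$feret_um, p2$feret_px * 2)
})
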