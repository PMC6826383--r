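test_that("fixture masks carry exact analytic expectations and reject overlap", {
  fx <- fixture_mask(list(
    shape_spec("single_pixel", row = 5, col = 5),
    shape_spec("rectangle", row = 20, col = 10, width = 10, height = 5),
    shape_spec("disk", row = 70, col = 70, radius = 20)),
    dim = c(128, 128))
  e <- fx$expected
  expect_equal(e$area, c(1, 50, pi * 400))
  expect_equal(e$perimeter, c(4, 30, 2 * pi * 20))
  expect_equal(e$feret, c(sqrt(2), sqrt(125), 40))
  expect_equal(sum(fx$mask), sum(e$area_px_rendered))
  # measured pixel areas equal the exact rendered pixel counts
  p <- measure_particles(fx$mask)
  expect_equal(sort(p$area_px), sort(e$area_px_rendered))

  expect_error(fixture_mask(list(
    shape_spec("disk", row = 30, col = 30, radius = 10),
    shape_spec("disk", row = 35, col = 35, radius = 10)), dim = c(64, 64)),
    "overlap")
  expect_error(fixture_mask(shape_spec("disk", row = 5, col = 5, radius = 10),
                            dim = c(64, 64)), "fit")
})

test_that("image rendering is bit-identical under a fixed seed", {
  sp <- small_morphology(n_cells = 10)
  r1 <- render_tumor_image(sp, seed = 7)
  r2 <- render_tumor_image(sp, seed = 7)
  expect_identical(unclass(r1$image), unclass(r2$image))
  r3 <- render_tumor_image(sp, seed = 8)
  expect_false(identical(unclass(r1$image), unclass(r3$image)))
})

test_that("an object-free image yields zero particles downstream", {
  sp <- morphology_spec(dim = c(64, 64), n_cells = 0, cluster_lambda = 0,
                        debris_lambda = 0)
  r <- render_tumor_image(sp, seed = 1)
  for (thr in list("auto", 220, 250)) {
    m <- if (identical(thr, "auto")) NULL else threshold_fixed(r$image, thr)
    if (is.null(m)) next  # constant background: no auto threshold exists
    expect_equal(nrow(measure_particles(m)), 0)
  }
})

test_that("the single-cell filter recovers the rendered ground truth", {
  sp <- morphology_spec(n_cells = 25, cluster_lambda = 3)
  r <- render_tumor_image(sp, seed = 7)
  expect_equal(r$truth$n_cells, 25)
  pt <- measure_particles(binarize(r$image, 250))
  f <- apply_filter(pt, filter_spec(circularity_min = 0.8, size_min_px = 20))
  recovered <- sum(f$area_px <= 60)   # cell-sized, round particles
  expect_gte(recovered, 0.9 * 25)
})

test_that("impossible placements fail explicitly", {
  sp <- morphology_spec(dim = c(40, 40), n_cells = 200, cluster_lambda = 0,
                        debris_lambda = 0)
  expect_error(render_tumor_image(sp, seed = 1), "too small")
})

test_that("cohorts have exactly the requested number of events and reproduce under seed", {
  coh <- small_cohort(n = 12, events = 3, images = 2, seed = 5)
  expect_equal(sum(coh$patients$event), 3)
  coh2 <- small_cohort(n = 12, events = 3, images = 2, seed = 5)
  expect_identical(coh$patients, coh2$patients)
  expect_identical(unclass(coh$images[[4]][[2]]), unclass(coh2$images[[4]][[2]]))
  expect_error(cohort_spec(n_patients = 10, n_events = 11), "smaller")
})

test_that("the generating AUC of the latent density follows the binormal law", {
  null_spec <- cohort_spec(n_patients = 200, n_events = 60, d = 0)
  coh0 <- simulate_cohort(null_spec, seed = 21, render_images = FALSE)
  a0 <- auc_mann_whitney(coh0$patients$true_mean_count, coh0$patients$event)$auc
  expect_lt(abs(a0 - 0.5), 0.08)

  d82 <- sqrt(2) * qnorm(0.82)
  spec <- cohort_spec(n_patients = 2000, n_events = 500, d = d82)
  coh <- simulate_cohort(spec, seed = 22, render_images = FALSE)
  a <- auc_mann_whitney(coh$patients$true_mean_count, coh$patients$event)$auc
  expect_gte(a, 0.79)
  expect_lte(a, 0.85)
})

test_that("cohort CSV/PNG round-trip preserves outcomes and images", {
  coh <- small_cohort(n = 4, events = 1, images = 2, seed = 9)
  dir <- tempfile("cohort")
  csv <- write_cohort(coh, dir)
  back <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(back$patients$patient_id, coh$patients$patient_id)
  expect_equal(back$patients$time_months, coh$patients$time_months,
               tolerance = 1e-12)
  expect_equal(back$patients$event, coh$patients$event)
  expect_identical(unclass(back$images[[2]][[1]]), unclass(coh$images[[2]][[1]]))
  unlink(dir, recursive = TRUE)
})
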