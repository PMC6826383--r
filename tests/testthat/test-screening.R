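test_that("grid enumeration is a complete Cartesian product in deterministic order", {
  g <- filter_grid()
  expect_equal(nrow(g), 80)
  expect_equal(g$binarization[1:20], rep("auto", 20))   # binarization-major
  expect_equal(g$size_min_px[1:4], c(10, 20, 50, 100))  # size varies fastest
  expect_equal(g$circularity_min[1:8], rep(c(0, 0.2), each = 4))
  expect_equal(nrow(filter_grid("250", 0.8, 20)), 1)
  expect_equal(nrow(filter_grid(c("auto", "240"), c(0, 0.4, 0.8),
                                c(10, 20, 50, 100))), 24)
  expect_error(filter_grid(character(0)), "at least one")
})

test_that("screening is deterministic and invariant to patient order", {
  coh <- small_cohort(n = 16, events = 5, images = 2, seed = 30)
  s1 <- particle_screen(coh, B = 60, seed = 4)
  s2 <- particle_screen(coh, B = 60, seed = 4)
  expect_identical(s1$results, s2$results)
  perm <- sample(seq_len(nrow(coh$patients)))
  coh_p <- coh
  coh_p$patients <- coh$patients[perm, ]
  coh_p$images <- coh$images[perm]
  s3 <- particle_screen(coh_p, B = 60, seed = 4)
  expect_identical(s1$results, s3$results)
})

test_that("screen output is one record per filter spec and feature, ranked coherently", {
  coh <- small_cohort(n = 16, events = 5, images = 2, seed = 31)
  scr <- particle_screen(coh, B = 60, seed = 2)
  expect_s3_class(scr, "particle_screen")
  expect_equal(nrow(scr$results), 80 * 5)
  r <- scr$results
  expect_true(all(is.na(r$rank[r$flagged])))
  ranked <- r[!is.na(r$rank), ]
  ranked <- ranked[order(ranked$rank), ]
  expect_true(all(diff(abs(ranked$corrected_auc - 0.5)) <= 1e-12))
  expect_true(all(r$auc >= 0 & r$auc <= 1, na.rm = TRUE))
  # HR consistent with its CI
  ok <- !is.na(r$hr)
  expect_true(all(r$hr[ok] >= r$hr_lo[ok] & r$hr[ok] <= r$hr_hi[ok]))
})

test_that("mean retained particle count is non-increasing in the circularity threshold", {
  coh <- small_cohort(n = 10, events = 3, images = 2, seed = 33)
  scr <- particle_screen(coh, grid = filter_grid("250"), B = 10, seed = 1,
                         cox = FALSE)
  g <- scr$grid
  for (sz in unique(g$size_min_px)) {
    rows <- which(g$size_min_px == sz)
    rows <- rows[order(g$circularity_min[rows])]
    mean_counts <- vapply(rows, function(r)
      mean(scr$patient_features[[r]][, "count"]), numeric(1))
    expect_true(all(diff(mean_counts) <= 1e-12))
  }
})

test_that("size windows partition the size filter (tally conservation)", {
  coh <- small_cohort(n = 10, events = 3, images = 2, seed = 34)
  breaks <- c(1, 10, 20, 60, Inf)
  prof <- size_profile(coh, breaks = breaks, binarization = "250",
                       circularity_min = 0, circularity_max = 1)
  expect_equal(nrow(prof), 4)
  # independent tally: all particles in [1, Inf) at circularity [0, 1]
  total <- 0
  for (i in seq_len(nrow(coh$patients)))
    for (img in coh$images[[i]])
      total <- total + nrow(measure_particles(threshold_fixed(img, 250)))
  expect_equal(sum(prof$n_particles), total)
  # a window beyond every particle size is flagged missing
  prof2 <- size_profile(coh, breaks = c(1e5, 2e5, 3e5), binarization = "250")
  expect_true(all(is.na(prof2$auc)))
  expect_true(all(prof2$n_particles == 0))
  expect_error(size_profile(coh, breaks = c(10, 20)), "ascending")
})

test_that("the size-window profile peaks in the single-cell 20-60 px band", {
  coh <- simulate_cohort(
    cohort_spec(n_patients = 60, n_events = 15, images_per_patient = 3,
                morphology = small_morphology()),
    seed = 35)
  prof <- size_profile(coh, breaks = c(1, 10, 20, 60, 120, Inf),
                       binarization = "250", circularity_min = 0.8)
  best <- which.max(abs(prof$auc - 0.5))
  expect_equal(c(prof$size_lo[best], prof$size_hi[best]), c(20, 60))
})

test_that("screen results can be written out as CSV", {
  coh <- small_cohort(n = 10, events = 3, images = 1, seed = 36)
  scr <- particle_screen(coh, grid = filter_grid("220", 0.8, c(10, 20)),
                         B = 10, seed = 1, cox = FALSE)
  dir <- tempfile("screenout")
  csv <- write_screen_results(scr, dir)
  expect_true(file.exists(csv))
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(scr$results))
  unlink(dir, recursive = TRUE)
})
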