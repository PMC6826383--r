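# Seeded simulation of a patient cohort whose metastasis risk is driven
# by the density of scattered single epithelial cells.
#
# The construction is retrospective (case-control-like), mirroring a
# cohort with a fixed number of observed metastases: event status is
# fixed first (exactly n_events patients), then a latent standardized
# log-density z is drawn N(0, 1) for non-events and N(d, 1) for events.
# Because both classes are Gaussian with unit variance, the generating
# AUC of any monotone transform of z is exactly Phi(d / sqrt(2)).
# Event times follow an exponential whose log-rate is linear in z,
# truncated below an administrative censoring time drawn uniformly from
# the follow-up window; non-events are censored at that time.

#' Parameters of the synthetic cohort simulator
#'
#' Defaults reproduce the study conditions the pipeline is designed for:
#' 102 patients, 20 metastasis events, 5 images per patient, and a
#' latent-count effect size `d` chosen so the generating AUC
#' `Phi(d / sqrt(2))` equals 0.82. Per-image single-cell counts are
#' drawn negative-binomially around the patient's latent mean
#' (`exp(mean_log_count + sd_log_count * z)`), giving overdispersed
#' counts on the log scale; a Gaussian count model is available for
#' calibration checks. Follow-up emulates the cohort's reported ranges:
#' censoring uniform on 77-165 months and a median time-to-event near 61
#' months.
#'
#' @param n_patients Cohort size (default 102).
#' @param n_events Number of metastasis events (default 20); must be
#'   below `n_patients`.
#' @param images_per_patient Images per patient (default 5).
#' @param d Standardized difference of the latent log-density between
#'   event and non-event patients (>= 0); the generating AUC is
#'   `pnorm(d / sqrt(2))`.
#' @param mean_log_count,sd_log_count Location/scale mapping z to the
#'   per-image mean single-cell count.
#' @param count_model `"negbin"` (default) or `"gaussian"`.
#' @param nb_size Negative-binomial size (within-patient image-to-image
#'   dispersion; larger = less overdispersion).
#' @param gaussian_sd Within-patient count SD for the Gaussian model.
#' @param median_event_months Median of the event-time distribution for a
#'   typical event patient.
#' @param log_hr_per_sd Log hazard-rate slope per SD of z.
#' @param censor_range Administrative censoring window in months.
#' @param morphology Base [morphology_spec()]; its `n_cells` is
#'   overridden per image by the simulated counts.
#' @param burden_shape Gamma shape of the outcome-independent per-patient
#'   multipliers applied to the cluster and debris intensities
#'   (`rgamma(shape, rate = shape)`, mean 1). This models the strong
#'   between-patient variation in stained tumor architecture; it is the
#'   nuisance variation that the circularity/size filters must separate
#'   the single-cell signal from. `Inf` disables the heterogeneity.
#' @param max_cells_per_image Rendering cap on the per-image count.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_patients = 102, n_events = 20,
                        images_per_patient = 5,
                        d = sqrt(2) * qnorm(0.82),
                        mean_log_count = log(8), sd_log_count = 0.35,
                        count_model = c("negbin", "gaussian"),
                        nb_size = 10, gaussian_sd = 2,
                        median_event_months = 61, log_hr_per_sd = 1,
                        censor_range = c(77, 165),
                        morphology = morphology_spec(),
                        burden_shape = 2,
                        max_cells_per_image = 80) {
  count_model <- match.arg(count_model)
  if (d < 0) stop("`d` must be non-negative")
  if (n_events >= n_patients)
    stop("`n_events` must be smaller than `n_patients`")
  if (n_events < 1 || images_per_patient < 1)
    stop("need at least one event and one image per patient")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a synthetic patient cohort
#'
#' Draws outcomes, latent single-cell densities, per-image cell counts
#' and (optionally) the rendered images for every patient. Exactly
#' `n_events` patients carry the event; clinicopathological covariates
#' (age, tumor size, grade, ER, PR) are drawn independent of outcome.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   bit-identically.
#' @param render_images If `FALSE`, only outcomes and true counts are
#'   generated (fast path for calibration tests).
#' @return A `"synthetic_cohort"` list: `patients` (data frame with
#'   `patient_id`, `time_months`, `event`, covariates, `latent_z`,
#'   `true_mean_count`), `counts` (patients x images matrix of true
#'   rendered cell counts), `images` (list of per-patient lists of
#'   [gray_image]s, if rendered), `spec`, `seed`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            render_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_patients
    m <- spec$images_per_patient
    event <- integer(n)
    event[sample.int(n, spec$n_events)] <- 1L
    z <- rnorm(n, mean = spec$d * event, sd = 1)
    mu <- exp(spec$mean_log_count + spec$sd_log_count * z)

    counts <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      counts[i, ] <- if (spec$count_model == "negbin") {
        rnbinom(m, mu = mu[i], size = spec$nb_size)
      } else {
        round(pmax(0, rnorm(m, mean = mu[i], sd = spec$gaussian_sd)))
      }
    }
    counts[counts > spec$max_cells_per_image] <- spec$max_cells_per_image

    cens <- runif(n, spec$censor_range[1], spec$censor_range[2])
    rate <- log(2) / spec$median_event_months *
      exp(spec$log_hr_per_sd * (z - spec$d))
    time <- cens
    ev <- which(event == 1L)
    if (length(ev)) {
      u <- runif(length(ev))
      lam <- rate[ev]
      time[ev] <- -log(1 - u * (1 - exp(-lam * cens[ev]))) / lam
    }

    patients <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      time_months = time,
      event = event,
      age = pmin(80, pmax(37, round(rnorm(n, 57, 9)))),
      tumor_size_mm = pmin(70, pmax(4, round(exp(rnorm(n, log(16), 0.35))))),
      grade = sample(1:3, n, replace = TRUE, prob = c(9, 92, 1) / 102),
      er = round(exp(rnorm(n, log(32), 1)), 1),
      pr = round(exp(rnorm(n, log(6), 1)), 1),
      latent_z = z,
      true_mean_count = mu
    )

    # outcome-independent per-patient tumor-architecture burden
    burden <- if (is.finite(spec$burden_shape)) {
      # truncated at 2.5x so the densest patients remain placeable
      cbind(cluster = pmin(2.5, rgamma(n, spec$burden_shape,
                                       rate = spec$burden_shape)),
            debris = pmin(2.5, rgamma(n, spec$burden_shape,
                                      rate = spec$burden_shape)))
    } else {
      cbind(cluster = rep(1, n), debris = rep(1, n))
    }

    images <- NULL
    if (render_images) {
      images <- vector("list", n)
      for (i in seq_len(n)) {
        images[[i]] <- vector("list", m)
        sp <- spec$morphology
        sp$cluster_lambda <- spec$morphology$cluster_lambda * burden[i, "cluster"]
        sp$debris_lambda <- spec$morphology$debris_lambda * burden[i, "debris"]
        for (j in seq_len(m)) {
          sp$n_cells <- counts[i, j]
          images[[i]][[j]] <- render_tumor_image(sp)$image
        }
      }
      names(images) <- patients$patient_id
    }

    structure(list(patients = patients, counts = counts, images = images,
                   spec = spec, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d events, %d images/patient%s\n",
              nrow(x$patients), sum(x$patients$event), ncol(x$counts),
              if (is.null(x$images)) " (images not rendered)" else ""))
  invisible(x)
}

#' Write a cohort to disk as PNG images plus a CSV table
#'
#' The CSV has one row per patient with columns `patient_id`,
#' `image_paths` (semicolon-separated, relative to the CSV), `time_months`,
#' `event`, `age`, `tumor_size_mm`, `grade`, `er`, `pr`.
#'
#' @param cohort A `"synthetic_cohort"` with rendered images.
#' @param dir Output directory (created if needed).
#' @return The path of the written CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"), !is.null(cohort$images))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(nrow(cohort$patients))
  for (i in seq_len(nrow(cohort$patients))) {
    pid <- cohort$patients$patient_id[i]
    files <- sprintf("%s_img%d.png", pid, seq_along(cohort$images[[i]]))
    for (j in seq_along(files))
      write_gray_image(cohort$images[[i]][[j]], file.path(dir, files[j]))
    paths[i] <- paste(files, collapse = ";")
  }
  tab <- cohort$patients[c("patient_id", "time_months", "event", "age",
                           "tumor_size_mm", "grade", "er", "pr")]
  tab <- cbind(tab[1], image_paths = paths, tab[-1])
  csv <- file.path(dir, "cohort.csv")
  write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param csv Path to the cohort CSV; image paths are resolved relative
#'   to its directory.
#' @param pixel_size_um Physical pixel size of the images.
#' @return A list with the same shape as a `"synthetic_cohort"`
#'   (`patients`, `images`), usable by [particle_screen()].
#' @export
read_cohort <- function(csv, pixel_size_um = 1.4) {
  tab <- read.csv(csv, stringsAsFactors = FALSE)
  base <- dirname(csv)
  images <- lapply(strsplit(tab$image_paths, ";", fixed = TRUE),
                   function(fs) lapply(file.path(base, fs), read_gray_image,
                                       pixel_size_um = pixel_size_um))
  names(images) <- tab$patient_id
  patients <- tab[setdiff(names(tab), "image_paths")]
  structure(list(patients = patients, images = images),
            class = "synthetic_cohort")
}
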