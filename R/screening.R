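# The discovery engine: enumerate the binarization x circularity x size
# filter grid, evaluate every feature of every particle subset
# prognostically, and rank subsets by distance of the bootstrap-corrected
# AUC from 0.5 (so low-risk features, AUC < 0.5, compete equally).
#
# Binarization and measurement are cached per (image x threshold):
# particles are measured once and filtered many times.

#' Enumerate the screening filter grid
#'
#' Full Cartesian product of the binarization, circularity-minimum and
#' size-minimum axes, in deterministic binarization-major order (then
#' circularity, then size). The defaults are the 4 x 5 x 4 = 80 filter
#' combinations of the screening design.
#'
#' @param binarizations Vector of `"auto"` and/or numeric thresholds.
#' @param circularity_min Circularity lower bounds.
#' @param size_min_px Particle size (area, px) lower bounds.
#' @param circularity_max,size_max_px Shared upper bounds (default 1 and
#'   `Inf`).
#' @return A `"filter_grid"` data frame, one row per filter spec.
#' @export
filter_grid <- function(binarizations = c("auto", "220", "240", "250"),
                        circularity_min = c(0, 0.2, 0.4, 0.6, 0.8),
                        size_min_px = c(10, 20, 50, 100),
                        circularity_max = 1, size_max_px = Inf) {
  if (length(binarizations) == 0 || length(circularity_min) == 0 ||
      length(size_min_px) == 0)
    stop("every grid axis needs at least one value")
  g <- expand.grid(size_min_px = size_min_px,
                   circularity_min = circularity_min,
                   binarization = as.character(binarizations),
                   stringsAsFactors = FALSE)
  g <- g[c("binarization", "circularity_min", "size_min_px")]
  g$circularity_max <- circularity_max
  g$size_max_px <- size_max_px
  rownames(g) <- NULL
  class(g) <- c("filter_grid", "data.frame")
  g
}

check_cohort <- function(cohort) {
  p <- cohort$patients
  if (is.null(p) || is.null(cohort$images))
    stop("`cohort` needs `$patients` and `$images`")
  need <- c("patient_id", "time_months", "event")
  if (!all(need %in% names(p)))
    stop("`cohort$patients` needs columns: ", paste(need, collapse = ", "))
  if (length(cohort$images) != nrow(p))
    stop("one image list per patient is required")
  if (length(unique(p$event)) < 2)
    stop("both outcome classes must be present in the cohort")
  invisible(cohort)
}

# rank-based AUC without the inference extras (hot loop of the bootstrap)
fast_auc <- function(values, pos) {
  r <- rank(values)
  n1 <- sum(pos)
  n0 <- length(values) - n1
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# measure particles of every image under one binarization; flat vectors
measure_cohort_tab <- function(images, n_img, binarization, connectivity) {
  measure_cohort_tabs(images, n_img, binarization, connectivity)[[1]]
}

# measure particles of every image under every binarization; one flat
# table (gid/area/circ/sol vectors) per binarization. Measurement is
# reused across thresholds that produce bit-identical masks on an image.
measure_cohort_tabs <- function(images, n_img, bins, connectivity) {
  n_total <- sum(n_img)
  tabs <- lapply(bins, function(b)
    list(gid = vector("list", n_total), area = vector("list", n_total),
         circ = vector("list", n_total), sol = vector("list", n_total)))
  names(tabs) <- bins
  g <- 0L
  for (i in seq_along(images)) {
    for (j in seq_len(n_img[i])) {
      g <- g + 1L
      img <- images[[i]][[j]]
      seen_masks <- list()
      seen_pts <- list()
      for (b in bins) {
        mask <- binarize(img, if (b == "auto") "auto" else as.numeric(b))
        mv <- as.vector(unclass(mask))
        pt <- NULL
        for (k in seq_along(seen_masks)) {
          if (identical(seen_masks[[k]], mv)) {
            pt <- seen_pts[[k]]
            break
          }
        }
        if (is.null(pt)) {
          pt <- measure_particles(mask, connectivity)
          seen_masks[[length(seen_masks) + 1L]] <- mv
          seen_pts[[length(seen_pts) + 1L]] <- pt
        }
        if (nrow(pt)) {
          tabs[[b]]$gid[[g]] <- rep.int(g, nrow(pt))
          tabs[[b]]$area[[g]] <- pt$area_px
          tabs[[b]]$circ[[g]] <- pt$circularity
          tabs[[b]]$sol[[g]] <- pt$solidity
        }
      }
    }
  }
  lapply(tabs, function(tb) lapply(tb, function(x) {
    x <- unlist(x)
    if (is.null(x)) numeric(0) else x
  }))
}

# per-patient feature matrix for one filter spec, from a measurement table
aggregate_features <- function(tb, keep, n_total_images, img_pat, n_img) {
  gk <- tb$gid[keep]
  cnt <- tabulate(gk, n_total_images)
  acc <- function(x) {
    out <- numeric(n_total_images)
    if (length(gk)) {
      s <- rowsum(x, gk)
      out[as.integer(rownames(s))] <- s
    }
    out
  }
  area_img <- acc(tb$area[keep])
  avg_img <- ifelse(cnt > 0, area_img / cnt, 0)
  circ_img <- ifelse(cnt > 0, acc(tb$circ[keep]) / cnt, NA_real_)
  sol_img <- ifelse(cnt > 0, acc(tb$sol[keep]) / cnt, NA_real_)
  pat_mean <- function(x) (rowsum(x, img_pat) / n_img)[, 1]
  pat_shape <- function(x) {
    nn <- rowsum(as.numeric(!is.na(x)), img_pat)[, 1]
    s <- rowsum(ifelse(is.na(x), 0, x), img_pat)[, 1]
    ifelse(nn > 0, s / nn, NA_real_)
  }
  cbind(count = pat_mean(cnt), total_area = pat_mean(area_img),
        average_size = pat_mean(avg_img), circularity = pat_shape(circ_img),
        solidity = pat_shape(sol_img))
}

#' Screen all particle subsets for prognostic value
#'
#' Runs the full discovery pipeline over a cohort: binarize each image at
#' every threshold in the grid, outline and measure the particles (once
#' per image and threshold), apply every circularity/size filter,
#' aggregate to per-image and per-patient features, and evaluate each of
#' the five features of each subset by continuous-value AUC (with
#' optimism-bootstrap correction) and by Cox regression on the
#' optimal-cutpoint dichotomization. Records are ranked by
#' `|corrected AUC - 0.5|`; a record whose feature is missing for more
#' than half the patients is flagged and excluded from ranking.
#' Multiple-testing across records is deliberately not corrected (the
#' `bonferroni_significant` column reports the adjusted call as
#' supplementary output).
#'
#' @param cohort A `"synthetic_cohort"` (or any list with `$patients` —
#'   columns `patient_id`, `time_months`, `event` — and `$images`, a list
#'   of per-patient lists of [gray_image]s).
#' @param grid A [filter_grid()].
#' @param B Bootstrap resamples for the AUC correction (default 1000).
#' @param seed Optional seed controlling the bootstrap resamples.
#' @param connectivity Particle connectivity (default 8).
#' @param min_group_fraction Passed to [optimal_cutpoint()].
#' @param cox If `FALSE`, skip the cutpoint/Cox stage (AUC screening
#'   only).
#' @return A `"particle_screen"` object: `results` (one row per filter
#'   spec x feature, in grid order, with a `rank` column), `patients`,
#'   `patient_features` (per-spec feature matrices), `grid`, `meta`.
#' @export
particle_screen <- function(cohort, grid = filter_grid(), B = 1000,
                            seed = NULL, connectivity = 8,
                            min_group_fraction = 0.1, cox = TRUE) {
  check_cohort(cohort)
  stopifnot(inherits(grid, "filter_grid"))
  ord <- order(cohort$patients$patient_id)
  patients <- cohort$patients[ord, , drop = FALSE]
  images <- cohort$images[ord]
  n <- nrow(patients)
  n_img <- vapply(images, length, integer(1))
  img_pat <- rep(seq_len(n), n_img)
  n_total_images <- sum(n_img)
  time <- patients$time_months
  event <- as.integer(patients$event)

  with_seed(seed, {
    tabs <- measure_cohort_tabs(images, n_img, unique(grid$binarization),
                                connectivity)

    resample_cache <- new.env(parent = emptyenv())
    stat_cache <- new.env(parent = emptyenv())

    resamples_for <- function(cc_idx) {
      key <- paste(cc_idx, collapse = ",")
      got <- resample_cache[[key]]
      if (!is.null(got)) return(got)
      ev <- which(event[cc_idx] == 1L)
      nv <- which(event[cc_idx] == 0L)
      idx <- matrix(0L, length(cc_idx), B)
      for (b in seq_len(B))
        idx[, b] <- c(ev[sample.int(length(ev), length(ev), replace = TRUE)],
                      nv[sample.int(length(nv), length(nv), replace = TRUE)])
      resample_cache[[key]] <- idx
      idx
    }

    eval_feature <- function(values) {
      key <- paste(round(values, 10), collapse = ",")
      got <- stat_cache[[key]]
      if (!is.null(got)) return(got)
      cc_idx <- which(!is.na(values))
      na_frac <- 1 - length(cc_idx) / n
      out <- list(n_used = length(cc_idx), na_frac = na_frac,
                  flagged = na_frac > 0.5,
                  auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                  auc_p = NA_real_, corrected_auc = NA_real_,
                  cutpoint = NA_real_, hr = NA_real_, hr_lo = NA_real_,
                  hr_hi = NA_real_, hr_p = NA_real_)
      v <- values[cc_idx]
      ee <- event[cc_idx]
      tt <- time[cc_idx]
      if (length(unique(ee)) == 2 && length(v) >= 4) {
        a <- auc_mann_whitney(v, ee)
        idx <- resamples_for(cc_idx)
        pos <- ee == 1L
        boot_aucs <- vapply(seq_len(ncol(idx)), function(b)
          fast_auc(v[idx[, b]], pos[idx[, b]]), numeric(1))
        out$auc <- a$auc
        out$auc_lo <- a$ci95[1]
        out$auc_hi <- a$ci95[2]
        out$auc_p <- a$p_value
        out$corrected_auc <- 2 * a$auc - mean(boot_aucs)
        if (cox) {
          cx <- tryCatch({
            ct <- optimal_cutpoint(v, tt, ee, min_group_fraction)
            fit <- cox_fit(as.numeric(v > ct$cutpoint), tt, ee)
            list(cut = ct$cutpoint, hr = fit$hr[[1]],
                 lo = fit$ci95[1, "lower"], hi = fit$ci95[1, "upper"],
                 p = fit$p_values[[1]])
          }, error = function(e) NULL)
          if (!is.null(cx)) {
            out$cutpoint <- cx$cut
            out$hr <- cx$hr
            out$hr_lo <- cx$lo
            out$hr_hi <- cx$hi
            out$hr_p <- cx$p
          }
        }
      } else {
        out$flagged <- TRUE
      }
      stat_cache[[key]] <- out
      out
    }

    feats <- feature_names()
    n_rec <- nrow(grid) * length(feats)
    rec <- vector("list", n_rec)
    pf_list <- vector("list", nrow(grid))
    k <- 0L
    for (r in seq_len(nrow(grid))) {
      tb <- tabs[[grid$binarization[r]]]
      keep <- tb$circ >= grid$circularity_min[r] &
        tb$circ <= grid$circularity_max[r] &
        tb$area >= grid$size_min_px[r] &
        tb$area <= grid$size_max_px[r]
      fmat <- aggregate_features(tb, keep, n_total_images, img_pat, n_img)
      pf_list[[r]] <- fmat
      for (f in feats) {
        k <- k + 1L
        st <- eval_feature(fmat[, f])
        rec[[k]] <- data.frame(
          spec_id = r, binarization = grid$binarization[r],
          circularity_min = grid$circularity_min[r],
          size_min_px = grid$size_min_px[r], feature = f,
          n_used = st$n_used, missing_frac = st$na_frac,
          auc = st$auc, auc_lo = st$auc_lo, auc_hi = st$auc_hi,
          auc_p = st$auc_p, corrected_auc = st$corrected_auc,
          cutpoint = st$cutpoint, hr = st$hr, hr_lo = st$hr_lo,
          hr_hi = st$hr_hi, hr_p = st$hr_p, flagged = st$flagged
        )
      }
    }
    results <- do.call(rbind, rec)
    results$bonferroni_significant <-
      !is.na(results$auc_p) & results$auc_p <= 0.05 / nrow(results)
    eligible <- !results$flagged & !is.na(results$corrected_auc)
    results$rank <- NA_integer_
    results$rank[eligible][order(-abs(results$corrected_auc[eligible] - 0.5))] <-
      seq_len(sum(eligible))

    structure(list(results = results, patients = patients,
                   patient_features = pf_list, grid = grid,
                   meta = list(seed = seed, B = B,
                               connectivity = connectivity,
                               min_group_fraction = min_group_fraction,
                               cox = cox,
                               n_patients = n, n_events = sum(event),
                               n_images = n_total_images,
                               perimeter_estimator =
                                 "corner-aware crack polygon")),
              class = "particle_screen")
  })
}

#' Top-ranked records of a screen
#' @param x A `"particle_screen"`.
#' @param n Number of records.
#' @return The `n` best-ranked result rows.
#' @export
top_subsets <- function(x, n = 10) {
  stopifnot(inherits(x, "particle_screen"))
  r <- x$results[!is.na(x$results$rank), , drop = FALSE]
  head(r[order(r$rank), , drop = FALSE], n)
}

#' Prognostic AUC of the count feature by particle-size window
#'
#' Restricts the size filter to consecutive half-open area windows
#' `[lo, hi)` and evaluates the per-patient particle count of each window
#' by AUC, profiling where along the size axis the prognostic signal
#' lives.
#'
#' @param cohort As in [particle_screen()].
#' @param breaks Ascending window breaks (>= 3 values, i.e. >= 2
#'   windows); the last may be `Inf`.
#' @param binarization,circularity_min,circularity_max,connectivity
#'   Filter settings shared by all windows.
#' @return A `"size_profile"` data frame: `size_lo`, `size_hi`, `auc`,
#'   `auc_p`, `n_particles` (cohort-wide tally; windows without any
#'   particle get `auc = NA`).
#' @export
size_profile <- function(cohort, breaks = c(1, 10, 20, 60, 80, 100, Inf),
                         binarization = "250", circularity_min = 0.8,
                         circularity_max = 1, connectivity = 8) {
  check_cohort(cohort)
  if (length(breaks) < 3 || is.unsorted(breaks, strictly = TRUE))
    stop("`breaks` must be >= 3 strictly ascending values")
  ord <- order(cohort$patients$patient_id)
  patients <- cohort$patients[ord, , drop = FALSE]
  images <- cohort$images[ord]
  n <- nrow(patients)
  n_img <- vapply(images, length, integer(1))
  img_pat <- rep(seq_len(n), n_img)
  G <- sum(n_img)
  tb <- measure_cohort_tab(images, n_img, as.character(binarization),
                           connectivity)
  circ_ok <- tb$circ >= circularity_min & tb$circ <= circularity_max
  out <- lapply(seq_len(length(breaks) - 1), function(w) {
    keep <- circ_ok & tb$area >= breaks[w] & tb$area < breaks[w + 1]
    tally <- sum(keep)
    if (tally == 0)
      return(data.frame(size_lo = breaks[w], size_hi = breaks[w + 1],
                        auc = NA_real_, auc_p = NA_real_, n_particles = 0))
    cnt <- tabulate(tb$gid[keep], G)
    cnt_pat <- (rowsum(cnt, img_pat) / n_img)[, 1]
    a <- auc_mann_whitney(cnt_pat, patients$event)
    data.frame(size_lo = breaks[w], size_hi = breaks[w + 1], auc = a$auc,
               auc_p = a$p_value, n_particles = tally)
  })
  out <- do.call(rbind, out)
  class(out) <- c("size_profile", "data.frame")
  out
}
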