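# Methods for the screen result objects.

#' @export
print.particle_screen <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Particle subset screen: %d filter specs x %d features = %d records\n",
              nrow(x$grid), length(feature_names()), nrow(x$results)))
  cat(sprintf("  cohort: %d patients, %d events, %d images\n",
              m$n_patients, m$n_events, m$n_images))
  cat(sprintf("  bootstrap B = %d, connectivity %d, perimeter: %s\n",
              m$B, m$connectivity, m$perimeter_estimator))
  top <- top_subsets(x, 1)
  if (nrow(top)) {
    cat(sprintf("  top subset: binarization %s, circularity >= %.1f, size >= %g px, feature '%s'\n",
                top$binarization, top$circularity_min, top$size_min_px,
                top$feature))
    cat(sprintf("    AUC %.3f (corrected %.3f)", top$auc, top$corrected_auc))
    if (!is.na(top$hr))
      cat(sprintf(", HR %.2f at cutpoint %.2f", top$hr, top$cutpoint))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.particle_screen <- function(object, n = 10, ...) {
  cat(sprintf("Top %d of %d ranked particle-subset records:\n\n", n,
              sum(!is.na(object$results$rank))))
  cols <- c("rank", "binarization", "circularity_min", "size_min_px",
            "feature", "auc", "corrected_auc", "auc_p", "cutpoint", "hr",
            "hr_p")
  top <- top_subsets(object, n)[cols]
  top[vapply(top, is.numeric, logical(1))] <-
    lapply(top[vapply(top, is.numeric, logical(1))], round, 3)
  print(top, row.names = FALSE)
  invisible(object)
}

#' Plot corrected count-feature AUC against the circularity threshold
#'
#' One line per binarization threshold, at a fixed size filter: the
#' discovery view of how the circularity filter concentrates prognostic
#' signal.
#'
#' @param x A `"particle_screen"`.
#' @param feature Feature to profile (default `"count"`).
#' @param size_min_px Size filter row to hold fixed (default 20).
#' @param ... Passed to [graphics::matplot()].
#' @return The plotted AUC matrix (circularity x binarization),
#'   invisibly.
#' @export
plot.particle_screen <- function(x, feature = "count", size_min_px = 20, ...) {
  r <- x$results[x$results$feature == feature &
                   x$results$size_min_px == size_min_px, ]
  bins <- unique(r$binarization)
  circ <- sort(unique(r$circularity_min))
  m <- sapply(bins, function(b)
    r$corrected_auc[r$binarization == b][order(r$circularity_min[r$binarization == b])])
  graphics::matplot(circ, m, type = "b", pch = 19, lty = 1,
                    xlab = "circularity threshold",
                    ylab = "corrected AUC",
                    main = sprintf("'%s' feature, size >= %g px",
                                   feature, size_min_px), ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("topleft", legend = bins, col = seq_along(bins),
                   pch = 19, bty = "n", title = "binarization")
  invisible(m)
}

#' @export
print.size_profile <- function(x, ...) {
  cat("Prognostic AUC of the particle count by size window:\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot a size-window AUC profile
#'
#' @param x A `"size_profile"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.size_profile <- function(x, ...) {
  mid <- ifelse(is.finite(x$size_hi), (x$size_lo + x$size_hi) / 2,
                x$size_lo * 1.5)
  graphics::plot(mid, x$auc, type = "b", pch = 19, log = "x",
                 xlab = "particle size window midpoint (px)",
                 ylab = "AUC of count feature", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Write screen results to CSV (plus a JSON run manifest)
#'
#' @param x A `"particle_screen"`.
#' @param dir Output directory.
#' @return The results CSV path, invisibly.
#' @export
write_screen_results <- function(x, dir) {
  stopifnot(inherits(x, "particle_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "screen_results.csv")
  write.csv(x$results, csv, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- c(x$meta[c("seed", "B", "connectivity", "min_group_fraction",
                           "n_patients", "n_events", "n_images",
                           "perimeter_estimator")],
                  list(package_version =
                         as.character(utils::packageVersion("morphoscreen"))))
    jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(csv)
}
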