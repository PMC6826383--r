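# Prognostic evaluation machinery: Mann-Whitney AUC, optimism bootstrap,
# optimal log-rank cutpoint, Cox regression, reverse Kaplan-Meier and the
# Hanley-McNeil ROC sample-size search.

#' Hanley-McNeil variance of an AUC estimate
#'
#' Uses `Q1 = theta / (2 - theta)` and `Q2 = 2 theta^2 / (1 + theta)`.
#'
#' @param theta AUC value in `(0, 1)`.
#' @param n_pos,n_neg Group sizes.
#' @return Variance of the AUC estimator.
#' @export
hanley_mcneil_var <- function(theta, n_pos, n_neg) {
  q1 <- theta / (2 - theta)
  q2 <- 2 * theta^2 / (1 + theta)
  (theta * (1 - theta) + (n_pos - 1) * (q1 - theta^2) +
      (n_neg - 1) * (q2 - theta^2)) / (n_pos * n_neg)
}

#' AUC by the Mann-Whitney statistic
#'
#' `AUC = (#(pos > neg) + 0.5 #ties) / (n_pos * n_neg)`, computed from
#' ranks. The orientation is NOT flipped: AUC below 0.5 is reported as-is
#' and read as association with low risk. The p-value tests AUC = 0.5 by
#' the normal approximation of the Mann-Whitney statistic with tie
#' correction; the 95% CI uses the Hanley-McNeil standard error at the
#' observed AUC.
#'
#' @param values Numeric feature values, one per patient.
#' @param labels Binary outcome (0/1 or logical), 1 = event.
#' @return An `"auc_result"` list: `auc`, `ci95`, `p_value`,
#'   `corrected_auc` (NA until bootstrap-corrected), `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  if (anyNA(values) || anyNA(labels)) stop("missing values are not allowed")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 1 || n_neg < 1) stop("both outcome classes must be present")
  r <- rank(values)
  u <- sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  # tie-corrected null variance of U
  n <- n_pos + n_neg
  ties <- table(values)
  v0 <- n_pos * n_neg / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v0 <= 0) {
    p <- 1
  } else {
    z <- (u - n_pos * n_neg / 2) / sqrt(v0)
    p <- 2 * pnorm(-abs(z))
  }
  se <- sqrt(max(0, hanley_mcneil_var(auc, n_pos, n_neg)))
  ci <- c(max(0, auc - qnorm(0.975) * se), min(1, auc + qnorm(0.975) * se))
  structure(list(auc = auc, ci95 = ci, p_value = p, corrected_auc = NA_real_,
                 n_pos = n_pos, n_neg = n_neg),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), p = %.3g [%d events / %d non-events]\n",
              x$auc, x$ci95[1], x$ci95[2], x$p_value, x$n_pos, x$n_neg))
  if (!is.na(x$corrected_auc))
    cat(sprintf("bootstrap-corrected AUC %.3f\n", x$corrected_auc))
  invisible(x)
}

#' Optimism bootstrap correction of a performance statistic
#'
#' Harrell-style internal validation: for each of `B` resamples, the rule
#' is derived on the resample and the optimism is the statistic on the
#' resample minus the resample-derived rule evaluated on the original
#' data. The corrected estimate is the apparent statistic minus the mean
#' optimism.
#'
#' @param fit_eval Function `(train, test) -> numeric`: derives the rule
#'   on `train` and evaluates the statistic on `test`. For rule-free
#'   statistics (e.g. the AUC of a fixed feature) `train` is ignored.
#' @param data Data frame resampled by rows.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @param strata Optional column name: resampling is stratified within the
#'   levels of this column (used with the event indicator to avoid
#'   single-class resamples).
#' @param valid Predicate on a resampled data frame; invalid resamples are
#'   redrawn and the redraw count reported.
#' @return A `"boot_corrected"` list: `apparent`, `corrected`, `optimism`,
#'   `ci95` (percentile interval of the optimism-adjusted resample
#'   statistics), `B`, `n_redraws`.
#' @export
bootstrap_correct <- function(fit_eval, data, B = 1000, seed = NULL,
                              strata = NULL, valid = function(d) TRUE) {
  stopifnot(B >= 1)
  apparent <- fit_eval(data, data)
  n <- nrow(data)
  idx_groups <- if (is.null(strata)) list(seq_len(n)) else
    split(seq_len(n), data[[strata]])
  with_seed(seed, {
    optimism <- numeric(B)
    n_redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- unlist(lapply(idx_groups, function(g)
          g[sample.int(length(g), length(g), replace = TRUE)]),
          use.names = FALSE)
        boot <- data[idx, , drop = FALSE]
        if (valid(boot)) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 100 * B) stop("too many degenerate resamples")
      }
      optimism[b] <- fit_eval(boot, boot) - fit_eval(boot, data)
    }
    structure(list(apparent = apparent,
                   corrected = apparent - mean(optimism, na.rm = TRUE),
                   optimism = mean(optimism, na.rm = TRUE),
                   ci95 = unname(quantile(apparent - optimism,
                                          c(0.025, 0.975), na.rm = TRUE)),
                   B = B, n_redraws = n_redraws),
              class = "boot_corrected")
  })
}

#' @export
print.boot_corrected <- function(x, ...) {
  cat(sprintf("apparent %.4f, optimism %.4f -> corrected %.4f (B = %d, %d redraws)\n",
              x$apparent, x$optimism, x$corrected, x$B, x$n_redraws))
  invisible(x)
}

#' Log-rank chi-square statistic for a two-group split
#'
#' Standard (unweighted) log-rank test statistic, computed directly from
#' the risk sets; agrees with `survival::survdiff`.
#'
#' @param group Logical or 0/1 vector (group membership).
#' @param time,event Follow-up time and event indicator.
#' @return The 1-df chi-square statistic (0 if no variance).
#' @export
logrank_chi2 <- function(group, time, event) {
  g <- as.logical(group)
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tj in ut) {
    at <- time >= tj
    nj <- sum(at)
    n1 <- sum(at & g)
    dj <- sum(time == tj & event == 1)
    o1 <- sum(time == tj & event == 1 & g)
    o_minus_e <- o_minus_e + (o1 - dj * n1 / nj)
    if (nj > 1)
      v <- v + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  if (v <= 0) return(0)
  o_minus_e^2 / v
}

#' Optimal cutpoint by maximally selected log-rank statistic
#'
#' Evaluates every midpoint between adjacent distinct feature values whose
#' induced low/high split leaves each group at least
#' `min_group_fraction` of the patients, and returns the cutpoint
#' maximizing the log-rank chi-square. Ties are broken toward the more
#' balanced split, then toward the lower cutpoint.
#'
#' @param values Continuous feature values.
#' @param time,event Follow-up time (months) and event indicator.
#' @param min_group_fraction Minimum fraction of patients in each group
#'   (default 0.10).
#' @return A list: `cutpoint` (high group is `values > cutpoint`),
#'   `chi2`, `n_low`, `n_high`.
#' @export
optimal_cutpoint <- function(values, time, event, min_group_fraction = 0.1) {
  if (anyNA(values)) stop("missing values are not allowed")
  sv <- sort(unique(values))
  if (length(sv) < 2) stop("need at least two distinct values to split")
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  n <- length(values)
  n_min <- min_group_fraction * n
  n_low <- vapply(cand, function(ct) sum(values <= ct), numeric(1))
  ok <- n_low >= n_min & (n - n_low) >= n_min
  if (!any(ok)) stop("no admissible split at this minimum group fraction")
  cand <- cand[ok]
  n_low <- n_low[ok]
  chi2 <- vapply(cand, function(ct) logrank_chi2(values > ct, time, event),
                 numeric(1))
  best <- which(chi2 >= max(chi2) - 1e-12)
  if (length(best) > 1) {
    bal <- abs(n_low[best] - (n - n_low[best]))
    best <- best[bal == min(bal)]
    best <- best[1]
  }
  list(cutpoint = cand[best], chi2 = chi2[best],
       n_low = n_low[best], n_high = n - n_low[best])
}

#' Cox proportional hazards fit
#'
#' Thin wrapper around `survival::coxph` with Breslow tie handling
#' (switchable), returning hazard ratios with Wald 95% CIs and p-values.
#' Non-convergence and monotone likelihood (infinite coefficients) raise
#' an explicit error.
#'
#' @param covariates Vector, matrix or data frame of covariates.
#' @param time,event Follow-up time and event indicator (needs >= 1
#'   event).
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @return A `"cox_result"` list: `coefficients`, `hr`, `ci95` (matrix),
#'   `p_values`, `n`, `n_events`, and the underlying `fit`.
#' @export
cox_fit <- function(covariates, time, event, ties = "breslow") {
  if (sum(event) < 1) stop("at least one event is required")
  x <- as.data.frame(covariates)
  if (any(!vapply(x, is.numeric, logical(1))))
    stop("covariates must be numeric")
  if (any(!is.finite(as.matrix(x)))) stop("covariates must be finite")
  x$.time <- time
  x$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(x), c(".time", ".event"))),
          collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = x, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (!is.null(warn) &&
      grepl("infinite|did not converge|beta may be infinite", warn))
    stop(sprintf("Cox fit failed (monotone likelihood or non-convergence): %s",
                 warn))
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- cf / se
  structure(list(coefficients = cf,
                 hr = exp(cf),
                 ci95 = cbind(lower = exp(cf - qnorm(0.975) * se),
                              upper = exp(cf + qnorm(0.975) * se)),
                 p_values = 2 * pnorm(-abs(z)),
                 n = length(time), n_events = sum(event), fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (%d patients, %d events)\n", x$n, x$n_events))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lower95 = x$ci95[, "lower"], upper95 = x$ci95[, "upper"],
                    p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Schoenfeld-residual proportional-hazards diagnostic
#'
#' Optional diagnostic (not a gate) for a fitted [cox_fit()] model.
#'
#' @param fit A `"cox_result"`.
#' @return The `survival::cox.zph` table.
#' @export
ph_test <- function(fit) {
  stopifnot(inherits(fit, "cox_result"))
  survival::cox.zph(fit$fit)
}

#' Multivariate Cox model with backward elimination
#'
#' Candidates are pre-screened by univariate Wald p-value at `p_enter`;
#' the multivariate model then iteratively drops the feature with the
#' largest p-value at or above `p_stay` (ties: the later-listed feature is
#' dropped) until all remaining features satisfy `p < p_stay`.
#'
#' @param candidates Data frame of candidate features.
#' @param time,event Follow-up time and event indicator.
#' @param p_enter Univariate entry criterion (default 0.2).
#' @param p_stay Multivariate stay criterion (default 0.05).
#' @return A list: `retained` (character), `fit` (a `"cox_result"` or NULL
#'   for the empty model), `univariate_p`.
#' @export
backward_elimination <- function(candidates, time, event,
                                 p_enter = 0.2, p_stay = 0.05) {
  candidates <- as.data.frame(candidates)
  uni <- vapply(candidates, function(v)
    cox_fit(v, time, event)$p_values[[1]], numeric(1))
  keep <- names(candidates)[uni <= p_enter]
  if (length(keep) == 0)
    return(list(retained = character(0), fit = NULL, univariate_p = uni))
  repeat {
    fit <- cox_fit(candidates[keep], time, event)
    p <- fit$p_values
    worst <- max(p)
    if (worst < p_stay) break
    drop_i <- max(which(p >= worst - 1e-15))  # ties: remove the later-listed
    keep <- keep[-drop_i]
    if (length(keep) == 0)
      return(list(retained = character(0), fit = NULL, univariate_p = uni))
  }
  list(retained = keep, fit = fit, univariate_p = uni)
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Kaplan-Meier estimate of the censoring distribution: the event
#' indicator is inverted so censoring is the "event", and the median is
#' the first time the survivor function drops to 0.5 or below.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 = event, 0 = censored); at least one
#'   censored observation is required.
#' @return Median follow-up in months.
#' @export
reverse_km_median <- function(time, event) {
  if (all(event == 1)) stop("all observations are events: median follow-up undefined")
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  i <- which(sf$surv <= 0.5 + 1e-12)
  if (length(i) == 0)
    stop("survivor function never reaches 0.5: median follow-up undefined")
  sf$time[min(i)]
}

#' ROC sample-size calculation (Hanley-McNeil)
#'
#' Finds the smallest number of positive cases `n` such that
#' `z_{alpha/2} SE0 + z_beta SE1 <= auc_alt - 0.5`, with Hanley-McNeil
#' variances under the null AUC 0.5 (`SE0`) and the alternative
#' (`SE1`), and `ratio` negatives per positive.
#'
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.80).
#' @param auc_alt Alternative AUC, in (0.5, 1).
#' @param neg_per_pos_ratio Negatives per positive case (>= 1).
#' @return A list: `n_positive`, `n_total`.
#' @export
roc_sample_size <- function(alpha = 0.05, power = 0.80, auc_alt,
                            neg_per_pos_ratio = 1) {
  stop_if_not_scalar_number(auc_alt, "auc_alt")
  if (auc_alt <= 0.5 || auc_alt >= 1)
    stop("`auc_alt` must lie strictly between 0.5 and 1")
  if (neg_per_pos_ratio < 1) stop("`neg_per_pos_ratio` must be >= 1")
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  delta <- auc_alt - 0.5
  for (n_pos in 2:100000) {
    n_neg <- ceiling(neg_per_pos_ratio * n_pos)
    se0 <- sqrt(hanley_mcneil_var(0.5, n_pos, n_neg))
    se1 <- sqrt(hanley_mcneil_var(auc_alt, n_pos, n_neg))
    if (za * se0 + zb * se1 <= delta)
      return(list(n_positive = n_pos, n_total = n_pos + n_neg))
  }
  stop("no feasible sample size below 100000 positives")
}

#' Full optimism-bootstrap validation of one feature
#'
#' Applies the optimism bootstrap to both prognostic readouts of a single
#' per-patient feature: the continuous-value AUC, and the Cox log hazard
#' ratio of the optimal-cutpoint dichotomization. Cutpoint selection is
#' repeated inside every resample, so the correction accounts for the
#' cutpoint optimization.
#'
#' @param values Per-patient feature values.
#' @param time,event Follow-up and event indicator.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Optional seed.
#' @param min_group_fraction Passed to [optimal_cutpoint()].
#' @return A list: `auc` (a `"boot_corrected"` on the AUC scale), `cox`
#'   (a `"boot_corrected"` on the log-HR scale), `corrected_hr`,
#'   `cutpoint`, `cox_fit`.
#' @export
validate_subset <- function(values, time, event, B = 1000, seed = NULL,
                            min_group_fraction = 0.1) {
  data <- data.frame(v = values, time = time, event = event)
  both_classes <- function(d) length(unique(d$event)) == 2
  auc_eval <- function(train, test) auc_mann_whitney(test$v, test$event)$auc
  cox_eval <- function(train, test) {
    tryCatch({
      ct <- optimal_cutpoint(train$v, train$time, train$event,
                             min_group_fraction)$cutpoint
      cox_fit(as.numeric(test$v > ct), test$time, test$event)$coefficients[[1]]
    }, error = function(e) NA_real_)
  }
  auc_bc <- bootstrap_correct(auc_eval, data, B = B, seed = seed,
                              strata = "event", valid = both_classes)
  cox_bc <- bootstrap_correct(cox_eval, data, B = B,
                              seed = if (is.null(seed)) NULL else seed + 1,
                              strata = "event", valid = both_classes)
  ct <- optimal_cutpoint(values, time, event, min_group_fraction)
  fit <- cox_fit(as.numeric(values > ct$cutpoint), time, event)
  list(auc = auc_bc, cox = cox_bc, corrected_hr = exp(cox_bc$corrected),
       cutpoint = ct$cutpoint, cox_fit = fit)
}
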