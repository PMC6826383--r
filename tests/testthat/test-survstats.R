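test_that("AUC equals brute-force pair counting, including ties", {
  a <- auc_mann_whitney(c(3, 5, 1, 3, 4), c(1, 1, 0, 0, 0))
  expect_equal(a$auc, 0.75)            # (1 + 0.5 + 0 + 3 + ...) / 6
  expect_equal(auc_mann_whitney(c(10, 9, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc_mann_whitney(rep(2, 6), c(1, 1, 0, 0, 0, 0))$auc, 0.5)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    v <- sample(1:12, n, replace = TRUE)  # heavy ties
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(auc_mann_whitney(v, l)$auc, auc_brute(v, l))
  }
  expect_error(auc_mann_whitney(1:5, rep(1, 5)), "both outcome classes")
})

test_that("AUC of a feature and of its negation sum to one", {
  set.seed(6)
  for (rep in 1:10) {
    v <- rnorm(30)
    l <- rbinom(30, 1, 0.3)
    if (length(unique(l)) < 2) next
    expect_equal(auc_mann_whitney(v, l)$auc + auc_mann_whitney(-v, l)$auc, 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(7)
  v <- rnorm(60)
  l <- rbinom(60, 1, 0.3)
  expect_equal(auc_mann_whitney(v, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, v, direction = "<",
                                              quiet = TRUE))))
})

test_that("orientation is preserved: low-risk features report AUC below 0.5", {
  v <- c(5, 4, 10, 9, 8, 7)
  l <- c(1, 1, 0, 0, 0, 0)
  expect_lt(auc_mann_whitney(v, l)$auc, 0.5)
})

test_that("optimism bootstrap is exact for constants and reproducible", {
  d <- data.frame(x = rnorm(30), event = rbinom(30, 1, 0.3))
  bc <- bootstrap_correct(function(tr, te) 0.42, d, B = 50, seed = 3)
  expect_equal(bc$corrected, 0.42)
  expect_equal(bc$optimism, 0)
  f <- function(tr, te) mean(te$x[seq_len(min(10, nrow(te)))])
  b1 <- bootstrap_correct(f, d, B = 100, seed = 9)
  b2 <- bootstrap_correct(f, d, B = 100, seed = 9)
  expect_identical(b1, b2)
  expect_error(bootstrap_correct(function(tr, te) 1, d, B = 0), "B >= 1")
})

test_that("corrected AUC of pure-noise features is centered on 0.5", {
  set.seed(123)
  corr <- replicate(15, {
    d <- data.frame(v = rnorm(102), event = rep(c(1, 0), c(20, 82)))
    bootstrap_correct(function(tr, te) auc_mann_whitney(te$v, te$event)$auc,
                      d, B = 200, strata = "event")$corrected
  })
  expect_lt(abs(mean(corr) - 0.5), 0.05)
})

test_that("own log-rank statistic matches survival::survdiff", {
  set.seed(8)
  for (rep in 1:15) {
    n <- sample(20:60, 1)
    g <- rbinom(n, 1, 0.5)
    time <- sample(1:40, n, replace = TRUE)   # ties included
    event <- rbinom(n, 1, 0.6)
    if (sum(event) < 2 || length(unique(g)) < 2) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(logrank_chi2(g, time, event), sd$chisq, tolerance = 1e-8)
  }
})

test_that("optimal cutpoint maximizes the log-rank statistic over admissible splits", {
  v <- c(1, 1, 1, 9, 9, 9)
  time <- c(50, 60, 70, 5, 10, 15)
  event <- c(0, 0, 0, 1, 1, 1)
  ct <- optimal_cutpoint(v, time, event)
  expect_equal(ct$cutpoint, 5)             # only admissible split class
  expect_error(optimal_cutpoint(rep(3, 6), time, event), "distinct")
  # recovery: two separated classes -> cutpoint between the class means
  set.seed(10)
  n <- 80
  grp <- rep(0:1, each = n / 2)
  vals <- rnorm(n, mean = ifelse(grp == 1, 15, 5), sd = 2)
  tt <- rexp(n, rate = ifelse(grp == 1, 0.05, 0.005))
  ev <- as.integer(tt < 60)
  tt <- pmin(tt, 60)
  ct2 <- optimal_cutpoint(vals, tt, ev)
  expect_gt(ct2$cutpoint, 5)
  expect_lt(ct2$cutpoint, 15)
})

test_that("Cox fit matches a grid-maximized Breslow partial likelihood", {
  x <- c(0, 1, 0, 1, 0, 1)
  time <- c(2, 3, 5, 7, 9, 11)
  event <- c(1, 1, 1, 0, 1, 0)
  fit <- cox_fit(x, time, event)
  oracle <- stats::optimize(function(b) breslow_loglik(b, x, time, event),
                            c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(unname(fit$coefficients[1]), oracle, tolerance = 1e-4)
  expect_equal(unname(fit$hr[1]), exp(oracle), tolerance = 1e-4)
  # two identical groups: no effect
  fit0 <- cox_fit(rep(c(0, 1), 5), rep(1:5, 2), rep(c(1, 1, 0, 0, 1), 2))
  expect_equal(unname(fit0$coefficients[1]), 0, tolerance = 1e-6)
  expect_error(cox_fit(x, time, rep(0, 6)), "at least one event")
})

test_that("monotone likelihood raises an explicit failure", {
  x <- c(1, 1, 1, 0, 0, 0)
  time <- c(1, 2, 3, 10, 11, 12)
  event <- c(1, 1, 1, 0, 0, 0)
  expect_error(cox_fit(x, time, event), "monotone|infinite|converge")
})

test_that("backward elimination keeps strong features and honors its criteria", {
  set.seed(12)
  n <- 300
  x_strong <- rnorm(n)
  rate <- 0.02 * exp(1.0 * x_strong)
  tt <- rexp(n, rate)
  ev <- as.integer(tt < 40)
  tt <- pmin(tt, 40)
  cand <- data.frame(strong = x_strong, n1 = rnorm(n), n2 = rnorm(n),
                     n3 = rnorm(n))
  kept <- replicate(8, {
    idx <- sample.int(n, n, replace = TRUE)
    be <- backward_elimination(cand[idx, ], tt[idx], ev[idx])
    "strong" %in% be$retained
  })
  expect_gte(mean(kept), 0.9)
  # single significant candidate is retained unchanged
  be1 <- backward_elimination(cand["strong"], tt, ev)
  expect_equal(be1$retained, "strong")
  # all-null candidates may yield the empty model
  set.seed(14)
  be0 <- backward_elimination(data.frame(a = rnorm(40)), rexp(40, 0.05),
                              rbinom(40, 1, 0.3), p_enter = 1e-6)
  expect_equal(be0$retained, character(0))
  expect_null(be0$fit)
})

test_that("reverse Kaplan-Meier median matches hand-computed tables", {
  expect_equal(reverse_km_median(c(10, 20, 30), c(0, 0, 0)), 20)
  expect_error(reverse_km_median(c(5, 8), c(1, 1)), "undefined")
  # hand table: censorings at 10 and 15 -> S drops 2/3 then 1/3
  expect_equal(reverse_km_median(c(5, 10, 15, 20), c(1, 0, 0, 1)), 15)
})

test_that("ROC sample-size search reproduces the Hanley-McNeil solution", {
  ss <- roc_sample_size(0.05, 0.80, 0.72, 4)
  expect_equal(ss$n_positive, 17)
  expect_equal(ss$n_total, 85)
  # hand-iterated inequality: 17 passes, 16 fails
  lhs <- function(np) {
    qnorm(0.975) * sqrt(hanley_mcneil_var(0.5, np, 4 * np)) +
      qnorm(0.80) * sqrt(hanley_mcneil_var(0.72, np, 4 * np))
  }
  expect_lte(lhs(17), 0.22)
  expect_gt(lhs(16), 0.22)
  expect_error(roc_sample_size(0.05, 0.8, 0.5, 4), "between 0.5 and 1")
  expect_lt(roc_sample_size(0.05, 0.8, 0.9, 4)$n_positive, 17)
})

test_that("cutpoint optimization is anti-conservative uncorrected and the bootstrap shrinks the selected effect", {
  set.seed(15)
  n <- 60
  p_vals <- shrunk <- logical(20)
  for (r in 1:20) {
    v <- rnorm(n)                       # pure noise feature
    tt <- rexp(n, 0.02)
    ev <- as.integer(tt < 50)
    tt <- pmin(tt, 50)
    if (sum(ev) < 5) { p_vals[r] <- NA; next }
    ct <- optimal_cutpoint(v, tt, ev)
    p_vals[r] <- pchisq(ct$chi2, 1, lower.tail = FALSE) < 0.05
    vs <- validate_subset(v, tt, ev, B = 120, seed = r)
    shrunk[r] <- abs(vs$cox$corrected) <= abs(vs$cox$apparent) + 1e-9
  }
  # maximally selected statistics reject far above the nominal 5% level
  expect_gte(mean(p_vals, na.rm = TRUE), 0.2)
  # the optimism correction pulls the selected log-HR toward zero
  expect_gte(mean(shrunk, na.rm = TRUE), 0.8)
})
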