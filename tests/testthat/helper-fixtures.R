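# shared fixture builders (all generated in code; no files)

digital_disk <- function(r, pad = 4, off = c(0, 0)) {
  n <- 2 * ceiling(r + max(abs(off))) + 2 * pad + 1
  cx <- (n + 1) / 2 + off[1]
  cy <- (n + 1) / 2 + off[2]
  outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
}

digital_rect <- function(w, h, pad = 3) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

plus_pentomino_mask <- function() {
  m <- matrix(FALSE, 9, 9)
  m[cbind(5 + c(0, -1, 1, 0, 0), 5 + c(0, 0, 0, -1, 1))] <- TRUE
  m
}

# small fast morphology for cohort-level tests
small_morphology <- function(...) {
  morphology_spec(dim = c(96, 96), cluster_lambda = 2, debris_lambda = 8, ...)
}

small_cohort <- function(n = 24, events = 6, images = 2, seed = 1, ...) {
  simulate_cohort(
    cohort_spec(n_patients = n, n_events = events, images_per_patient = images,
                morphology = small_morphology(), ...),
    seed = seed)
}

# independent brute-force AUC oracle: explicit pair counting
auc_brute <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# independent Breslow partial log-likelihood (for the Cox grid oracle)
breslow_loglik <- function(beta, x, time, event) {
  lp <- beta * x
  ll <- 0
  for (t in unique(time[event == 1])) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(lp[d]) - length(d) * log(sum(exp(lp[risk])))
  }
  ll
}
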