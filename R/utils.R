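# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. `seed = NULL` leaves the
# RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
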