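# Standard gravity used for all body-weight <-> Newton conversions.
.g0 <- 9.80665

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Draw from N(mean, sd) truncated to [lower, upper] by rejection, falling
# back to clamping if the window is extremely improbable.
rnorm_clamped <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(100L)) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

stop_config <- function(...) stop(..., call. = FALSE)
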