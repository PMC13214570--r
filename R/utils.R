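#' @keywords internal
"_PACKAGE"

## Local RNG scoping: every stochastic routine takes an explicit seed and
## restores the caller's .Random.seed, so package functions never perturb
## the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic child-seed derivation; keeps results < 2^31 so they are
## valid R integer seeds.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 7919 + (as.numeric(p) %% 104729) + 17) %% 2147483587
  as.integer(h) + 1L
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

## population (divide-by-n) standard deviation, fixed convention throughout
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

col_sd_pop <- function(X) {
  m <- colMeans(X)
  sqrt(colMeans(X^2) - m^2)
}
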