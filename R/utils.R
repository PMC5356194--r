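#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporarily seeded RNG, restoring global state afterwards.
## Every stochastic operation in the package routes through this, so results
## are reproducible from (seed, parameters) alone and no stage leaks into the
## caller's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Trapezoid quadrature weights for a uniform grid.
trapz_weights <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  dx <- x[2L] - x[1L]
  w <- rep(dx, n)
  w[c(1L, n)] <- dx / 2
  w
}

trapz <- function(x, y) sum(trapz_weights(x) * y)
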