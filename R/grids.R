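#' Distance grid for P(r)
#'
#' Uniformly spaced, strictly increasing distances (nm) on which distance
#' distributions and the dipolar kernel are discretized.  The defaults cover
#' the range accessible to nitroxide DEER (1.5--8 nm).
#'
#' @param r_min,r_max grid limits in nm (both > 0).
#' @param n number of points (>= 2).
#' @return numeric vector of distances in nm.
#' @export
#' @examples
#' r <- distance_grid()
#' range(r)
distance_grid <- function(r_min = 1.5, r_max = 8.0, n = 256L) {
  stopifnot(r_min > 0, r_max > r_min, n >= 2L)
  seq(r_min, r_max, length.out = as.integer(n))
}

#' Dipolar evolution time grid
#'
#' Uniform time axis in microseconds starting at zero, matching the layout of
#' background-corrected four-pulse DEER traces.
#'
#' @param t_max maximum dipolar evolution time in us.
#' @param n number of points (>= 2).
#' @return numeric vector of times in us.
#' @export
time_grid <- function(t_max = 3.2, n = 256L) {
  stopifnot(t_max > 0, n >= 2L)
  seq(0, t_max, length.out = as.integer(n))
}

assert_distance_grid <- function(r) {
  if (length(r) < 2L) stop("distance grid needs at least 2 points", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("distance grid must be finite and strictly positive", call. = FALSE)
  }
  d <- diff(r)
  if (any(d <= 0)) stop("distance grid must be strictly increasing", call. = FALSE)
  if (diff(range(d)) > 1e-12 * mean(d)) {
    stop("distance grid must be uniformly spaced", call. = FALSE)
  }
  invisible(r)
}

assert_time_grid <- function(t) {
  if (length(t) < 2L) stop("time grid needs at least 2 points", call. = FALSE)
  if (any(!is.finite(t))) stop("time grid must be finite", call. = FALSE)
  if (t[1L] != 0) stop("time grid must start at 0", call. = FALSE)
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  invisible(t)
}
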