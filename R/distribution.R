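#' Gaussian component of a conformer-state mixture
#'
#' One state of the compact/extended (S/S*) two-state model: a Gaussian
#' distance component with mean `r` (nm), standard deviation `sigma` (nm)
#' and mixture `weight` (population fraction).
#'
#' @param r mean inter-spin distance, nm.
#' @param sigma standard deviation, nm (> 0).
#' @param weight population fraction in \[0, 1\].
#' @return a list of class `gaussian_component`.
#' @export
gaussian_component <- function(r, sigma, weight = 1) {
  stopifnot(is.finite(r), r > 0, is.finite(sigma), sigma > 0,
            is.finite(weight), weight >= 0, weight <= 1)
  structure(list(r = r, sigma = sigma, weight = weight),
            class = "gaussian_component")
}

#' Distance distribution container
#'
#' A non-negative probability density P(r) on a uniform distance grid,
#' normalized to unit area by the trapezoid rule.  Distributions are stored
#' as unit-area densities throughout; peak normalization (density scaled to
#' one at its maximum, as DEER distributions are commonly displayed) is a
#' display option, see [peak_normalize()].
#'
#' @param r distance grid, nm.
#' @param density density values, per nm (non-negative).
#' @param normalize renormalize to unit area (default TRUE).
#' @return object of class `distance_distribution` with fields `r`, `density`.
#' @export
distance_distribution <- function(r, density, normalize = TRUE) {
  assert_distance_grid(r)
  stopifnot(length(density) == length(r))
  if (any(!is.finite(density)) || any(density < -1e-12)) {
    stop("density must be finite and non-negative", call. = FALSE)
  }
  density <- pmax(density, 0)
  if (normalize) {
    a <- trapz(r, density)
    if (a <= 0) stop("density has zero area; cannot normalize", call. = FALSE)
    density <- density / a
  }
  structure(list(r = r, density = density), class = "distance_distribution")
}

#' Gaussian mixture to distance distribution
#'
#' Evaluates a one- or two-component Gaussian mixture on a distance grid and
#' renormalizes on the truncated grid, giving the ground-truth P(r) of the
#' two-state (S/S*) model: \eqn{P(r) = \sum_i w_i N(r; r_i, \sigma_i)}.
#'
#' @param components list of [gaussian_component()] (1 or 2); weights must
#'   sum to 1.
#' @param grid distance grid (nm).
#' @return a [distance_distribution].
#' @export
#' @examples
#' g <- distance_grid()
#' P <- mixture_to_distribution(list(gaussian_component(3.16, 0.98, 1)), g)
mixture_to_distribution <- function(components, grid) {
  if (length(components) < 1L) stop("need at least one component", call. = FALSE)
  if (length(components) > 2L) {
    stop("the two-state model admits at most two components", call. = FALSE)
  }
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("component weights must sum to 1", call. = FALSE)
  }
  assert_distance_grid(grid)
  dens <- rep(0, length(grid))
  for (cm in components) {
    dens <- dens + cm$weight * stats::dnorm(grid, cm$r, cm$sigma)
  }
  distance_distribution(grid, dens)
}

#' Peak-normalized copy of a distribution (display convention)
#'
#' Returns density scaled to unity at its maximum, the convention in which
#' DEER distance distributions are usually plotted.  Populations and all
#' fitting are defined on the unit-area form.
#'
#' @param dist a [distance_distribution].
#' @return list with `r` and `density` (max 1); not a unit-area distribution.
#' @export
peak_normalize <- function(dist) {
  stopifnot(inherits(dist, "distance_distribution"))
  m <- max(dist$density)
  if (m <= 0) stop("cannot peak-normalize an empty distribution", call. = FALSE)
  list(r = dist$r, density = dist$density / m)
}

## First and second moments of a distribution by the trapezoid rule.
distribution_moments <- function(dist) {
  mu <- trapz(dist$r, dist$r * dist$density)
  v <- trapz(dist$r, (dist$r - mu)^2 * dist$density)
  c(mean = mu, sd = sqrt(max(v, 0)))
}

#' @export
print.distance_distribution <- function(x, ...) {
  m <- distribution_moments(x)
  cat(sprintf("Distance distribution on [%.3g, %.3g] nm (%d pts): mean %.3f nm, sd %.3f nm\n",
              min(x$r), max(x$r), length(x$r), m["mean"], m["sd"]))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ..., peak = FALSE) {
  y <- if (peak) peak_normalize(x)$density else x$density
  graphics::plot(x$r, y, type = "l", xlab = "r (nm)",
                 ylab = if (peak) "P(r) / max" else "P(r) (1/nm)", ...)
  invisible(x)
}
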