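#' Fit a DEER trace: background, inversion, two-state populations
#'
#' The central fitting function of the package.  Takes a measured (or
#' simulated) dipolar evolution trace and performs the full analysis chain:
#' (1) tail fit and removal of the multiplicative intermolecular background,
#' with joint estimation of the modulation depth; (2) non-negative Tikhonov
#' inversion with L-curve selection of the regularization parameter,
#' optionally refined by maximum entropy under the chi-squared discrepancy
#' principle; (3) constrained one/two-Gaussian fitting of the reconstructed
#' distance distribution, yielding the compact (S) and extended (S*) state
#' means, widths and populations.
#'
#' @param trace a [deer_trace] (V(0) = 1 within noise).
#' @param n_components 1, 2, or `"auto"` (F-ratio model selection).
#' @param r_grid distance grid for the reconstruction; default
#'   `distance_grid()` (1.5--8 nm, 256 points).
#' @param fit_start_fraction start of the background window (default 0.6).
#' @param background_d background dimensionality held fixed (default 3), or
#'   `NULL` to fit it.
#' @param lambda modulation depth override; by default estimated from the
#'   background tail intercept.
#' @param alpha_grid L-curve alpha grid; default 40 log-spaced points over 8
#'   decades relative to the kernel norm.
#' @param maxent logical: refine the Tikhonov solution by maximum entropy
#'   (default TRUE).
#' @param frozen named list of Gaussian parameters to freeze (see
#'   [fit_gaussians()]).
#' @param seed integer seed for the multi-start fitting.
#' @return an object of class `deer_fit` with components `trace`,
#'   `background` (the `background_fit`), `form_factor` (corrected signal),
#'   `inversion` (`deer_inversion`), `distribution` (final P(r)), `fit`
#'   (`two_state_fit`), `kernel`, `call`.
#' @seealso [simulate_deer()], [fit_gaussians()], [l_curve_select()]
#' @export
#' @examples
#' sim <- simulate_deer(list(gaussian_component(3.16, 0.98, 1)),
#'                      n_t = 64, n_r = 64, snr = 100, seed = 1)
#' fit <- deer_fit(sim$trace, n_components = 1, r_grid = sim$kernel$r)
#' coef(fit)
deer_fit <- function(trace, n_components = "auto", r_grid = distance_grid(),
                     fit_start_fraction = 0.6, background_d = 3,
                     lambda = NULL, alpha_grid = NULL, maxent = TRUE,
                     frozen = NULL, seed = 1L) {
  stopifnot(inherits(trace, "deer_trace"))
  cl <- match.call()

  kern <- build_kernel(trace$t, r_grid)
  bg <- fit_background(trace, fit_start_fraction, background_d)
  if (!is.null(lambda)) bg$lambda <- lambda
  ff <- remove_background(trace, bg)
  inv <- l_curve_select(ff, kern, alpha_grid)
  if (is.null(lambda)) {
    ## the tail fit is biased when the dipolar oscillation has not decayed
    ## inside the window (slow oscillations of extended states); refine
    ## (k, lambda) jointly with a parametric two-state dipolar model on the
    ## full trace, then re-invert
    for (it in 1:2) {
      f0 <- fit_gaussians(inv$distribution, 2L, seed = seed,
                          resolution = inv$resolution)
      bg <- joint_background_fit(trace, kern, bg, f0)
      ff <- remove_background(trace, bg)
      inv <- l_curve_select(ff, kern, alpha_grid)
    }
  }
  dist <- inv$distribution
  if (maxent) dist <- maxent_auto(ff, kern, dist)

  fit <- if (identical(n_components, "auto")) {
    f1 <- fit_gaussians(dist, 1L, frozen = frozen, seed = seed)
    f2 <- fit_gaussians(dist, 2L, frozen = frozen, seed = seed)
    select_model(f1, f2)
  } else {
    fit_gaussians(dist, as.integer(n_components), frozen = frozen, seed = seed)
  }

  structure(list(trace = trace, background = bg, form_factor = ff,
                 kernel = kern, inversion = inv, distribution = dist,
                 fit = fit, maxent = maxent, seed = seed, call = cl),
            class = "deer_fit")
}

#' @export
print.deer_fit <- function(x, ...) {
  cat("DEER two-state population fit\n")
  cat(sprintf("  background: k = %.4g 1/us (d = %.3g), lambda = %.3f\n",
              x$background$model$k, x$background$model$d, x$background$lambda))
  cat(sprintf("  inversion:  alpha = %.4g%s%s\n", x$inversion$alpha,
              if (x$inversion$fallback) " (L-curve fallback)" else " (L-curve corner)",
              if (x$maxent) ", maxent refined" else ""))
  print(x$fit)
  invisible(x)
}

#' @export
summary.deer_fit <- function(object, ...) {
  f <- object$fit
  tab <- if (f$n_components == 2L) {
    data.frame(state = c("S", "Sstar"),
               r = c(f$r_S, f$r_Sstar),
               sigma = c(f$sigma_S, f$sigma_Sstar),
               p = c(f$p, 1 - f$p))
  } else {
    data.frame(state = "S", r = f$r_S, sigma = f$sigma_S, p = 1)
  }
  structure(list(fit_table = tab, r_squared = f$r_squared,
                 alpha = object$inversion$alpha,
                 lambda = object$background$lambda,
                 background_k = object$background$model$k,
                 n_points = length(object$trace$t),
                 fallback = object$inversion$fallback),
            class = "summary.deer_fit")
}

#' @export
print.summary.deer_fit <- function(x, ...) {
  cat("DEER analysis summary\n")
  cat(sprintf("  %d time points; lambda = %.3f; background k = %.4g 1/us\n",
              x$n_points, x$lambda, x$background_k))
  cat(sprintf("  regularization alpha = %.4g; fit R^2 = %.4f\n",
              x$alpha, x$r_squared))
  print(x$fit_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.deer_fit <- function(object, ...) coef(object$fit)

#' Predictions from a fitted DEER analysis
#'
#' @param object a `deer_fit`.
#' @param type `"distribution"` (fitted Gaussian model density on the
#'   reconstruction grid), `"form_factor"` (the signal implied by the
#'   reconstructed distribution) or `"trace"` (form factor times fitted
#'   background, on the original scale).
#' @param ... unused.
#' @return numeric vector on the corresponding grid.
#' @export
predict.deer_fit <- function(object, type = c("distribution", "form_factor",
                                              "trace"), ...) {
  type <- match.arg(type)
  if (type == "distribution") {
    return(predict(object$fit, object$distribution$r))
  }
  lam <- object$background$lambda
  ff <- (1 - lam) + lam * apply_kernel(object$kernel, object$distribution)
  if (type == "form_factor") return(ff)
  ff * background_decay(object$background$model, object$trace$t)
}

#' @export
fitted.deer_fit <- function(object, ...) predict(object, "trace")

#' Residuals of a fitted DEER analysis
#'
#' @param object a `deer_fit`.
#' @param type `"time"` (measured minus reconstructed trace) or
#'   `"distance"` (reconstructed density minus fitted Gaussian model).
#' @param ... unused.
#' @export
residuals.deer_fit <- function(object, type = c("time", "distance"), ...) {
  type <- match.arg(type)
  if (type == "time") {
    object$trace$signal - predict(object, "trace")
  } else {
    object$distribution$density - predict(object, "distribution")
  }
}

#' Simulate new traces from a fitted DEER analysis
#'
#' Parametric simulation: forward-simulates the fitted two-state Gaussian
#' model through the fitted background and modulation depth, adding noise at
#' the level estimated from the data.
#'
#' @param object a `deer_fit`.
#' @param nsim number of traces.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [deer_trace] of length `nsim`.
#' @export
simulate.deer_fit <- function(object, nsim = 1, seed = 1L, ...) {
  f <- object$fit
  comps <- if (f$n_components == 2L) {
    list(gaussian_component(f$r_S, f$sigma_S, f$p),
         gaussian_component(f$r_Sstar, f$sigma_Sstar, 1 - f$p))
  } else {
    list(gaussian_component(f$r_S, f$sigma_S, 1))
  }
  dist <- mixture_to_distribution(comps, object$kernel$r)
  ff <- simulate_form_factor(dist, object$kernel, object$background$lambda)
  sigma <- object$trace$noise_sigma
  if (is.na(sigma)) sigma <- stats::sd(residuals(object, "time"))
  snr <- if (sigma > 0) object$background$lambda / sigma else Inf
  lapply(seq_len(nsim), function(i) {
    apply_background_and_noise(ff, object$background$model, snr,
                               seed = seed + i - 1L)
  })
}

#' Plot a fitted DEER analysis
#'
#' Two panels: the measured trace with the fitted reconstruction, and the
#' reconstructed distance distribution with the fitted Gaussian components.
#'
#' @param x a `deer_fit`.
#' @param ... passed to the base plot calls.
#' @export
plot.deer_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$trace$t, x$trace$signal, type = "l", col = "grey40",
                 xlab = "t (us)", ylab = "V(t)", main = "DEER trace", ...)
  graphics::lines(x$trace$t, predict(x, "trace"), col = "red")
  graphics::plot(x$distribution$r, x$distribution$density, type = "l",
                 xlab = "r (nm)", ylab = "P(r) (1/nm)",
                 main = "Distance distribution", ...)
  graphics::lines(x$distribution$r, predict(x, "distribution"),
                  col = "red", lty = 2)
  invisible(x)
}
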