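#' Fit the intermolecular background of a DEER trace
#'
#' On the tail of the trace, where the intramolecular dipolar oscillation has
#' decayed, the signal approaches \eqn{V(t) \approx (1-\lambda)
#' \exp(-k t^{d/3})}.  A linear least-squares fit of \eqn{\ln V(t)} against
#' \eqn{t^{d/3}} over the tail window yields the background rate `k` and the
#' modulation depth \eqn{\lambda} from the intercept.  With `dimension_fixed
#' = NULL` the effective dimensionality `d` is profiled over \[1, 6\] by a
#' 1-D optimization of the window residual.
#'
#' @param trace a [deer_trace].
#' @param fit_start_fraction start of the fit window as a fraction of the
#'   trace length, in (0, 1); default 0.6.
#' @param dimension_fixed background dimensionality to hold fixed (default
#'   3), or `NULL` to fit it.
#' @return object of class `background_fit`: list with `model`
#'   ([background_model]), `lambda`, `fit_window`, `rms_residual`.
#' @export
fit_background <- function(trace, fit_start_fraction = 0.6,
                           dimension_fixed = 3) {
  stopifnot(inherits(trace, "deer_trace"))
  if (fit_start_fraction <= 0 || fit_start_fraction >= 1) {
    stop("fit_start_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- length(trace$t)
  i0 <- max(2L, ceiling(fit_start_fraction * n))
  idx <- i0:n
  if (length(idx) < 16L) {
    stop("background window too short: need >= 16 points after fit_start_fraction",
         call. = FALSE)
  }
  v <- trace$signal[idx]
  if (any(v <= 0)) {
    stop("non-positive signal values in background window; cannot take log",
         call. = FALSE)
  }
  tt <- trace$t[idx]
  lv <- log(v)

  fit_for_d <- function(d) {
    x <- tt^(d / 3)
    f <- stats::lm.fit(cbind(1, x), lv)
    list(d = d, intercept = f$coefficients[1L], k = -f$coefficients[2L],
         rms = sqrt(mean(f$residuals^2)))
  }

  if (is.null(dimension_fixed)) {
    opt <- stats::optimize(function(d) fit_for_d(d)$rms, c(1, 6))
    best <- fit_for_d(opt$minimum)
  } else {
    stopifnot(dimension_fixed >= 1, dimension_fixed <= 6)
    best <- fit_for_d(dimension_fixed)
  }
  k <- max(best$k, 0)
  lambda <- 1 - exp(best$intercept)
  structure(list(model = background_model(k, best$d), lambda = lambda,
                 fit_window = 1 - fit_start_fraction,
                 fit_start_fraction = fit_start_fraction,
                 rms_residual = best$rms),
            class = "background_fit")
}

#' @export
print.background_fit <- function(x, ...) {
  cat(sprintf("Background fit: k = %.4g 1/us, d = %.3g, lambda = %.3f, rms = %.3g\n",
              x$model$k, x$model$d, x$lambda, x$rms_residual))
  invisible(x)
}

#' Self-consistent refinement of the background fit
#'
#' The tail fit of [fit_background()] assumes the intramolecular dipolar
#' oscillation has decayed inside the fit window.  For extended-state
#' distributions (long distances, slow oscillation) this is not true over a
#' 3 us trace, which biases both the decay rate and the modulation depth.
#' Given a current estimate of the distance distribution, this refines
#' (k, lambda) by least squares on the full trace against the complete model
#' \eqn{V(t) = [(1-\lambda) + \lambda (KP)(t)] \exp(-k t^{d/3})}.
#'
#' @param trace the measured [deer_trace].
#' @param fit current `background_fit`.
#' @param kernel a `deer_kernel` on the trace's time grid.
#' @param dist current estimate of the distance distribution.
#' @return an updated `background_fit`.
#' @export
refine_background <- function(trace, fit, kernel, dist) {
  stopifnot(inherits(trace, "deer_trace"), inherits(kernel, "deer_kernel"),
            inherits(dist, "distance_distribution"))
  s_mod <- apply_kernel(kernel, dist)
  d <- fit$model$d
  tt <- trace$t
  obj <- function(th) {
    k <- th[1L]; lam <- th[2L]
    sum((trace$signal - ((1 - lam) + lam * s_mod) * exp(-k * tt^(d / 3)))^2)
  }
  st <- c(max(fit$model$k, 1e-4), min(max(fit$lambda, 0.02), 0.98))
  opt <- stats::optim(st, obj, method = "L-BFGS-B",
                      lower = c(0, 0.01), upper = c(10, 0.99),
                      control = list(maxit = 500L))
  structure(list(model = background_model(opt$par[1L], d),
                 lambda = opt$par[2L],
                 fit_window = 1, fit_start_fraction = 0,
                 rms_residual = sqrt(opt$value / length(tt))),
            class = "background_fit")
}

## Joint time-domain refinement of (k, lambda) with a parametric two-state
## dipolar model.  A nonparametric reconstruction cannot separate slow
## long-distance dipolar decay from the intermolecular background (ghost
## mass at the top of the distance grid absorbs any background error), so
## the refinement constrains the intramolecular part to a two-Gaussian
## mixture: V(t; k, lambda, theta) = [(1-lambda) + lambda K P_theta] B(t; k).
joint_background_fit <- function(trace, kernel, bg, init) {
  tt <- trace$t
  d <- bg$model$d
  V <- trace$signal
  r <- kernel$r
  obj <- function(th) {
    dens <- th[3L] * stats::dnorm(r, th[4L], th[5L]) +
      (1 - th[3L]) * stats::dnorm(r, th[6L], th[7L])
    a <- trapz(r, dens)
    if (a <= 0) return(1e10)
    s <- (1 - th[2L]) + th[2L] * apply_kernel(kernel, dens / a)
    sum((V - s * exp(-th[1L] * tt^(d / 3)))^2)
  }
  st <- c(max(bg$model$k, 1e-4), min(max(bg$lambda, 0.02), 0.98),
          init$p, init$r_S, init$sigma_S,
          if (is.na(init$r_Sstar)) min(init$r_S + 0.8, 7.9) else init$r_Sstar,
          if (is.na(init$sigma_Sstar)) init$sigma_S else init$sigma_Sstar)
  ## the (k, lambda) valley is shallow; starts straddling the tail estimate
  ## and perturbing the mixture guard against premature termination on its
  ## slopes and against a poor initial decomposition
  starts <- list(st,
                 replace(st, 1:2, c(st[1L] * 1.25, st[2L] * 0.92)),
                 replace(st, 1:2, c(st[1L] * 0.8, st[2L] * 1.08)),
                 replace(st, 3:7, c(0.35, st[4L] - 0.1, st[5L],
                                    max(st[6L], st[4L] + 0.9), st[7L])),
                 replace(st, 3:7, c(0.75, st[4L], st[5L],
                                    max(st[6L], st[4L] + 0.9), st[7L])))
  opt <- NULL
  for (s0 in starts) {
    o <- stats::optim(pmin(pmax(s0, c(0, 0.01, 0, 1.5, 0.05, 1.5, 0.05)),
                           c(10, 0.99, 1, 8, 2, 8, 2)),
                      obj, method = "L-BFGS-B",
                      lower = c(0, 0.01, 0, 1.5, 0.05, 1.5, 0.05),
                      upper = c(10, 0.99, 1, 8, 2, 8, 2),
                      control = list(maxit = 2000L, factr = 1e2))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  structure(list(model = background_model(opt$par[1L], d),
                 lambda = opt$par[2L],
                 fit_window = 1, fit_start_fraction = 0,
                 rms_residual = sqrt(opt$value / length(tt))),
            class = "background_fit")
}

#' Remove the fitted background from a DEER trace
#'
#' The physical model is multiplicative, \eqn{V = F \cdot B}, so removal
#' divides by B(t) and rescales the modulated part:
#' \eqn{S(t) = (V/B - (1-\lambda)) / \lambda}, renormalized so S(0) = 1.
#' The output is the dipolar signal passed to inversion.  A subtractive
#' variant (`method = "subtract"`, \eqn{S \propto V - (1-\lambda) B}) is
#' provided for comparison.
#'
#' @param trace a [deer_trace].
#' @param fit a `background_fit` from [fit_background()], or a list with
#'   elements `model` and `lambda` for manual override.
#' @param method `"divide"` (default) or `"subtract"`.
#' @return a [deer_trace] holding the normalized dipolar signal S(t); its
#'   `noise_sigma` is propagated as `trace$noise_sigma / lambda`.
#' @export
remove_background <- function(trace, fit, method = c("divide", "subtract")) {
  stopifnot(inherits(trace, "deer_trace"))
  method <- match.arg(method)
  lambda <- fit$lambda
  if (!is.finite(lambda) || lambda <= 0 || lambda > 1) {
    stop("estimated modulation depth outside (0, 1]; supply lambda manually",
         call. = FALSE)
  }
  b <- background_decay(fit$model, trace$t)
  s <- switch(method,
              divide = (trace$signal / b - (1 - lambda)) / lambda,
              subtract = (trace$signal - (1 - lambda) * b) / lambda)
  s0 <- s[1L]
  if (abs(s0) < .Machine$double.eps) stop("degenerate signal at t = 0", call. = FALSE)
  s <- s / s0
  ns <- if (is.na(trace$noise_sigma)) NA_real_ else trace$noise_sigma / lambda
  meta <- trace$meta
  meta$lambda_used <- lambda
  meta$background_removed <- TRUE
  deer_trace(trace$t, s, noise_sigma = ns, meta = meta)
}
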