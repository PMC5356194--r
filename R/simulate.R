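#' DEER trace container
#'
#' A dipolar evolution signal V(t) with acquisition metadata.  Traces are
#' normalized to unity at zero time.
#'
#' @param t time grid, us (starting at 0).
#' @param signal signal amplitudes.
#' @param noise_sigma known noise standard deviation (amplitude units), or NA.
#' @param meta named list of metadata (sample label, timepoint label,
#'   modulation depth `lambda` if known, background rate `k`, ...).
#' @return object of class `deer_trace`.
#' @export
deer_trace <- function(t, signal, noise_sigma = NA_real_, meta = list()) {
  assert_time_grid(t)
  stopifnot(length(signal) == length(t), all(is.finite(signal)))
  structure(list(t = t, signal = signal, noise_sigma = noise_sigma,
                 meta = meta), class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  lab <- x$meta$sample %||% "unlabelled"
  tp <- x$meta$timepoint %||% ""
  cat(sprintf("DEER trace '%s'%s: %d points, 0-%.3g us, V(0) = %.4f\n",
              lab, if (nzchar(tp)) paste0(" [", tp, "]") else "",
              length(x$t), max(x$t), x$signal[1L]))
  invisible(x)
}

#' Intermolecular background model
#'
#' Stretched-exponential decay \eqn{B(t) = \exp(-k t^{d/3})} from randomly
#' distributed intermolecular spins; `d = 3` is a homogeneous 3-D spin bath.
#'
#' @param k decay rate, 1/us (>= 0).
#' @param d effective dimensionality in \[1, 6\] (default 3).
#' @return object of class `background_model`.
#' @export
background_model <- function(k = 0.05, d = 3) {
  stopifnot(is.finite(k), k >= 0, is.finite(d), d >= 1, d <= 6)
  structure(list(k = k, d = d), class = "background_model")
}

#' Evaluate a background model
#' @param bg a [background_model].
#' @param t times, us.
#' @return B(t).
#' @export
background_decay <- function(bg, t) {
  stopifnot(inherits(bg, "background_model"))
  exp(-bg$k * t^(bg$d / 3))
}

#' Simulate a noiseless dipolar form factor
#'
#' Forward model of the intramolecular DEER signal:
#' \eqn{F(t) = (1 - \lambda) + \lambda (KP)(t)} with modulation depth
#' \eqn{\lambda}; `F(0) = 1` for a unit-area distribution.
#'
#' @param dist a [distance_distribution] on the kernel's distance grid.
#' @param kernel a `deer_kernel` from [build_kernel()].
#' @param lambda modulation depth in \[0, 1\] (default 0.3, a typical Ku-band
#'   nitroxide value).
#' @return a [deer_trace] with `lambda` recorded in `meta`.
#' @export
simulate_form_factor <- function(dist, kernel, lambda = 0.3) {
  stopifnot(inherits(dist, "distance_distribution"),
            inherits(kernel, "deer_kernel"))
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  s <- (1 - lambda) + lambda * apply_kernel(kernel, dist)
  deer_trace(kernel$t, s, noise_sigma = 0, meta = list(lambda = lambda))
}

#' Apply intermolecular background and noise to a form factor
#'
#' Produces the measured signal \eqn{V(t) = F(t) B(t) + \epsilon(t)} with
#' i.i.d. Gaussian noise of standard deviation \eqn{\lambda/\mathrm{snr}},
#' so recovery difficulty is comparable across modulation depths.
#' Deterministic given `seed`.
#'
#' @param trace a noiseless [deer_trace] from [simulate_form_factor()].
#' @param bg a [background_model].
#' @param snr signal-to-noise ratio relative to the modulation depth
#'   (> 0); `Inf` for noiseless.
#' @param seed integer RNG seed.
#' @return a [deer_trace] with `noise_sigma` recorded.
#' @export
apply_background_and_noise <- function(trace, bg, snr = Inf, seed = 1L) {
  stopifnot(inherits(trace, "deer_trace"), inherits(bg, "background_model"))
  if (!(snr > 0)) stop("snr must be > 0", call. = FALSE)
  lambda <- trace$meta$lambda %||% 0.3
  sig <- trace$signal * background_decay(bg, trace$t)
  sigma <- if (is.infinite(snr)) 0 else lambda / snr
  if (sigma > 0) {
    sig <- sig + with_seed(seed, stats::rnorm(length(sig), 0, sigma))
  }
  meta <- trace$meta
  meta$background_k <- bg$k
  meta$background_d <- bg$d
  meta$seed <- seed
  deer_trace(trace$t, sig, noise_sigma = sigma, meta = meta)
}

#' Simulate a complete synthetic DEER measurement
#'
#' Convenience wrapper: Gaussian-mixture ground truth, dipolar evolution,
#' multiplicative background, additive noise.
#'
#' @param components list of [gaussian_component()].
#' @param t_max maximum evolution time, us.
#' @param n_t,n_r number of time / distance points.
#' @param r_range distance grid range, nm.
#' @param lambda modulation depth.
#' @param k,d background rate (1/us) and dimensionality.
#' @param snr signal-to-noise ratio relative to lambda.
#' @param seed integer RNG seed.
#' @param meta extra metadata merged into the trace.
#' @return list with `trace` ([deer_trace]), `truth` (the ground-truth
#'   [distance_distribution]) and `kernel`.
#' @export
simulate_deer <- function(components, t_max = 3.2, n_t = 256L, n_r = 256L,
                          r_range = c(1.5, 8), lambda = 0.3, k = 0.05, d = 3,
                          snr = 50, seed = 1L, meta = list()) {
  rg <- distance_grid(r_range[1L], r_range[2L], n_r)
  tg <- time_grid(t_max, n_t)
  kern <- build_kernel(tg, rg)
  truth <- mixture_to_distribution(components, rg)
  ff <- simulate_form_factor(truth, kern, lambda)
  ff$meta <- utils::modifyList(ff$meta, meta)
  trace <- apply_background_and_noise(ff, background_model(k, d), snr, seed)
  list(trace = trace, truth = truth, kernel = kern)
}
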