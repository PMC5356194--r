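## Mixture density model: A * [p N(r; r_S, s_S) + (1-p) N(r; r_Sstar, s_Sstar)]
two_state_density <- function(r, par, n_components) {
  if (n_components == 1L) {
    par[["A"]] * stats::dnorm(r, par[["r_S"]], par[["sigma_S"]])
  } else {
    par[["A"]] * (par[["p"]] * stats::dnorm(r, par[["r_S"]], par[["sigma_S"]]) +
                  (1 - par[["p"]]) * stats::dnorm(r, par[["r_Sstar"]], par[["sigma_Sstar"]]))
  }
}

default_fit_bounds <- function() {
  list(r = c(1.5, 8), sigma = c(0.05, 2), p = c(0, 1), A = c(1e-3, 100))
}

#' Constrained one/two-Gaussian fit of a distance distribution
#'
#' Fits the two-state model
#' \deqn{P(r) = A\,[\,p\,N(r; r_S, \sigma_S) + (1-p)\,N(r; r_{S^*},
#' \sigma_{S^*})\,]}
#' to a distance density by constrained nonlinear least squares (box bounds,
#' L-BFGS-B) with seeded multi-start initialization (8 starts derived from
#' mass-quantile splits of the density), keeping the best-residual solution.
#' Components are relabelled so that the S state is the smaller-mean
#' component (\eqn{r_S < r_{S^*}}); `p` is the population of S and `1 - p`
#' that of S*.  Individual parameters may be frozen at fixed values, which
#' supports carrying a previously determined compact-state component across
#' timepoints.
#'
#' @param dist a [distance_distribution].
#' @param n_components 1 or 2.
#' @param bounds list with elements `r`, `sigma`, `p`, `A`, each a
#'   length-2 range; defaults r in \[1.5, 8\] nm, sigma in \[0.05, 2\] nm,
#'   p in \[0, 1\].
#' @param frozen named list of parameters to hold exactly (names among
#'   `r_S`, `sigma_S`, `r_Sstar`, `sigma_Sstar`, `p`, `A`).
#' @param seed integer seed for the multi-start jitter.
#' @param n_starts number of starts (default 8).
#' @param resolution optional square resolution matrix (length(r) x
#'   length(r)) applied to the model density before comparison.  A
#'   regularized inversion returns a smoothed image of the true
#'   distribution; passing the inversion's resolution operator here lets the
#'   Gaussian parameters be estimated on the unsmoothed scale, so means and
#'   widths are comparable across traces inverted at different
#'   regularization strengths.  `NULL` (default) fits the model directly.
#' @return object of class `two_state_fit`: fields `r_S`, `sigma_S`,
#'   `r_Sstar`, `sigma_Sstar` (NA for one component), `p`, `A`,
#'   `r_squared`, `n_components`, `rss`, `n_obs`, `constraint_set`,
#'   `p_at_bound` (flag), `converged`.
#' @export
#' @examples
#' g <- distance_grid()
#' d <- mixture_to_distribution(list(gaussian_component(3.16, 0.98, 0.45),
#'                                   gaussian_component(4.1, 1.1, 0.55)), g)
#' f <- fit_gaussians(d, 2)
#' coef(f)
fit_gaussians <- function(dist, n_components = 2L, bounds = default_fit_bounds(),
                          frozen = NULL, seed = 1L, n_starts = 8L,
                          resolution = NULL) {
  stopifnot(inherits(dist, "distance_distribution"),
            n_components %in% c(1L, 2L))
  b <- utils::modifyList(default_fit_bounds(), bounds %||% list())
  r <- dist$r
  y <- dist$density

  par_names <- if (n_components == 1L) c("A", "r_S", "sigma_S") else
    c("A", "p", "r_S", "sigma_S", "r_Sstar", "sigma_Sstar")
  lower <- c(A = b$A[1], p = b$p[1], r_S = b$r[1], sigma_S = b$sigma[1],
             r_Sstar = b$r[1], sigma_Sstar = b$sigma[1])[par_names]
  upper <- c(A = b$A[2], p = b$p[2], r_S = b$r[2], sigma_S = b$sigma[2],
             r_Sstar = b$r[2], sigma_Sstar = b$sigma[2])[par_names]
  frozen <- frozen %||% list()
  bad <- setdiff(names(frozen), par_names)
  if (length(bad)) stop("unknown frozen parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  free <- setdiff(par_names, names(frozen))

  make_full <- function(theta) {
    full <- as.list(stats::setNames(rep(NA_real_, length(par_names)), par_names))
    full[free] <- as.list(theta)
    full[names(frozen)] <- frozen
    if (n_components == 1L) full$p <- 1
    full
  }
  rss_fun <- function(theta) {
    full <- make_full(theta)
    m <- two_state_density(r, full, n_components)
    if (!is.null(resolution)) m <- drop(resolution %*% m)
    sum((y - m)^2)
  }

  ## moment-based starts: split the density mass at a quantile threshold and
  ## use block moments for the two component means/widths
  cumw <- cumsum(trapz_weights(r) * y)
  cumw <- cumw / cumw[length(cumw)]
  qsplit <- function(qq) r[which.min(abs(cumw - qq))]
  mom <- distribution_moments(dist)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (n_components == 1L) {
        st <- c(A = 1, r_S = mom[["mean"]], sigma_S = mom[["sd"]])
      } else {
        qq <- c(0.3, 0.4, 0.5, 0.6, 0.7, 0.35, 0.55, 0.65)[((i - 1L) %% 8L) + 1L]
        rs <- qsplit(qq)
        lo <- r <= rs
        wl <- trapz_weights(r) * y
        ml <- sum(wl[lo] * r[lo]) / max(sum(wl[lo]), 1e-12)
        mh <- sum(wl[!lo] * r[!lo]) / max(sum(wl[!lo]), 1e-12)
        sl <- sqrt(max(sum(wl[lo] * (r[lo] - ml)^2) / max(sum(wl[lo]), 1e-12), 0.01))
        sh <- sqrt(max(sum(wl[!lo] * (r[!lo] - mh)^2) / max(sum(wl[!lo]), 1e-12), 0.01))
        st <- c(A = 1, p = sum(wl[lo]), r_S = ml, sigma_S = sl,
                r_Sstar = mh, sigma_Sstar = sh)
      }
      if (i > 1L) {  # jitter subsequent starts
        st <- st * exp(stats::rnorm(length(st), 0, 0.08))
        if ("p" %in% names(st)) st[["p"]] <- stats::runif(1)
      }
      pmin(pmax(st[par_names], lower + 1e-9), upper - 1e-9)[free]
    })
  })

  ## a component mean pinned at the distance bounds describes a truncated
  ## half-Gaussian, not a distance state: prefer interior solutions and fall
  ## back to an edge-pinned one only if no start stays interior
  mean_names <- intersect(c("r_S", "r_Sstar"), free)
  is_interior <- function(theta) {
    if (!length(mean_names)) return(TRUE)
    all(theta[mean_names] > b$r[1] + 1e-6 & theta[mean_names] < b$r[2] - 1e-6)
  }
  best <- best_any <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, rss_fun, method = "L-BFGS-B",
                   lower = lower[free], upper = upper[free],
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best_any) || fit$value < best_any$value) best_any <- fit
    if (is_interior(fit$par) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  best <- best %||% best_any
  if (is.null(best)) {
    stop("fit_gaussians: no start converged; inspect the distribution", call. = FALSE)
  }

  full <- make_full(best$par)
  out <- list(A = full$A, p = full$p, r_S = full$r_S, sigma_S = full$sigma_S,
              r_Sstar = if (n_components == 2L) full$r_Sstar else NA_real_,
              sigma_Sstar = if (n_components == 2L) full$sigma_Sstar else NA_real_,
              n_components = n_components, rss = best$value,
              n_obs = length(r), constraint_set = frozen,
              converged = best$convergence == 0)
  ## relabel so S is the compact (smaller-mean) state
  if (n_components == 2L && !is.na(out$r_Sstar) && out$r_S > out$r_Sstar &&
      !any(c("r_S", "r_Sstar", "sigma_S", "sigma_Sstar", "p") %in% names(frozen))) {
    out[c("r_S", "r_Sstar")] <- out[c("r_Sstar", "r_S")]
    out[c("sigma_S", "sigma_Sstar")] <- out[c("sigma_Sstar", "sigma_S")]
    out$p <- 1 - out$p
  }
  out$p_at_bound <- n_components == 2L &&
    (out$p <= b$p[1] + 1e-9 || out$p >= b$p[2] - 1e-9)
  fit <- structure(out, class = "two_state_fit")
  ss_tot <- sum((y - mean(y))^2)
  fit$r_squared <- if (ss_tot > 0) 1 - best$value / ss_tot else NA_real_
  fit
}

#' Coefficient of determination of a two-state fit
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean density.
#'
#' @param fit a `two_state_fit`.
#' @param dist the [distance_distribution] the fit was produced on.
#' @return R-squared (at most 1; can be negative for a poor fit).  A
#'   constant density makes it undefined: `NA` with a warning.
#' @export
compute_r_squared <- function(fit, dist) {
  stopifnot(inherits(fit, "two_state_fit"),
            inherits(dist, "distance_distribution"))
  y <- dist$density
  yhat <- two_state_density(dist$r, unclass(fit), fit$n_components)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant density: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Choose between the one- and two-Gaussian models
#'
#' The two-component model is chosen only when it earns its three extra
#' parameters: the residual sum of squares must drop by more than an F-ratio
#' threshold (default the 0.99 quantile of F(3, n - 6)) and the minor
#' population must exceed `p_min` (default 0.03).  A one-component fit that
#' already explains the density to near machine precision short-circuits to
#' one component.
#'
#' @param fit1 one-component `two_state_fit`.
#' @param fit2 two-component `two_state_fit` on the same distribution.
#' @param criterion list with `f_level` (tail probability, default 0.01),
#'   `p_min` (minor-population floor, default 0.03), or `f_critical`
#'   (explicit F threshold overriding `f_level`).
#' @return the chosen fit, with attribute `selection` (list: F statistic,
#'   threshold, minor population).
#' @export
select_model <- function(fit1, fit2, criterion = list()) {
  stopifnot(inherits(fit1, "two_state_fit"), inherits(fit2, "two_state_fit"),
            fit1$n_components == 1L, fit2$n_components == 2L,
            fit1$n_obs == fit2$n_obs)
  crit <- utils::modifyList(list(f_level = 0.01, p_min = 0.03,
                                 f_critical = NULL), criterion)
  n <- fit1$n_obs
  df2 <- n - 6L
  f_crit <- crit$f_critical %||% stats::qf(1 - crit$f_level, 3, df2)
  minor <- min(fit2$p, 1 - fit2$p)

  ## one component already essentially exact?
  near_exact <- fit1$r_squared > 1 - 1e-8
  fstat <- if (fit2$rss <= 0) Inf else ((fit1$rss - fit2$rss) / 3) / (fit2$rss / df2)
  choose2 <- !near_exact && is.finite(fstat) && fstat > f_crit && minor > crit$p_min
  if (fit2$rss <= 0 && !near_exact && minor > crit$p_min) choose2 <- TRUE
  chosen <- if (choose2) fit2 else fit1
  attr(chosen, "selection") <- list(f_statistic = fstat, f_critical = f_crit,
                                    minor_population = minor,
                                    chose_two = choose2)
  chosen
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (x$n_components == 1L) {
    cat(sprintf("Single-state fit: r = %.3f nm, sigma = %.3f nm (R^2 = %.4f)\n",
                x$r_S, x$sigma_S, x$r_squared))
  } else {
    cat(sprintf("Two-state fit (R^2 = %.4f):\n", x$r_squared))
    cat(sprintf("  S : r = %.3f nm, sigma = %.3f nm, p = %.3f\n",
                x$r_S, x$sigma_S, x$p))
    cat(sprintf("  S*: r = %.3f nm, sigma = %.3f nm, p = %.3f\n",
                x$r_Sstar, x$sigma_Sstar, 1 - x$p))
  }
  if (length(x$constraint_set)) {
    cat("  frozen:", paste(names(x$constraint_set), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.two_state_fit <- function(object, ...) {
  c(r_S = object$r_S, sigma_S = object$sigma_S,
    r_Sstar = object$r_Sstar, sigma_Sstar = object$sigma_Sstar,
    p = object$p, A = object$A)
}

#' Evaluate the fitted two-state density
#' @param object a `two_state_fit`.
#' @param r distances (nm) at which to evaluate.
#' @param ... unused.
#' @return fitted density values.
#' @export
predict.two_state_fit <- function(object, r, ...) {
  two_state_density(r, unclass(object), object$n_components)
}
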