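#' Ordered series of per-timepoint distributions and fits
#'
#' Assembles distributions and their two-state fits along an aggregation
#' time course.  Time labels are categorical (`before`, `right_after`,
#' `10min`, `1h`, `12h`, or minute values) and must be unique; all
#' distributions must share one distance grid.
#'
#' @param labels character vector of timepoint labels, in time order.
#' @param distributions list of [distance_distribution], one per label.
#' @param fits list of `two_state_fit`, one per label (may be NULL entries
#'   before fitting).
#' @param sample sample name.
#' @return object of class `timepoint_series`.
#' @export
timepoint_series <- function(labels, distributions, fits = NULL,
                             sample = "sample") {
  stopifnot(length(labels) == length(distributions))
  if (anyDuplicated(labels)) stop("time labels must be unique", call. = FALSE)
  r0 <- distributions[[1L]]$r
  same <- vapply(distributions, function(d) {
    isTRUE(all.equal(d$r, r0, tolerance = 1e-12))
  }, logical(1))
  if (!all(same)) stop("all distributions must share the distance grid", call. = FALSE)
  fits <- fits %||% vector("list", length(labels))
  stopifnot(length(fits) == length(labels))
  structure(list(sample = sample, labels = labels,
                 distributions = distributions, fits = fits),
            class = "timepoint_series")
}

#' @export
print.timepoint_series <- function(x, ...) {
  cat(sprintf("Timepoint series '%s': %s\n", x$sample,
              paste(x$labels, collapse = " -> ")))
  invisible(x)
}

#' Fit every timepoint of a series independently
#'
#' @param series a [timepoint_series].
#' @param n_components 1, 2, or `"auto"` (per-timepoint [select_model()]).
#' @param seed integer seed for the multi-start fitting.
#' @param ... passed to [fit_gaussians()].
#' @return the series with `fits` filled in.
#' @export
fit_series <- function(series, n_components = "auto", seed = 1L, ...) {
  stopifnot(inherits(series, "timepoint_series"))
  series$fits <- lapply(seq_along(series$labels), function(i) {
    d <- series$distributions[[i]]
    if (identical(n_components, "auto")) {
      f1 <- fit_gaussians(d, 1L, seed = seed + i, ...)
      f2 <- fit_gaussians(d, 2L, seed = seed + i, ...)
      select_model(f1, f2)
    } else {
      fit_gaussians(d, as.integer(n_components), seed = seed + i, ...)
    }
  })
  series
}
#' Global two-state fit with shared components across timepoints
#'
#' Jointly fits the series by stacked least squares over all distributions,
#' with per-timepoint populations p_i and scales A_i, and component shapes
#' shared across timepoints according to `share`:
#' \describe{
#'   \item{`"none"`}{independent fits, returned unchanged.}
#'   \item{`"share_S"`}{the compact-state pair (r_S, sigma_S) is shared,
#'     reflecting the observation that the residual compact population
#'     retains the pre-aggregation distance distribution; the extended
#'     state is free per timepoint.}
#'   \item{`"share_both"`}{both state pairs are shared; only p_i and A_i
#'     vary.}
#'   \item{`"transition"`}{the S-to-S* transition model: (r_S, sigma_S) and
#'     the extended-state width sigma_S* are shared, while the extended-state
#'     mean evolves per timepoint as r_S*,i = r_S*,base + delta_i with
#'     |delta_i| <= 0.3 nm.  This is the default analysis for aggregation
#'     time courses: the compact state is the stable solution ensemble
#'     throughout, and the extended state is the beta-strand-commensurate
#'     conformation whose mean can creep modestly as aggregation matures but
#'     cannot wander, which keeps the population and the extended-state mean
#'     from trading against each other in heavily overlapping mixtures.}
#' }
#'
#' When the series' distributions come from regularized inversions, the
#' per-timepoint resolution operators (see [l_curve_select()]) can be
#' supplied so every model is compared to its reconstruction through the
#' same smoothing; shared parameters are then estimated on a common,
#' unsmoothed scale.
#'
#' @param series a [timepoint_series].
#' @param share `"none"`, `"share_S"`, `"share_both"` or `"transition"`.
#' @param resolutions optional list of resolution matrices, one per
#'   timepoint (NULL entries allowed).
#' @param seed integer seed.
#' @return the series with refreshed fits; attribute `global_rss` holds the
#'   total residual sum of squares of the joint fit.
#' @export
global_two_state_fit <- function(series,
                                 share = c("none", "share_S", "share_both",
                                           "transition"),
                                 resolutions = NULL, seed = 1L) {
  stopifnot(inherits(series, "timepoint_series"))
  share <- match.arg(share)
  if (share == "none") return(series)
  nt <- length(series$labels)
  if (nt < 2L) stop("shared fitting needs at least 2 timepoints", call. = FALSE)
  b <- default_fit_bounds()
  r <- series$distributions[[1L]]$r
  ys <- lapply(series$distributions, `[[`, "density")
  if (is.null(resolutions)) resolutions <- vector("list", nt)
  stopifnot(length(resolutions) == nt)

  ## Initialization: the aggregation course runs compact -> extended, so the
  ## first timepoint anchors the S component and the last anchors S*; both
  ## are taken from single-Gaussian fits of those endpoint distributions.
  ## Per-timepoint populations are then initialized by non-negative linear
  ## unmixing of each density onto the two anchor Gaussians.
  f_first <- fit_gaussians(series$distributions[[1L]], 1L, seed = seed,
                           resolution = resolutions[[1L]])
  f_last <- fit_gaussians(series$distributions[[nt]], 1L, seed = seed,
                          resolution = resolutions[[nt]])
  rS0 <- min(f_first$r_S, f_last$r_S)
  rX0 <- max(f_first$r_S, f_last$r_S)
  sS0 <- if (f_first$r_S <= f_last$r_S) f_first$sigma_S else f_last$sigma_S
  sX0 <- if (f_first$r_S <= f_last$r_S) f_last$sigma_S else f_first$sigma_S
  if (rX0 - rS0 < 0.2) rX0 <- min(rS0 + 0.5, b$r[2])
  basis <- cbind(stats::dnorm(r, rS0, sS0), stats::dnorm(r, rX0, sX0))
  p0 <- vapply(ys, function(y) {
    w <- tryCatch(drop(solve(crossprod(basis), crossprod(basis, y))),
                  error = function(e) c(0.5, 0.5))
    w <- pmax(w, 0)
    if (sum(w) <= 0) 0.5 else w[1L] / sum(w)
  }, numeric(1))
  p0 <- pmin(pmax(p0, 1e-3), 1 - 1e-3)

  ## parameter layout: shared block, then per-timepoint block; in
  ## transition mode the shared r_Sstar is a base value and each timepoint
  ## carries a bounded offset delta
  delta_max <- 0.3
  shared_names <- switch(share,
    share_S = c("r_S", "sigma_S"),
    share_both = c("r_S", "sigma_S", "r_Sstar", "sigma_Sstar"),
    transition = c("r_S", "sigma_S", "r_Sstar", "sigma_Sstar"))
  per_t_names <- switch(share,
    share_S = c("r_Sstar", "sigma_Sstar", "p", "A"),
    share_both = c("p", "A"),
    transition = c("delta", "p", "A"))
  shared0 <- c(r_S = rS0, sigma_S = sS0, r_Sstar = rX0,
               sigma_Sstar = sX0)[shared_names]
  box <- function(nms) {
    lo <- c(r_S = b$r[1], sigma_S = b$sigma[1], r_Sstar = b$r[1],
            sigma_Sstar = b$sigma[1], delta = -delta_max, p = 0,
            A = b$A[1])[nms]
    hi <- c(r_S = b$r[2], sigma_S = b$sigma[2], r_Sstar = b$r[2],
            sigma_Sstar = b$sigma[2], delta = delta_max, p = 1,
            A = b$A[2])[nms]
    list(lo = lo, hi = hi)
  }
  bs <- box(shared_names)
  bt <- box(per_t_names)
  per_t0 <- function(i) {
    c(r_Sstar = rX0, sigma_Sstar = sX0, delta = 0, p = p0[i],
      A = 1)[per_t_names]
  }
  theta0 <- c(shared0, unlist(lapply(seq_len(nt), per_t0)))
  lower <- c(bs$lo, rep(bt$lo, nt))
  upper <- c(bs$hi, rep(bt$hi, nt))
  n_sh <- length(shared_names)
  n_pt <- length(per_t_names)

  unpack <- function(theta, i) {
    par <- as.list(stats::setNames(theta[seq_len(n_sh)], shared_names))
    pt <- stats::setNames(theta[n_sh + (i - 1L) * n_pt + seq_len(n_pt)],
                          per_t_names)
    par[setdiff(per_t_names, "delta")] <- as.list(pt[setdiff(per_t_names, "delta")])
    if ("delta" %in% per_t_names) {
      par$r_Sstar <- min(max(par$r_Sstar + pt[["delta"]], b$r[1]), b$r[2])
    }
    par
  }
  objective <- function(theta) {
    tot <- 0
    for (i in seq_len(nt)) {
      m <- two_state_density(r, unpack(theta, i), 2L)
      if (!is.null(resolutions[[i]])) m <- drop(resolutions[[i]] %*% m)
      tot <- tot + sum((ys[[i]] - m)^2)
    }
    tot
  }
  opt <- stats::optim(theta0, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 2000L, factr = 1e4))

  for (i in seq_len(nt)) {
    par <- unpack(opt$par, i)
    if (par$r_S > par$r_Sstar) {  # keep S the compact state
      par[c("r_S", "r_Sstar")] <- par[c("r_Sstar", "r_S")]
      par[c("sigma_S", "sigma_Sstar")] <- par[c("sigma_Sstar", "sigma_S")]
      par$p <- 1 - par$p
    }
    m <- two_state_density(r, par, 2L)
    if (!is.null(resolutions[[i]])) m <- drop(resolutions[[i]] %*% m)
    rss_i <- sum((ys[[i]] - m)^2)
    ss_tot <- sum((ys[[i]] - mean(ys[[i]]))^2)
    f <- structure(list(A = par$A, p = par$p, r_S = par$r_S,
                        sigma_S = par$sigma_S, r_Sstar = par$r_Sstar,
                        sigma_Sstar = par$sigma_Sstar, n_components = 2L,
                        rss = rss_i, n_obs = length(r),
                        constraint_set = list(shared = shared_names),
                        converged = opt$convergence == 0,
                        p_at_bound = par$p <= 1e-9 || par$p >= 1 - 1e-9,
                        r_squared = if (ss_tot > 0) 1 - rss_i / ss_tot
                                    else NA_real_),
                   class = "two_state_fit")
    series$fits[[i]] <- f
  }
  attr(series, "global_rss") <- opt$value
  series
}

#' Population table of a fitted series
#'
#' Emits one row per (timepoint, state) with the fitted mean, width and
#' population, in the layout of a published population-analysis table:
#' states not populated at a timepoint get NA mean/width and population 0;
#' a state entirely absent from the model at a timepoint (one-component
#' fit) is reported with population 0 and missing parameters rather than a
#' zero-width Gaussian.
#'
#' @param series a fitted [timepoint_series].
#' @return data.frame with columns `sample`, `timepoint`, `state`, `r`,
#'   `sigma`, `p`, `r_squared`.
#' @export
population_table <- function(series) {
  stopifnot(inherits(series, "timepoint_series"))
  if (any(vapply(series$fits, is.null, logical(1)))) {
    stop("series has unfitted timepoints; run fit_series() first", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(series$labels)) {
    f <- series$fits[[i]]
    lab <- series$labels[i]
    if (f$n_components == 1L) {
      ## single state: decide which label it carries by its mean relative to
      ## the series-wide span of fitted means
      means <- unlist(lapply(series$fits, function(g) c(g$r_S, g$r_Sstar)))
      mid <- mean(range(means, na.rm = TRUE))
      is_S <- f$r_S <= mid
      rows[[length(rows) + 1L]] <- data.frame(
        sample = series$sample, timepoint = lab, state = "S",
        r = if (is_S) f$r_S else NA_real_,
        sigma = if (is_S) f$sigma_S else NA_real_,
        p = if (is_S) 1 else 0, r_squared = f$r_squared,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = series$sample, timepoint = lab, state = "Sstar",
        r = if (is_S) NA_real_ else f$r_S,
        sigma = if (is_S) NA_real_ else f$sigma_S,
        p = if (is_S) 0 else 1, r_squared = f$r_squared,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = series$sample, timepoint = lab, state = "S",
        r = f$r_S, sigma = f$sigma_S, p = f$p, r_squared = f$r_squared,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = series$sample, timepoint = lab, state = "Sstar",
        r = f$r_Sstar, sigma = f$sigma_Sstar, p = 1 - f$p,
        r_squared = f$r_squared, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Parse a population table back into series metadata
#'
#' Inverse of [population_table()] at the metadata level: recovers the
#' sample name, ordered timepoint labels and per-timepoint state parameters.
#'
#' @param tb a data.frame as produced by [population_table()].
#' @return list with `sample`, `labels`, and `states` (per-timepoint list of
#'   parameter rows).
#' @export
parse_population_table <- function(tb) {
  stopifnot(all(c("sample", "timepoint", "state", "r", "sigma", "p") %in% names(tb)))
  labels <- unique(tb$timepoint)
  states <- lapply(labels, function(l) {
    tb[tb$timepoint == l, c("state", "r", "sigma", "p"), drop = FALSE]
  })
  names(states) <- labels
  list(sample = unique(tb$sample)[1L], labels = labels, states = states)
}
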