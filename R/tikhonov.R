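## Fast non-negative least squares (active-set method of Bro & de Jong,
## operating on the normal equations A'A x = A'b), with optional warm start
## from a previous passive set.  Authored here because the Tikhonov stage
## solves many closely related systems along the alpha grid and profits from
## warm starts; an independent stacked-system NNLS serves as its oracle in
## the test suite.
fnnls <- function(AtA, Atb, passive = NULL, max_iter = NULL) {
  n <- length(Atb)
  stopifnot(nrow(AtA) == n, ncol(AtA) == n)
  if (is.null(max_iter)) max_iter <- 30L * n
  tol <- 1e-12 * max(abs(Atb), 1e-300)
  x <- numeric(n)
  P <- rep(FALSE, n)

  solve_passive <- function(P) {
    s <- numeric(n)
    if (any(P)) {
      s[P] <- tryCatch(
        solve(AtA[P, P, drop = FALSE], Atb[P]),
        error = function(e) {
          ## near-singular passive block: ridge-stabilized fallback
          m <- AtA[P, P, drop = FALSE]
          solve(m + diag(1e-12 * max(diag(m)), sum(P)), Atb[P])
        })
    }
    s
  }

  repair <- function(x, P) {
    ## inner loop: restore feasibility of the passive-set solution
    it <- 0L
    repeat {
      s <- solve_passive(P)
      if (all(s[P] > 0) || !any(P)) return(list(x = s, P = P))
      it <- it + 1L
      if (it > max_iter) return(list(x = pmax(x, 0), P = P))
      sel <- P & s <= 0
      alpha <- min(x[sel] / (x[sel] - s[sel]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
  }

  if (!is.null(passive) && any(passive)) {
    P <- passive
    st <- repair(x, P)
    x <- st$x; P <- st$P
  }

  iter <- 0L
  repeat {
    w <- Atb - drop(AtA %*% x)
    w[P] <- -Inf
    j <- which.max(w)
    if (!any(!P) || w[j] <= tol || iter > max_iter) break
    iter <- iter + 1L
    P[j] <- TRUE
    st <- repair(x, P)
    x <- st$x; P <- st$P
  }
  list(x = x, passive = P)
}

## Second-difference smoothness operator with reflective (mirror) ends.
second_difference_operator <- function(n) {
  stopifnot(n >= 3L)
  L <- matrix(0, n, n)
  for (i in 2:(n - 1L)) L[i, (i - 1L):(i + 1L)] <- c(1, -2, 1)
  L[1L, 1:2] <- c(-1, 1)
  L[n, (n - 1L):n] <- c(1, -1)
  L
}

#' Tikhonov inversion of a dipolar signal at fixed alpha
#'
#' Solves the smoothness-regularized non-negative least-squares problem
#' \deqn{P = \arg\min_{P \ge 0} \|K P - S\|^2 + \alpha^2 \|L P\|^2,}
#' where L is the second-difference operator with reflective ends, as a
#' non-negative least-squares problem on the stacked system \eqn{[K; \alpha
#' L]}.  Non-negativity is enforced by the active-set solver, not by
#' clipping.  The returned distribution is renormalized to unit area; the
#' raw area (the scale absorbed by normalization) is attached as attribute
#' `raw_area`.
#'
#' @param signal a background-corrected [deer_trace] on the kernel's time
#'   grid (S(0) = 1).
#' @param kernel a `deer_kernel`.
#' @param alpha regularization parameter (>= 0), on the scale of the signal
#'   (absolute, not relative to the kernel norm).
#' @return a [distance_distribution]; attributes `raw_area`,
#'   `residual_norm` (\eqn{\|KP - S\|}) and `penalty_norm`
#'   (\eqn{\|L P\|}, computed on the raw solution).
#' @export
tikhonov_solve <- function(signal, kernel, alpha) {
  stopifnot(inherits(signal, "deer_trace"), inherits(kernel, "deer_kernel"))
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (!isTRUE(all.equal(signal$t, kernel$t, tolerance = 1e-12))) {
    stop("signal time grid does not match kernel time grid", call. = FALSE)
  }
  A <- kernel_design(kernel)
  L <- second_difference_operator(length(kernel$r))
  AtA <- crossprod(A) + alpha^2 * crossprod(L)
  Atb <- drop(crossprod(A, signal$signal))
  sol <- fnnls(AtA, Atb)
  p_raw <- sol$x
  area <- trapz(kernel$r, p_raw)
  if (area <= 0) {
    dist <- distance_distribution(kernel$r, rep(0, length(kernel$r)),
                                  normalize = FALSE)
    attr(dist, "empty") <- TRUE
  } else {
    dist <- distance_distribution(kernel$r, p_raw / area)
    attr(dist, "empty") <- FALSE
  }
  attr(dist, "raw_area") <- area
  attr(dist, "residual_norm") <- sqrt(sum((drop(A %*% p_raw) - signal$signal)^2))
  attr(dist, "penalty_norm") <- sqrt(sum(drop(L %*% p_raw)^2))
  dist
}

#' L-curve selection of the Tikhonov regularization parameter
#'
#' Scans a log-spaced alpha grid, records the parametric curve of log
#' residual norm versus log penalty norm, and selects the alpha at the point
#' of maximum curvature (the L-curve corner) by central finite differences in
#' log-log space.  Ties are broken toward larger alpha (the smoother
#' solution).  If no interior curvature maximum exists the median alpha of
#' the grid is returned with `fallback = TRUE` and a warning.
#'
#' @param signal a background-corrected [deer_trace].
#' @param kernel a `deer_kernel`.
#' @param alpha_grid increasing vector of >= 10 alphas spanning >= 4 decades;
#'   default 40 points from `1e-4` to `1e4` times the kernel spectral norm.
#' @return object of class `deer_inversion`: list with `distribution`,
#'   `alpha`, `residual_norm`, `penalty_norm`, `lcurve` (data.frame with
#'   columns alpha, residual_norm, penalty_norm, curvature), `fallback`.
#' @export
l_curve_select <- function(signal, kernel, alpha_grid = NULL) {
  stopifnot(inherits(signal, "deer_trace"), inherits(kernel, "deer_kernel"))
  A <- kernel_design(kernel)
  if (is.null(alpha_grid)) {
    nrmK <- norm(A, "2")
    alpha_grid <- nrmK * 10^seq(-4, 4, length.out = 40L)
  }
  alpha_grid <- sort(alpha_grid)
  if (length(alpha_grid) < 10L) stop("need >= 10 alphas", call. = FALSE)
  if (log10(max(alpha_grid) / min(alpha_grid)) < 4) {
    stop("alpha grid must span at least 4 decades", call. = FALSE)
  }
  L <- second_difference_operator(length(kernel$r))
  AtA0 <- crossprod(A)
  LtL <- crossprod(L)
  Atb <- drop(crossprod(A, signal$signal))

  n_a <- length(alpha_grid)
  res <- pen <- numeric(n_a)
  sols <- vector("list", n_a)
  passive <- NULL
  ## scan from large alpha (few active pixels) downward, warm-starting
  for (i in rev(seq_len(n_a))) {
    a <- alpha_grid[i]
    sol <- fnnls(AtA0 + a^2 * LtL, Atb, passive = passive)
    passive <- sol$passive
    p <- sol$x
    sols[[i]] <- p
    res[i] <- sqrt(sum((drop(A %*% p) - signal$signal)^2))
    pen[i] <- sqrt(sum(drop(L %*% p)^2))
  }

  lr <- log(pmax(res, 1e-300))
  lp <- log(pmax(pen, 1e-300))
  la <- log(alpha_grid)
  kappa <- rep(NA_real_, n_a)
  ii <- 2:(n_a - 1L)
  d1x <- (lr[ii + 1L] - lr[ii - 1L]) / (la[ii + 1L] - la[ii - 1L])
  d1y <- (lp[ii + 1L] - lp[ii - 1L]) / (la[ii + 1L] - la[ii - 1L])
  h <- diff(la)[1L]
  d2x <- (lr[ii + 1L] - 2 * lr[ii] + lr[ii - 1L]) / h^2
  d2y <- (lp[ii + 1L] - 2 * lp[ii] + lp[ii - 1L]) / h^2
  kappa[ii] <- (d1x * d2y - d1y * d2x) / (d1x^2 + d1y^2)^1.5

  fallback <- FALSE
  finite <- which(is.finite(kappa))
  if (length(finite) == 0L || max(kappa[finite]) <= 0) {
    warning("degenerate L-curve: no curvature maximum; falling back to median alpha")
    i_sel <- ceiling(n_a / 2)
    fallback <- TRUE
  } else {
    kmax <- max(kappa[finite])
    ## Local curvature maxima with at least 20% of the global prominence.
    ## Non-negative Tikhonov L-curves often grow a second, spurious bend at
    ## strong over-smoothing (the solution collapsing toward the zero-penalty
    ## limit); the physically meaningful corner is the first prominent one
    ## coming from the under-smoothed side, so that is the one selected.
    is_locmax <- vapply(finite, function(i) {
      kl <- if ((i - 1L) %in% finite) kappa[i - 1L] else -Inf
      kr <- if ((i + 1L) %in% finite) kappa[i + 1L] else -Inf
      kappa[i] >= kl && kappa[i] >= kr
    }, logical(1))
    cand <- finite[is_locmax & kappa[finite] >= 0.2 * kmax]
    if (length(cand) == 0L) cand <- finite[kappa[finite] >= kmax * (1 - 1e-12)]
    i_first <- min(cand)
    ## ties (equal curvature within rounding) broken toward larger alpha:
    ## extend over a contiguous plateau of numerically equal curvature
    i_sel <- i_first
    while ((i_sel + 1L) %in% finite &&
           abs(kappa[i_sel + 1L] - kappa[i_first]) <= 1e-12 * abs(kappa[i_first])) {
      i_sel <- i_sel + 1L
    }
  }
  a_sel <- alpha_grid[i_sel]
  p <- sols[[i_sel]]
  area <- trapz(kernel$r, p)
  dist <- if (area > 0) {
    distance_distribution(kernel$r, p / area)
  } else {
    distance_distribution(kernel$r, rep(0, length(kernel$r)), normalize = FALSE)
  }
  attr(dist, "raw_area") <- area
  ## resolution operator of the (unconstrained) Tikhonov inversion at the
  ## selected alpha: the reconstruction is approximately this linear
  ## smoothing of the true distribution, so downstream model fitting can
  ## account for it (see fit_gaussians(resolution = ))
  Rop <- solve(AtA0 + a_sel^2 * LtL, AtA0)
  structure(list(distribution = dist, alpha = a_sel,
                 resolution = Rop,
                 residual_norm = res[i_sel], penalty_norm = pen[i_sel],
                 lcurve = data.frame(alpha = alpha_grid, residual_norm = res,
                                     penalty_norm = pen, curvature = kappa),
                 fallback = fallback),
            class = "deer_inversion")
}

#' @export
print.deer_inversion <- function(x, ...) {
  cat(sprintf("Tikhonov L-curve inversion: alpha = %.4g (%s), residual = %.4g\n",
              x$alpha, if (x$fallback) "fallback" else "corner", x$residual_norm))
  invisible(x)
}
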