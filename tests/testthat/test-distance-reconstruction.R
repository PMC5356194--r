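test_that("noiseless Tikhonov inversion localizes a single Gaussian", {
  K <- small_kernel(128L, 128L)
  d <- preset_distribution("dtau187_G272C_S285C", "1h", K$r)
  sig <- dipolar_signal(d, K)
  A <- K$values %*% diag(trapz_weights_oracle(K$r))
  alpha <- 1e-3 * norm(A, "2")
  sol <- tikhonov_solve(sig, K, alpha)
  peak_true <- K$r[which.max(d$density)]
  peak_rec <- K$r[which.max(sol$density)]
  expect_lt(abs(peak_rec - peak_true), 0.05 + (K$r[2] - K$r[1]))
})

test_that("residual norm grows with the regularization strength", {
  K <- small_kernel()
  d <- preset_distribution("dtau187_G272C_S285C", "right_after", K$r)
  sig <- dipolar_signal(d, K)
  a0 <- 0.5
  r1 <- attr(tikhonov_solve(sig, K, a0), "residual_norm")
  r2 <- attr(tikhonov_solve(sig, K, 10 * a0), "residual_norm")
  expect_gte(r2, r1)
})

test_that("a zero signal inverts to an empty, flagged distribution", {
  K <- small_kernel(32L, 32L)
  sig <- deer_trace(K$t, rep(0, length(K$t)))
  sol <- tikhonov_solve(sig, K, 1)
  expect_true(attr(sol, "empty"))
  expect_true(all(sol$density == 0))
  expect_error(tikhonov_solve(sig, K, -1), "alpha")
})

test_that("the in-house NNLS solve matches a brute-force constrained QP", {
  ## 24-point coarse grid; oracle: Lawson-Hanson NNLS on the explicitly
  ## stacked system [K; alpha L], an independent route to the same QP
  K <- small_kernel(24L, 24L, t_max = 2.5, r_range = c(2, 6))
  d <- mixture_to_distribution(list(gaussian_component(3.2, 0.4, 0.5),
                                    gaussian_component(4.6, 0.5, 0.5)), K$r)
  sig <- dipolar_signal(d, K)
  n <- length(K$r)
  A <- K$values %*% diag(trapz_weights_oracle(K$r))
  L <- matrix(0, n, n)
  for (i in 2:(n - 1)) L[i, (i - 1):(i + 1)] <- c(1, -2, 1)
  L[1, 1:2] <- c(-1, 1); L[n, (n - 1):n] <- c(1, -1)
  for (alpha in c(1e-3, 0.1, 2)) {
    stacked <- rbind(A, alpha * L)
    rhs <- c(sig$signal, rep(0, n))
    oracle <- pracma::lsqnonneg(stacked, rhs)$x
    mine <- tikhonov_solve(sig, K, alpha)
    raw <- mine$density * attr(mine, "raw_area")
    expect_lt(max(abs(raw - oracle)), 1e-6)
  }
})

test_that("L-curve scan is monotone and lands near the best alpha", {
  sim <- simulate_deer(list(gaussian_component(3.16, 0.98, 1)),
                       n_t = 96, n_r = 96, snr = 50, seed = 31)
  ff <- remove_background(sim$trace, list(model = background_model(0.05, 3),
                                          lambda = 0.3))
  inv <- l_curve_select(ff, sim$kernel)
  lc <- inv$lcurve
  expect_true(all(diff(lc$residual_norm) >= -1e-8 * lc$residual_norm[-1]))
  expect_true(all(diff(lc$penalty_norm) <= 1e-8 * lc$penalty_norm[-nrow(lc)]))
  expect_false(inv$fallback)

  ## ground-truth-error oracle over the same grid: the corner must sit
  ## within one decade of the error-minimizing alpha
  errs <- vapply(lc$alpha, function(a) {
    l1_distance(tikhonov_solve(ff, sim$kernel, a), sim$truth)
  }, numeric(1))
  best <- lc$alpha[which.min(errs)]
  expect_lt(abs(log10(inv$alpha / best)), 1)
})

test_that("stronger noise never calls for less regularization", {
  cnt <- 0L
  for (s in 1:10) {
    sims <- lapply(c(100, 50), function(snr) {
      simulate_deer(list(gaussian_component(3.16, 0.98, 1)),
                    n_t = 96, n_r = 96, snr = snr, seed = 900 + s)
    })
    alphas <- vapply(sims, function(sm) {
      ff <- remove_background(sm$trace,
                              list(model = background_model(0.05, 3),
                                   lambda = 0.3))
      l_curve_select(ff, sm$kernel)$alpha
    }, numeric(1))
    if (alphas[2] >= alphas[1]) cnt <- cnt + 1L
  }
  expect_gte(cnt, 8L)
})

test_that("alpha grids must span enough decades", {
  K <- small_kernel(32L, 32L)
  sig <- deer_trace(K$t, apply_kernel(K, mixture_to_distribution(
    list(gaussian_component(3.5, 0.8, 1)), K$r)))
  expect_error(l_curve_select(sig, K, alpha_grid = 10^seq(-1, 1, length.out = 12)),
               "4 decades")
  expect_error(l_curve_select(sig, K, alpha_grid = c(1e-4, 1e4)), ">= 10")
})

test_that("maximum entropy leaves an exact solution essentially unchanged", {
  K <- small_kernel(96L, 96L)
  d <- preset_distribution("dtau187_G272C_S285C", "right_after", K$r)
  sig <- dipolar_signal(d, K, noise_sigma = 0)
  out <- maxent_refine(sig, K, d, alpha = 1)
  expect_lt(l1_distance(out, d), 1e-4)
  ## entropy barrier: strictly positive everywhere
  expect_true(all(out$density > 0))
})

test_that("maxent refinement helps at low signal-to-noise", {
  better <- 0L
  comps <- preset_components("dtau187_G272C_S285C", "right_after")
  for (s in 1:10) {
    sim <- simulate_deer(comps, snr = 30, seed = 4200 + s * 7)
    ff <- remove_background(sim$trace, fit_background(sim$trace, 0.6, 3))
    inv <- l_curve_select(ff, sim$kernel)
    refined <- deerpop:::maxent_auto(ff, sim$kernel, inv$distribution)
    if (l1_distance(refined, sim$truth) <=
          l1_distance(inv$distribution, sim$truth)) better <- better + 1L
  }
  expect_gte(better, 7L)
})
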