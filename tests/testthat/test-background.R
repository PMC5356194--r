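test_that("a pure exponential decay is fitted exactly", {
  t <- time_grid(3.2, 128)
  tr <- deer_trace(t, exp(-0.05 * t))
  bf <- fit_background(tr, 0.6, dimension_fixed = 3)
  expect_lt(abs(bf$model$k - 0.05), 1e-6)
  expect_lt(abs(bf$lambda), 1e-6)
})

test_that("background rate is recovered from a realistic synthetic trace", {
  sim <- simulate_deer(preset_components("dtau187_G272C_S285C", "before"),
                       snr = 100, seed = 7)
  ## the package's background estimate (tail fit + joint refinement)
  f <- deer_fit(sim$trace, n_components = 1,
                fit_start_fraction = 0.6, seed = 7)
  expect_lt(abs(f$background$model$k / 0.05 - 1), 0.05)
  expect_lt(abs(f$background$lambda / 0.3 - 1), 0.05)
})

test_that("free dimensionality estimation is unbiased for a 3-D bath", {
  ## d enters only through the weak curvature of ln B(t), so any single
  ## noisy trace determines it loosely; the estimator must nevertheless be
  ## centred on 3 for a homogeneous 3-D spin bath
  ds <- vapply(1:10, function(s) {
    sim <- simulate_deer(list(gaussian_component(2.5, 0.4, 1)),
                         k = 0.3, snr = 100, seed = 3000 + s)
    fit_background(sim$trace, 0.6, dimension_fixed = NULL)$model$d
  }, numeric(1))
  expect_gt(mean(ds), 2.7)
  expect_lt(mean(ds), 3.3)
  expect_true(all(ds >= 1 & ds <= 6))
})

test_that("fitted rate is stable against the choice of fit window", {
  ## fixture whose dipolar signal has fully decayed before the window, so
  ## the window sees pure background; noiseless -> no window systematics,
  ## noisy -> spread bounded by the slope-estimate noise floor
  sim0 <- simulate_deer(list(gaussian_component(2.5, 0.4, 1)),
                        k = 0.3, snr = Inf, seed = 11)
  ks0 <- vapply(c(0.5, 0.6, 0.7, 0.8), function(fs) {
    fit_background(sim0$trace, fs, 3)$model$k
  }, numeric(1))
  expect_lt(diff(range(ks0)) / mean(ks0), 0.02)

  sim <- simulate_deer(list(gaussian_component(2.5, 0.4, 1)),
                       k = 0.3, snr = 100, seed = 11)
  ks <- vapply(c(0.5, 0.6, 0.7, 0.8), function(fs) {
    fit_background(sim$trace, fs, 3)$model$k
  }, numeric(1))
  expect_lt(diff(range(ks)) / mean(ks), 0.1)
})

test_that("background fitting rejects unusable inputs", {
  t <- time_grid(3.2, 64)
  expect_error(fit_background(deer_trace(t, exp(-0.05 * t)), 0.9),
               "window too short")
  bad <- deer_trace(t, c(rep(1, 40), rep(-0.1, 24)) - 0)
  expect_error(suppressWarnings(fit_background(bad, 0.6)), "non-positive")
  expect_error(fit_background(deer_trace(t, exp(-t)), 1.2),
               "fit_start_fraction")
})

test_that("noiseless background removal is an exact algebraic inverse", {
  K <- small_kernel(128L, 96L)
  d <- mixture_to_distribution(list(gaussian_component(3.16, 0.98, 1)), K$r)
  ff <- simulate_form_factor(d, K, 0.3)
  tr <- apply_background_and_noise(ff, background_model(0.05, 3), Inf, 1)
  s <- remove_background(tr, list(model = background_model(0.05, 3),
                                  lambda = 0.3))
  expect_equal(s$signal, apply_kernel(K, d), tolerance = 1e-9)
  expect_equal(s$signal[1], 1, tolerance = 1e-12)
})

test_that("removal with unit modulation depth is idempotent", {
  t <- time_grid(2, 64)
  tr <- deer_trace(t, 0.4 + 0.6 * exp(-2 * t))
  fit <- list(model = background_model(0, 3), lambda = 1)
  once <- remove_background(tr, fit)
  twice <- remove_background(once, fit)
  expect_equal(twice$signal, once$signal, tolerance = 1e-12)
})

test_that("an unusable modulation-depth estimate is refused with advice", {
  t <- time_grid(2, 64)
  tr <- deer_trace(t, exp(-0.05 * t))
  expect_error(remove_background(tr, list(model = background_model(0.05, 3),
                                          lambda = 1.2)),
               "manually")
})

test_that("joint refinement repairs the tail-window bias of extended states", {
  ## a pure extended state oscillates too slowly for the tail window: the
  ## plain tail fit overestimates lambda, the joint parametric refinement
  ## recovers the generating values
  sim <- simulate_deer(preset_components("dtau187_G272C_S285C", "1h"),
                       snr = Inf, seed = 1)
  tail_fit <- fit_background(sim$trace, 0.6, 3)
  expect_gt(tail_fit$lambda, 0.31)
  f <- deer_fit(sim$trace, n_components = 1, seed = 1)
  expect_lt(abs(f$background$lambda - 0.3), 0.005)
  expect_lt(abs(f$background$model$k - 0.05), 0.005)
})
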