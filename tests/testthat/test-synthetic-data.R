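test_that("Gaussian mixtures become unit-area densities on the grid", {
  g <- distance_grid()
  d <- preset_distribution("dtau187_G272C_S285C", "before")
  dr <- g[2] - g[1]
  expect_lt(abs(sum(trapz_weights_oracle(g) * d$density) - 1), 1e-6)
  ## unimodal, peaking at the component mean (within one grid step)
  expect_lt(abs(g[which.max(d$density)] - 3.16), dr)
  expect_true(all(d$density >= 0))
})

test_that("degenerate mixtures collapse correctly", {
  g <- distance_grid(2, 6, 128)
  one <- mixture_to_distribution(list(gaussian_component(3.2, 0.5, 1)), g)
  two <- mixture_to_distribution(list(gaussian_component(3.2, 0.5, 0.5),
                                      gaussian_component(3.2, 0.5, 0.5)), g)
  expect_equal(two$density, one$density, tolerance = 1e-12)
  ## p = 1: second component contributes nothing
  p1 <- mixture_to_distribution(list(gaussian_component(3.2, 0.5, 1),
                                     gaussian_component(5, 0.4, 0)), g)
  expect_equal(p1$density, one$density, tolerance = 1e-12)
})

test_that("mixture construction rejects invalid component sets", {
  g <- distance_grid(2, 6, 64)
  expect_error(mixture_to_distribution(list(), g), "at least one")
  expect_error(mixture_to_distribution(
    list(gaussian_component(3, 0.5, 0.6), gaussian_component(4, 0.5, 0.6)), g),
    "sum to 1")
  expect_error(mixture_to_distribution(
    rep(list(gaussian_component(3, 0.5, 1 / 3)), 3), g), "at most two")
})

test_that("component parameters are recoverable from the density", {
  ## well-separated mixture: moment extraction by refitting returns the
  ## generating parameters within grid resolution
  g <- distance_grid(1.5, 8, 256)
  d <- mixture_to_distribution(list(gaussian_component(2.6, 0.25, 0.35),
                                    gaussian_component(5.2, 0.4, 0.65)), g)
  f <- fit_gaussians(d, 2L, seed = 1)
  expect_lt(abs(f$r_S - 2.6), 0.03)
  expect_lt(abs(f$r_Sstar - 5.2), 0.03)
  expect_lt(abs(f$p - 0.35), 0.01)
})

test_that("peak normalization is a display transform only", {
  d <- preset_distribution("dtau187_G272C_S285C", "10min")
  pk <- peak_normalize(d)
  expect_equal(max(pk$density), 1)
  expect_equal(pk$density * max(d$density), d$density)
})

test_that("form factor simulation obeys the modulation-depth contract", {
  K <- small_kernel()
  d <- mixture_to_distribution(list(gaussian_component(3.16, 0.98, 1)), K$r)
  ## lambda = 0: no pumped spins, flat signal
  f0 <- simulate_form_factor(d, K, lambda = 0)
  expect_equal(f0$signal, rep(1, length(K$t)), tolerance = 1e-12)
  ## F(0) = 1 for any valid input
  for (lam in c(0.1, 0.3, 0.8)) {
    expect_lt(abs(simulate_form_factor(d, K, lam)$signal[1] - 1), 1e-10)
  }
  expect_error(simulate_form_factor(d, K, 1.2), "lambda")
  ## monotone in lambda at fixed t where K < 1: deeper modulation, deeper dip
  f1 <- simulate_form_factor(d, K, 0.2)$signal
  f2 <- simulate_form_factor(d, K, 0.4)$signal
  kp <- apply_kernel(K, d)
  expect_true(all(f2[kp < 1] <= f1[kp < 1] + 1e-12))
})

test_that("near-delta distributions approach the bare kernel trace", {
  K <- small_kernel(96L, 512L, r_range = c(2, 6))
  r0 <- 4.01
  dev <- vapply(c(0.12, 0.06, 0.03), function(s) {
    d <- mixture_to_distribution(list(gaussian_component(r0, s, 1)), K$r)
    f <- simulate_form_factor(d, K, 0.3)
    max(abs(f$signal - ((1 - 0.3) + 0.3 * kernel_element(K$t, r0))))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))   # deviation shrinks as sigma -> 0
  expect_lt(dev[3], 0.01)
})

test_that("background and noise application is controlled and reproducible", {
  K <- small_kernel()
  d <- mixture_to_distribution(list(gaussian_component(3.5, 0.9, 1)), K$r)
  ff <- simulate_form_factor(d, K, 0.3)

  ## identity background, no noise: output equals input
  same <- apply_background_and_noise(ff, background_model(0, 3), Inf, seed = 1)
  expect_equal(same$signal, ff$signal, tolerance = 1e-15)

  ## determinism: same seed gives bit-identical traces
  a <- apply_background_and_noise(ff, background_model(0.05, 3), 50, seed = 42)
  b <- apply_background_and_noise(ff, background_model(0.05, 3), 50, seed = 42)
  expect_identical(a$signal, b$signal)
  c2 <- apply_background_and_noise(ff, background_model(0.05, 3), 50, seed = 43)
  expect_false(identical(a$signal, c2$signal))

  ## realized noise sd within 10% of lambda/snr at 256 points
  K256 <- small_kernel(256L, 64L)
  d256 <- mixture_to_distribution(list(gaussian_component(3.5, 0.9, 1)), K256$r)
  ff256 <- simulate_form_factor(d256, K256, 0.3)
  bg <- background_model(0.05, 3)
  v <- apply_background_and_noise(ff256, bg, 50, seed = 11)
  eps <- v$signal - ff256$signal * background_decay(bg, K256$t)
  expect_lt(abs(sd(eps) / (0.3 / 50) - 1), 0.1)
  expect_equal(v$noise_sigma, 0.3 / 50)
})

test_that("simulate_deer is reproducible from seed and parameters alone", {
  comps <- preset_components("dtau187_G303C_S316C", "right_after")
  s1 <- simulate_deer(comps, n_t = 64, n_r = 64, seed = 7)
  s2 <- simulate_deer(comps, n_t = 64, n_r = 64, seed = 7)
  expect_identical(s1$trace$signal, s2$trace$signal)
  expect_identical(s1$truth$density, s2$truth$density)
  ## the global RNG stream is left untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_deer(comps, n_t = 64, n_r = 64, seed = 7))
  expect_identical(rnorm(3), before)
})

test_that("preset table carries the full set of published parameter rows", {
  tb <- two_state_presets()
  expect_equal(nrow(tb), 24L)
  expect_setequal(unique(tb$sample),
                  c("dtau187_G272C_S285C", "dtau187_G303C_S316C",
                    "r2_12_G273C_L284C", "r2_14_G272C_S285C"))
  ## weights sum to one at every sample/timepoint
  agg <- aggregate(p ~ sample + timepoint, tb, sum)
  expect_true(all(abs(agg$p - 1) < 1e-12))
  expect_error(preset_components("r2_12_G273C_L284C", "10min"), "no preset")
})
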