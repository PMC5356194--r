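test_that("an exact single Gaussian is recovered to numerical precision", {
  g <- distance_grid(1.5, 8, 256)
  d <- mixture_to_distribution(list(gaussian_component(3.38, 0.8, 1)), g)
  f <- fit_gaussians(d, 1L, seed = 1)
  expect_gte(f$r_squared, 0.9999)
  expect_lt(abs(f$r_S - 3.38), 1e-5)
  expect_lt(abs(f$sigma_S - 0.8), 1e-5)
})

test_that("published mixture rows sampled exactly are recovered tightly", {
  ## grid-sampled two-Gaussian density: parameters must come back within
  ## 0.03 nm (means) and 0.02 (population)
  g <- distance_grid(1.5, 8, 256)
  d <- preset_distribution("dtau187_G272C_S285C", "10min", g)
  f <- fit_gaussians(d, 2L, seed = 3)
  expect_lt(abs(f$r_S - 3.16), 0.03)
  expect_lt(abs(f$r_Sstar - 4.1), 0.03)
  expect_lt(abs(f$p - 0.09), 0.02)
  ## label stability: S is the compact component
  expect_lt(f$r_S, f$r_Sstar)
})

test_that("degenerate mixtures reduce to the surviving component", {
  g <- distance_grid(1.5, 8, 256)
  dr <- g[2] - g[1]
  d <- mixture_to_distribution(list(gaussian_component(3.16, 0.98, 1),
                                    gaussian_component(4.1, 1.1, 0)), g)
  f1 <- fit_gaussians(d, 1L, seed = 2)
  f2 <- fit_gaussians(d, 2L, seed = 2)
  surviving <- if (f2$p >= 0.5) f2$r_S else f2$r_Sstar
  expect_lt(abs(surviving - f1$r_S), dr)
})

test_that("frozen parameters are held exactly", {
  g <- distance_grid(1.5, 8, 192)
  d <- preset_distribution("dtau187_G272C_S285C", "right_after", g)
  f <- fit_gaussians(d, 2L, frozen = list(r_S = 3.16, sigma_S = 0.98),
                     seed = 4)
  expect_identical(f$r_S, 3.16)
  expect_identical(f$sigma_S, 0.98)
  expect_identical(f$constraint_set, list(r_S = 3.16, sigma_S = 0.98))
  expect_lt(abs(f$p - 0.45), 0.02)
  expect_error(fit_gaussians(d, 2L, frozen = list(nonsense = 1)),
               "unknown frozen")
})

test_that("the mixture-mean identity holds across preset fixtures", {
  g <- distance_grid(1.5, 8, 256)
  tb <- two_state_presets()
  cases <- unique(tb[, c("sample", "timepoint")])
  for (i in seq_len(nrow(cases))) {
    d <- preset_distribution(cases$sample[i],
                             as.character(cases$timepoint[i]), g)
    nc <- nrow(tb[tb$sample == cases$sample[i] &
                    tb$timepoint == cases$timepoint[i], ])
    f <- fit_gaussians(d, nc, seed = 5 + i)
    ## first moment of the fitted model on the same truncated support
    ## (components near the grid edge lose tail mass to truncation, which
    ## shifts the distribution's moment relative to the untruncated
    ## component means)
    w <- trapz_weights_oracle(g)
    yhat <- predict(f, g)
    mu_fit <- sum(w * g * yhat) / sum(w * yhat)
    mu_dist <- sum(w * g * d$density)
    expect_lt(abs(mu_fit - mu_dist), 0.05)
  }
})

test_that("fits are invariant to doubling the grid resolution", {
  d1 <- preset_distribution("dtau187_G303C_S316C", "right_after",
                            distance_grid(1.5, 8, 256))
  d2 <- preset_distribution("dtau187_G303C_S316C", "right_after",
                            distance_grid(1.5, 8, 512))
  f1 <- fit_gaussians(d1, 2L, seed = 6)
  f2 <- fit_gaussians(d2, 2L, seed = 6)
  expect_lt(abs(f1$r_S - f2$r_S), 0.02)
  expect_lt(abs(f1$r_Sstar - f2$r_Sstar), 0.02)
  expect_lt(abs(f1$p - f2$p), 0.02)
})

test_that("R-squared follows its definition and flags degenerate input", {
  g <- distance_grid(2, 6, 128)
  d <- mixture_to_distribution(list(gaussian_component(3.5, 0.6, 1)), g)
  f <- fit_gaussians(d, 1L, seed = 1)
  expect_equal(compute_r_squared(f, d), 1, tolerance = 1e-8)
  ## hand-computed value on a perturbed density
  pert <- d
  pert$density <- d$density + 0.05 * sin(seq(0, 6 * pi, length.out = 128))
  pert$density <- pmax(pert$density, 0)
  yhat <- predict(f, g)
  expected <- 1 - sum((pert$density - yhat)^2) /
    sum((pert$density - mean(pert$density))^2)
  expect_equal(compute_r_squared(f, pert), expected, tolerance = 1e-12)
  ## constant density: undefined, signalled
  flat <- distance_distribution(g, rep(1, 128))
  expect_warning(val <- compute_r_squared(f, flat), "undefined")
  expect_true(is.na(val))
})

test_that("model selection needs both an F-ratio win and a real minority", {
  g <- distance_grid(1.5, 8, 256)
  ## pure single Gaussian: one component wins
  d1 <- mixture_to_distribution(list(gaussian_component(3.4, 0.8, 1)), g)
  ch1 <- select_model(fit_gaussians(d1, 1L, seed = 1),
                      fit_gaussians(d1, 2L, seed = 1))
  expect_equal(ch1$n_components, 1L)
  ## resolvable mixture with a real minority: two components win
  d2 <- preset_distribution("dtau187_G272C_S285C", "right_after", g)
  d2$density <- d2$density + 0.002 * sin(seq(0, 20 * pi, length.out = 256))
  d2$density <- pmax(d2$density, 0)
  ch2 <- select_model(fit_gaussians(d2, 1L, seed = 2),
                      fit_gaussians(d2, 2L, seed = 2))
  expect_equal(ch2$n_components, 2L)
  ## minority below the population floor: one component despite the F-test
  d3 <- mixture_to_distribution(list(gaussian_component(3.0, 0.5, 0.99),
                                     gaussian_component(5.5, 0.3, 0.01)), g)
  ch3 <- select_model(fit_gaussians(d3, 1L, seed = 3),
                      fit_gaussians(d3, 2L, seed = 3))
  expect_equal(ch3$n_components, 1L)
})

test_that("two-state fit methods expose coefficients and predictions", {
  g <- distance_grid(1.5, 8, 128)
  d <- preset_distribution("dtau187_G272C_S285C", "right_after", g)
  f <- fit_gaussians(d, 2L, seed = 1)
  co <- coef(f)
  expect_named(co, c("r_S", "sigma_S", "r_Sstar", "sigma_Sstar", "p", "A"))
  yhat <- predict(f, g)
  expect_length(yhat, 128)
  expect_true(all(yhat >= 0))
  expect_output(print(f), "Two-state fit")
})
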