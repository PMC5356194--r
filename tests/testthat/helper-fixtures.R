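## Shared fixture builders: everything is generated in code at test time.

## numeric quadrature oracle for the powder-averaged dipolar kernel,
## independent of the closed-form implementation
kernel_quadrature <- function(t, r) {
  nu <- 52.04 / r^3
  stats::integrate(function(x) cos((1 - 3 * x^2) * 2 * pi * nu * t),
                   0, 1, rel.tol = 1e-11, abs.tol = 1e-11,
                   subdivisions = 2000L)$value
}

small_kernel <- function(n_t = 64L, n_r = 64L, t_max = 3.2,
                         r_range = c(1.5, 8)) {
  build_kernel(time_grid(t_max, n_t),
               distance_grid(r_range[1], r_range[2], n_r))
}

## exact mixture density for a preset row, on a given grid
preset_distribution <- function(sample, timepoint, grid = distance_grid()) {
  mixture_to_distribution(preset_components(sample, timepoint), grid)
}

## independent trapezoid weights, used only as a brute-force oracle
trapz_weights_oracle <- function(x) {
  dx <- x[2] - x[1]
  c(dx / 2, rep(dx, length(x) - 2L), dx / 2)
}

l1_distance <- function(d1, d2) {
  dr <- d1$r[2] - d1$r[1]
  sum(abs(d1$density - d2$density)) * dr
}

## noiseless form factor for a mixture (no background, lambda = 1):
## the plain dipolar signal K P as a deer_trace
dipolar_signal <- function(dist, kernel, noise_sigma = 0) {
  deer_trace(kernel$t, apply_kernel(kernel, dist),
             noise_sigma = noise_sigma)
}
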