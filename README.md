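# deerpop

Conformational population analysis of DEER (double electron-electron
resonance) distance distributions, built around the two-state model used to
track the compact-to-extended transformation of amyloidogenic protein
segments — such as the PHF6/PHF6* hexapeptide regions of tau — during the
earliest stages of aggregation.

It is written for EPR spectroscopists and structural biologists who have
(or want to simulate) four-pulse DEER dipolar evolution traces of
spin-labelled, intrinsically disordered proteins and need populations of
conformational states, not just distance distributions.

## The model

A background-corrected DEER trace is the dipolar form factor

F(t) = (1 − λ) + λ ∫ K(t, r) P(r) dr,

with modulation depth λ and the powder-averaged dipolar kernel
K(t, r) = ∫₀¹ cos[(1 − 3x²)·2π·ν(r)·t] dx, ν(r) = 52.04 MHz·nm³ / r³.
The measured signal is V(t) = F(t)·B(t) + noise with an intermolecular
background B(t) = exp(−k·t^(d/3)).

The distance distribution P(r) is inverted from S(t) by non-negative
Tikhonov regularization with L-curve corner selection of α, refined by a
maximum-entropy step, and then fitted with the constrained two-state
Gaussian model

P(r) = A·[ p·N(r; r_S, σ_S) + (1 − p)·N(r; r_S*, σ_S*) ],

where S is the compact (stable) state, S* the extended
(aggregation-prone) state and p the S population.  Aggregation time
courses are analysed jointly with shared component shapes (the S→S*
transition model), so populations p(t) are comparable across timepoints.

## Worked example

Simulate a trace for the compact state of Δtau187 G272C/S285C (spin labels
flanking PHF6*) under realistic conditions — 256 points to 3.2 μs,
λ = 0.3, k = 0.05 μs⁻¹, SNR 50 — and analyse it end to end:

```r
library(deerpop)

sim <- simulate_deer(preset_components("dtau187_G272C_S285C", "before"),
                     seed = 101)
fit <- deer_fit(sim$trace, n_components = 1, seed = 101)
fit
#> DEER two-state population fit
#>   background: k = 0.05053 1/us (d = 3), lambda = 0.299
#>   inversion:  alpha = 47.55 (L-curve corner), maxent refined
#> Single-state fit: r = 3.160 nm, sigma = 1.021 nm (R^2 = 0.9626)
```

The background rate and modulation depth come back at their generating
values (0.05 μs⁻¹, 0.3), and the fitted mean inter-label distance, 3.16 nm,
is the compact-state distance the trace was generated from; sigma is
slightly broadened by regularization.  `plot(fit)` shows the trace with its
reconstruction and P(r) with the fitted Gaussian; `coef()`, `summary()`,
`predict()`, `residuals()` and `simulate()` behave as for any fitted model
object.

A full aggregation time course, with the shared-shape transition analysis:

```r
res <- run_deer_pipeline(list(
  simulation = list(preset = "dtau187_G272C_S285C", seed = 3)))
res$table   # sample, timepoint, state, r, sigma, p, R^2 per row
```

which reports, per timepoint, the S and S* means, widths and populations —
the synthetic course reproduces the compact state emptying into the
extended state (p_S: 1.00 → ~0.5 → ~0.2 → ~0.1 across
before/right-after/10 min/1 h at these conditions).

File-based workflows use `read_deer_trace()` / `write_deer_trace()`
(two-column text, `#` headers, μs or flagged-ns time), distribution files
(`r_nm density_per_nm`), and conformer ensembles either as multi-model PDB
or as a plain XYZ dialect: one `x y z` row (nm) per site, conformers
separated by blank lines, with an optional `# site_labels: ...` header.

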