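#' Published two-state parameter sets for tau constructs
#'
#' The Gaussian two-state (S/S*) parameters reported for the four
#' spin-labelled tau constructs — Dtau187 G272C/S285C and G303C/S316C
#' (flanking PHF6* and PHF6 respectively) and the R2 peptides R2/12
#' G273C/L284C and R2/14 G272C/S285C — across the heparin-induced
#' aggregation time course.  Each row gives the mean distance `r` (nm),
#' width `sigma` (nm) and population `p` of one state at one timepoint;
#' states not populated at a timepoint are absent.  These parameter sets
#' drive the synthetic trace generator: they are the ground truths against
#' which the inversion and population fitting are validated.
#'
#' Dipolar evolution runs to 3.2 us for the Dtau187 constructs and 2.0 us
#' for the shorter R2 peptides (`t_max` column).
#'
#' @return a data.frame with columns `sample`, `timepoint` (one of
#'   `before`, `right_after`, `10min`, `1h`), `state` (`S` or `Sstar`),
#'   `r`, `sigma`, `p`, `t_max`.
#' @export
#' @examples
#' tb <- two_state_presets()
#' subset(tb, sample == "dtau187_G272C_S285C" & timepoint == "10min")
two_state_presets <- function() {
  row <- function(sample, timepoint, state, r, sigma, p, t_max) {
    data.frame(sample = sample, timepoint = timepoint, state = state,
               r = r, sigma = sigma, p = p, t_max = t_max,
               stringsAsFactors = FALSE)
  }
  tb <- rbind(
    ## Dtau187 G272C/S285C (PHF6* region, sites 272/285)
    row("dtau187_G272C_S285C", "before",      "S",     3.16, 0.98, 1.00, 3.2),
    row("dtau187_G272C_S285C", "right_after", "S",     3.16, 0.98, 0.45, 3.2),
    row("dtau187_G272C_S285C", "right_after", "Sstar", 4.10, 1.10, 0.55, 3.2),
    row("dtau187_G272C_S285C", "10min",       "S",     3.16, 0.98, 0.09, 3.2),
    row("dtau187_G272C_S285C", "10min",       "Sstar", 4.10, 1.10, 0.91, 3.2),
    row("dtau187_G272C_S285C", "1h",          "Sstar", 4.35, 1.10, 1.00, 3.2),
    ## Dtau187 G303C/S316C (PHF6 region, sites 303/316)
    row("dtau187_G303C_S316C", "before",      "S",     3.38, 0.80, 1.00, 3.2),
    row("dtau187_G303C_S316C", "right_after", "S",     3.38, 0.86, 0.47, 3.2),
    row("dtau187_G303C_S316C", "right_after", "Sstar", 4.40, 0.80, 0.53, 3.2),
    row("dtau187_G303C_S316C", "10min",       "S",     3.38, 0.86, 0.12, 3.2),
    row("dtau187_G303C_S316C", "10min",       "Sstar", 4.22, 0.86, 0.88, 3.2),
    row("dtau187_G303C_S316C", "1h",          "Sstar", 4.10, 0.98, 1.00, 3.2),
    ## R2/12 peptide G273C/L284C (no 10 min timepoint reported)
    row("r2_12_G273C_L284C",   "before",      "S",     3.00, 0.56, 0.80, 2.0),
    row("r2_12_G273C_L284C",   "before",      "Sstar", 3.75, 0.48, 0.20, 2.0),
    row("r2_12_G273C_L284C",   "right_after", "S",     3.00, 0.62, 0.65, 2.0),
    row("r2_12_G273C_L284C",   "right_after", "Sstar", 4.00, 0.65, 0.35, 2.0),
    row("r2_12_G273C_L284C",   "1h",          "S",     3.00, 0.50, 0.54, 2.0),
    row("r2_12_G273C_L284C",   "1h",          "Sstar", 4.00, 0.60, 0.46, 2.0),
    ## R2/14 peptide G272C/S285C
    row("r2_14_G272C_S285C",   "before",      "S",     3.60, 0.75, 0.95, 2.0),
    row("r2_14_G272C_S285C",   "before",      "Sstar", 4.35, 0.30, 0.05, 2.0),
    row("r2_14_G272C_S285C",   "right_after", "S",     3.40, 0.75, 0.90, 2.0),
    row("r2_14_G272C_S285C",   "right_after", "Sstar", 4.60, 0.60, 0.10, 2.0),
    row("r2_14_G272C_S285C",   "1h",          "S",     3.40, 0.75, 0.45, 2.0),
    row("r2_14_G272C_S285C",   "1h",          "Sstar", 4.60, 0.70, 0.55, 2.0)
  )
  tb$timepoint <- factor(tb$timepoint,
                         levels = c("before", "right_after", "10min", "1h"))
  tb
}

#' Gaussian components for one preset sample/timepoint
#'
#' @param sample sample name as in [two_state_presets()].
#' @param timepoint timepoint label.
#' @return list of [gaussian_component()] ordered S then S*, with attribute
#'   `t_max` (us).
#' @export
preset_components <- function(sample, timepoint) {
  tb <- two_state_presets()
  sel <- tb[tb$sample == sample & tb$timepoint == timepoint, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop(sprintf("no preset for sample '%s' at timepoint '%s'", sample, timepoint),
         call. = FALSE)
  }
  comps <- lapply(seq_len(nrow(sel)), function(i) {
    gaussian_component(sel$r[i], sel$sigma[i], sel$p[i])
  })
  names(comps) <- sel$state
  attr(comps, "t_max") <- sel$t_max[1L]
  comps
}
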