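# Independent oracles used across the suite. These synthesize decays by the
# direct wrapped-exponential formula at mid-bin times (no FFT, no shared code
# with the generator) so they stay independent of the paths they check.

PERIOD_80MHZ <- 12.5
OMEGA_1 <- 2 * pi / PERIOD_80MHZ

# normalized wrapped mono-exponential sampled at mid-bin times
oracle_exp_shape <- function(tau, n_bins = 256L, period = PERIOD_80MHZ) {
  t_k <- (seq_len(n_bins) - 0.5) * period / n_bins
  if (tau == 0) {
    y <- numeric(n_bins)
    y[1L] <- 1
    return(y)
  }
  y <- exp(-t_k / tau)
  y / sum(y)
}

# decay histogram of an intensity-weighted multi-exponential mixture
oracle_mix_hist <- function(taus, fractions, n_bins = 256L,
                            period = PERIOD_80MHZ, total = 1) {
  shape <- Reduce(`+`, Map(function(tau, f) f * oracle_exp_shape(tau, n_bins, period),
                           taus, fractions))
  decay_histogram(shape * total, period = period)
}

# closed-form Welch statistic, computed from first principles
oracle_welch_t <- function(x, y) {
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  (mean(x) - mean(y)) / se
}

# a synthetic phasor field built directly from matrices (bypasses images)
make_field <- function(g, s, intensity = matrix(100, nrow(g), ncol(g)),
                       harmonic = 1L, period = PERIOD_80MHZ, n_bins = 256L) {
  structure(
    list(g = g, s = s, intensity = intensity, harmonic = harmonic,
         omega = 2 * pi * harmonic / period, period = period,
         n_bins = n_bins, calibrated = FALSE),
    class = "phasor_field"
  )
}
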