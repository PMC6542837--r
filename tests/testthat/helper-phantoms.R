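# Shared fixture builders for the test suite. Everything is generated in
# code from fixed seeds; nothing is read from disk.

# A mid-sized trajectory spec per regime, used by recovery properties.
regime_spec <- function(regime, seed) {
  switch(regime,
    two_step_no_recovery = squeeze_trajectory_spec(
      "two_step_no_recovery", plateau_diameter_mm = 12,
      first_step_diameter_mm = 5, seed = seed),
    oscillatory_partial_recovery = squeeze_trajectory_spec(
      "oscillatory_partial_recovery", plateau_diameter_mm = 6.8,
      osc_freq_hz = 6, osc_amplitude_mm = 1, residual_diameter_mm = 5,
      seed = seed),
    fast_rise_full_recovery = squeeze_trajectory_spec(
      "fast_rise_full_recovery", plateau_diameter_mm = 6, seed = seed))
}

# Independent decompensation oracle, coded via log10 rather than ln.
oracle_i_prime <- function(counts, gamma, bit_depth) {
  gamma * (log10(2^bit_depth - 1) - log10(pmax(counts, 1)))
}

# Analytic disc mask on an integer pixel grid.
disc_mask <- function(dim, center, radius) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}
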