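# Shared fixtures and independent oracles used across the test files.

# A canonical noiseless decay on the standard 0-300 s / 5 s grid.
noiseless_decay <- function(p1 = 0.25, t1 = 15, p2 = 0.5, t2 = 200) {
  normalize_trace(simulate_decay(decay_truth(p1, t1, p2, t2),
                                 noise_sd = 0, seed = 1))
}

# Independent transcription of the per-fiber ATP consumption formula,
# written term by term so it shares no code with the implementation.
oracle_atp <- function(p1_pct, t1_s, p2_pct, t2_s, conc = 220) {
  drx_heads <- p1_pct / 100
  srx_heads <- p2_pct / 100
  drx_turnovers_per_min <- 60 / t1_s
  srx_turnovers_per_min <- 60 / t2_s
  drx_heads * conc * drx_turnovers_per_min +
    srx_heads * conc * srx_turnovers_per_min
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# q_i = min_{j >= i} ( m * p_(j) / j ), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Small two-condition study used by several end-to-end tests.
small_torpor_effects <- function(t1_mult = 0.65) {
  condition_effects(condition_mult = tibble::tibble(
    condition = "torpor", fiber_type = "II",
    t1_mult = t1_mult, t2_mult = 1, p1_shift = 0))
}
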