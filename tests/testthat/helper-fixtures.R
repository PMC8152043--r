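# shared fixture builders: everything is generated in code at test time

# spectral frame built directly from a magnitude vector (bins 0..n_half)
frame_from_mags <- function(mags, rate_hz = 6000) {
  n_half <- length(mags) - 1L
  structure(
    list(magnitudes = as.numeric(mags),
         freq_hz = (0:n_half) * rate_hz / (2 * n_half),
         bin_hz = rate_hz / (2 * n_half), t_s = 0,
         weighting = "magnitude"),
    class = "spectral_frame"
  )
}

# random non-negative frame with a random subset of zeroed bins
random_frame <- function(n_half = 128, rate_hz = 6000) {
  mags <- stats::runif(n_half + 1, 0, 10)
  mags[sample.int(n_half + 1, size = n_half %/% 4)] <- 0
  frame_from_mags(mags, rate_hz)
}

# independent brute-force oracles (plain loops, no shared code path)
oracle_median_freq <- function(mags, freqs) {
  tot <- 0
  for (m in mags) tot <- tot + m
  if (tot <= 0) return(NA_real_)
  acc <- 0
  for (i in seq_along(mags)) {
    acc <- acc + mags[i]
    if (acc >= tot / 2) return(freqs[i])
  }
  NA_real_
}

oracle_mean_freq <- function(mags, freqs) {
  num <- 0; den <- 0
  for (i in seq_along(mags)) {
    num <- num + freqs[i] * mags[i]
    den <- den + mags[i]
  }
  if (den <= 0) NA_real_ else num / den
}

oracle_total_mag <- function(mags) {
  s <- 0
  for (i in seq_along(mags)) if (i > 1) s <- s + mags[i]
  s
}

# mid-stroke summary used by synthesis fidelity checks: median of the gated
# median-frequency samples over the central 20% of windows
mid_stroke_median <- function(ft, gate_mv = 300) {
  n <- nrow(ft)
  mid <- ft[seq(floor(0.4 * n) + 1, ceiling(0.6 * n)), ]
  mid <- mid[mid$total_mag_mv > gate_mv & !is.na(mid$median_hz), ]
  stats::median(mid$median_hz)
}

# narrowband test burst: tone cluster centered on `center_hz`
narrowband_profile <- function(center_hz, bandwidth_hz = 10, jitter_hz = 1) {
  texture_profile("burst", function(u) rep(center_hz, length(u)),
                  bandwidth_hz = bandwidth_hz, jitter_hz = jitter_hz)
}

# constant-frequency command trace helper for scheduler tests
constant_commands <- function(freq_hz, t_end_s, step_s = 128 / 6000,
                              active = TRUE, amplitude_ma = 4) {
  t <- seq(0, t_end_s, by = step_s)
  data.frame(t_s = t, active = active,
             frequency_hz = ifelse(active, freq_hz, NA_real_),
             amplitude_ma = amplitude_ma, pulse_width_us = 250)
}
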