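# FFT stage, bin exclusions, and the three spectral features

test_that("spectrum handles null, sub-cutoff and bin-centered signals", {
  cfg <- spectral_config()
  expect_equal(spectrum(numeric(2048), cfg)$magnitudes, rep(0, 1025))

  # a bin-centered tone below the 20 Hz cut (bin 4, ~11.7 Hz) is removed
  # entirely by the exclusion rule
  f_lo <- 4 * 6000 / 2048
  t_lo <- 5000 * sin(2 * pi * f_lo * (0:2047) / 6000)
  expect_true(all(abs(spectrum(round(t_lo), cfg)$magnitudes) < 1))

  # a tone at an exact bin center concentrates in that single bin
  f100 <- 100 * 6000 / 2048  # bin 100 center, ~292.97 Hz
  tone <- round(8000 * cos(2 * pi * f100 * (0:2047) / 6000))
  fr <- spectrum(tone, cfg)
  expect_equal(which.max(fr$magnitudes) - 1, 100)
  expect_gt(fr$magnitudes[101], 100 * sum(fr$magnitudes[-101]) + 1e-12)
  expect_error(spectrum(numeric(100), cfg), "length")
})

test_that("spectrum matches a direct DFT oracle on a small window", {
  cfg <- spectral_config(fft_size = 256, hop = 64)
  set.seed(7)
  x <- round(rnorm(256, 0, 2000))
  fr <- spectrum(x, cfg, scale_mv_per_count = 1)
  # O(n^2) DFT, amplitude convention: 2|X|/n except DC and Nyquist
  n <- 256
  k <- 0:(n / 2)
  oracle <- vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))) / n
  }, 0)
  oracle[2:(n / 2)] <- 2 * oracle[2:(n / 2)]
  freqs <- k * cfg$rate_hz / n
  oracle[freqs < cfg$highpass_hz] <- 0
  oracle[which.min(abs(freqs - cfg$notch_hz))] <- 0
  expect_equal(fr$magnitudes, oracle, tolerance = 1e-10)
})

test_that("exclusions zero DC, sub-20 Hz bins and the 50 Hz notch bin", {
  cfg <- spectral_config()
  x <- round(3000 * rnorm(2048))
  set.seed(3)
  fr <- spectrum(x, cfg)
  freqs <- fr$freq_hz
  expect_true(all(fr$magnitudes[freqs < 20] == 0))
  expect_equal(fr$magnitudes[which.min(abs(freqs - 50))], 0)
  # bin resolution at defaults ~2.93 Hz
  expect_equal(fr$bin_hz, 6000 / 2048)
})

test_that("median frequency follows the cumulative half-mass convention", {
  n_half <- 1024
  mags <- rep(0, n_half + 1)
  bin200 <- round(200 * 2048 / 6000)  # bin nearest 200 Hz
  mags[bin200 + 1] <- 7
  fr <- frame_from_mags(mags)
  expect_equal(median_frequency(fr), fr$freq_hz[bin200 + 1])

  # equal mass at ~100 and ~300 Hz: the lower bin reaches half mass first
  mags <- rep(0, n_half + 1)
  b100 <- round(100 * 2048 / 6000); b300 <- round(300 * 2048 / 6000)
  mags[c(b100, b300) + 1] <- 5
  fr <- frame_from_mags(mags)
  expect_equal(median_frequency(fr), fr$freq_hz[b100 + 1])

  # uniform mass: first bin whose cumulative count reaches half the bins
  mags <- rep(1, n_half + 1)
  fr <- frame_from_mags(mags)
  expect_equal(median_frequency(fr),
               oracle_median_freq(mags, fr$freq_hz))

  expect_true(is.na(median_frequency(frame_from_mags(rep(0, 10)))))
})

test_that("mean frequency is the magnitude-weighted bin-center mean", {
  mags <- rep(0, 1025)
  b200 <- round(200 * 2048 / 6000)
  mags[b200 + 1] <- 3
  fr <- frame_from_mags(mags)
  expect_equal(mean_frequency(fr), fr$freq_hz[b200 + 1])

  mags <- rep(0, 1025)
  b100 <- round(100 * 2048 / 6000); b300 <- round(300 * 2048 / 6000)
  mags[c(b100, b300) + 1] <- 4
  fr <- frame_from_mags(mags)
  expect_equal(mean_frequency(fr),
               (fr$freq_hz[b100 + 1] + fr$freq_hz[b300 + 1]) / 2)
  expect_true(is.na(mean_frequency(frame_from_mags(rep(0, 10)))))
})

test_that("features agree with brute-force oracles on random frames", {
  set.seed(11)
  for (i in 1:50) {
    fr <- random_frame()
    expect_equal(median_frequency(fr),
                 oracle_median_freq(fr$magnitudes, fr$freq_hz))
    expect_equal(mean_frequency(fr),
                 oracle_mean_freq(fr$magnitudes, fr$freq_hz))
    expect_equal(total_magnitude(fr), oracle_total_mag(fr$magnitudes))
  }
})

test_that("half-mass bracketing and scaling invariances hold", {
  set.seed(12)
  for (i in 1:30) {
    fr <- random_frame()
    med <- median_frequency(fr)
    idx <- match(med, fr$freq_hz)
    cs <- cumsum(fr$magnitudes)
    tot <- sum(fr$magnitudes)
    expect_gte(cs[idx], tot / 2)
    if (idx > 1) expect_lt(cs[idx - 1], tot / 2)
    # median invariant to uniform magnitude scaling; total scales linearly
    fr3 <- fr; fr3$magnitudes <- 3 * fr$magnitudes
    expect_equal(median_frequency(fr3), med)
    expect_equal(total_magnitude(fr3), 3 * total_magnitude(fr))
  }
})

test_that("total magnitude of a pure tone grows linearly with amplitude", {
  cfg <- spectral_config()
  f <- 120 * 6000 / 2048
  tone <- function(a) round(a * cos(2 * pi * f * (0:2047) / 6000))
  t1 <- total_magnitude(spectrum(tone(2000), cfg))
  t2 <- total_magnitude(spectrum(tone(4000), cfg))
  t4 <- total_magnitude(spectrum(tone(8000), cfg))
  expect_equal(t2 / t1, 2, tolerance = 1e-3)
  expect_equal(t4 / t1, 4, tolerance = 1e-3)
})

test_that("feature traces have the documented cadence and bounds", {
  cfg <- spectral_config()
  silence <- audio_stream(integer(6000))
  ft <- feature_trace(silence, cfg)
  expect_equal(nrow(ft), 31)
  expect_true(all(ft$total_mag_mv == 0))
  expect_true(all(is.na(ft$median_hz)))
  # nominal update interval hop/rate ~ 21.3 ms
  expect_equal(unique(round(diff(ft$t_s), 12)), 128 / 6000)

  burst <- synth_stroke(narrowband_profile(200), 1, seed = 5)
  ftb <- feature_trace(burst, cfg)
  on <- ftb$total_mag_mv > 300
  interior <- on & seq_len(nrow(ftb)) > 5 & seq_len(nrow(ftb)) < nrow(ftb) - 5
  expect_true(all(abs(ftb$median_hz[interior] - 200) <= 2 * 6000 / 2048))
  # gated-on features stay inside [highpass, Nyquist]
  expect_true(all(ftb$median_hz[on] >= 20 & ftb$median_hz[on] <= 3000))
  expect_true(all(ftb$mean_hz[on] >= 20 & ftb$mean_hz[on] <= 3000))
})

test_that("feature CSV export round-trips", {
  csv <- withr::local_tempfile(fileext = ".csv")
  ft <- feature_trace(synth_stroke(narrowband_profile(200), 0.5, seed = 2))
  write_feature_csv(ft, csv)
  df <- read.csv(csv)
  expect_named(df, c("t_s", "median_hz", "mean_hz", "total_mag_mv"))
  expect_equal(df$total_mag_mv, ft$total_mag_mv)
})
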