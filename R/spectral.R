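#' Spectral analysis configuration
#'
#' Parameters of the sliding-window FFT stage. Defaults reproduce the
#' real-time sensor pipeline: 2048-sample FFT updated every 128 samples at a
#' 6 kHz sampling rate (a ~50 Hz update rate, 2048/6000 ~ 0.34 s of context
#' per window, ~2.93 Hz per bin), with all bins below 20 Hz and the bin at
#' the 50 Hz mains frequency zeroed before any feature is computed.
#'
#' @param fft_size Window/FFT length in samples; must be a power of two.
#' @param hop Update stride in samples; `1 <= hop <= fft_size`.
#' @param rate_hz Sampling rate in Hz.
#' @param highpass_hz Every bin with center frequency strictly below this is
#'   removed (DC included). Default 20 Hz.
#' @param notch_hz Mains notch: the bin whose center is nearest this
#'   frequency is removed. Default 50 Hz.
#' @param notch_halfwidth_bins Extra bins removed on each side of the notch
#'   bin (default 0: single-bin notch).
#' @param window_fn Analysis window, `"rectangular"` (default) or `"hann"`.
#' @param weighting Whether median/mean frequency weight bins by magnitude
#'   (default) or by power (squared magnitude), for sensitivity analysis.
#' @return An object of class `"spectral_config"`.
#' @export
spectral_config <- function(fft_size = 2048, hop = 128, rate_hz = 6000,
                            highpass_hz = 20, notch_hz = 50,
                            notch_halfwidth_bins = 0,
                            window_fn = c("rectangular", "hann"),
                            weighting = c("magnitude", "power")) {
  window_fn <- match.arg(window_fn)
  weighting <- match.arg(weighting)
  fft_size <- as.integer(fft_size); hop <- as.integer(hop)
  if (fft_size < 2 || bitwAnd(fft_size, fft_size - 1L) != 0L) {
    stop("fft_size must be a power of two")
  }
  if (hop < 1 || hop > fft_size) stop("need 1 <= hop <= fft_size")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (highpass_hz < 0 || notch_hz < 0) stop("cutoffs must be non-negative")
  structure(
    list(fft_size = fft_size, hop = hop, rate_hz = rate_hz,
         highpass_hz = highpass_hz, notch_hz = notch_hz,
         notch_halfwidth_bins = as.integer(notch_halfwidth_bins),
         window_fn = window_fn, weighting = weighting),
    class = "spectral_config"
  )
}

#' @export
print.spectral_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<spectral_config> fft %d / hop %d @ %g Hz (%.2f Hz/bin, %.1f ms ",
    "update)\n  exclusions: < %g Hz, notch %g Hz (+/-%d bins); %s window, ",
    "%s weighting\n"),
    x$fft_size, x$hop, x$rate_hz, x$rate_hz / x$fft_size,
    1000 * x$hop / x$rate_hz, x$highpass_hz, x$notch_hz,
    x$notch_halfwidth_bins, x$window_fn, x$weighting))
  invisible(x)
}

# indices (1-based) of excluded bins for a config, over bins 0..fft_size/2
excluded_bins <- function(config) {
  freqs <- bin_freqs(config)
  excl <- which(freqs < config$highpass_hz)
  notch_center <- which.min(abs(freqs - config$notch_hz))
  hw <- config$notch_halfwidth_bins
  notch <- (notch_center - hw):(notch_center + hw)
  notch <- notch[notch >= 1 & notch <= length(freqs)]
  sort(unique(c(excl, notch)))
}

bin_freqs <- function(config) {
  (0:(config$fft_size / 2)) * config$rate_hz / config$fft_size
}

analysis_window <- function(config) {
  n <- config$fft_size
  switch(config$window_fn,
         rectangular = rep(1, n),
         hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Magnitude spectrum of one analysis window
#'
#' Computes the one-sided amplitude spectrum of a single window of samples,
#' scales it to millivolts, and zeroes the excluded bins (below the highpass
#' cutoff and at the mains notch). Magnitudes use the amplitude convention
#' in which a pure full-bin tone of peak amplitude A appears as a single bin
#' of magnitude A (times the mV scale), so summed magnitudes are directly
#' comparable to the millivolt gate threshold.
#'
#' @param window_samples Numeric vector of exactly `config$fft_size` samples
#'   (ADC counts).
#' @param config A [spectral_config()].
#' @param scale_mv_per_count Millivolts per count (default as in
#'   [audio_stream()]).
#' @param t_s Timestamp (window-end time, seconds) to attach to the frame.
#' @return An object of class `"spectral_frame"`: list with `magnitudes`
#'   (length `fft_size/2 + 1`, mV), `freq_hz` (bin centers), `bin_hz`, `t_s`.
#' @export
spectrum <- function(window_samples, config = spectral_config(),
                     scale_mv_per_count = 3300 / 32768, t_s = NA_real_) {
  n <- config$fft_size
  if (length(window_samples) != n) {
    stop("window_samples must have length fft_size = ", n,
         " (got ", length(window_samples), ")")
  }
  mag <- window_magnitudes(matrix(as.numeric(window_samples), ncol = 1),
                           config, scale_mv_per_count)[, 1]
  spectral_frame(mag, config, t_s)
}

# shared FFT core: samples matrix (fft_size x nwin) -> magnitude matrix
# ((fft_size/2+1) x nwin), mV-scaled, exclusions applied
window_magnitudes <- function(frames, config, scale_mv_per_count) {
  n <- config$fft_size
  half <- n %/% 2L
  w <- analysis_window(config)
  X <- stats::mvfft(frames * w)
  mag <- Mod(X[1:(half + 1L), , drop = FALSE]) / n
  if (half >= 2) mag[2:half, ] <- 2 * mag[2:half, ]
  mag <- mag * scale_mv_per_count
  mag[excluded_bins(config), ] <- 0
  mag
}

spectral_frame <- function(magnitudes, config, t_s = NA_real_) {
  structure(
    list(magnitudes = magnitudes, freq_hz = bin_freqs(config),
         bin_hz = config$rate_hz / config$fft_size, t_s = t_s,
         weighting = config$weighting),
    class = "spectral_frame"
  )
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf(
    "<spectral_frame> %d bins x %.3f Hz, total %.1f mV, t = %s s\n",
    length(x$magnitudes), x$bin_hz, sum(x$magnitudes[-1]),
    format(x$t_s)))
  invisible(x)
}

frame_weights <- function(frame, weighting) {
  w <- frame$magnitudes
  if (identical(weighting, "power")) w <- w^2
  w
}

#' Median frequency of a spectral frame
#'
#' The texture feature driving the stimulation frequency: the smallest
#' bin-center frequency at which the cumulative retained spectral mass
#' reaches at least half of the total retained mass. Mass is bin magnitude
#' by default (squared magnitude under `weighting = "power"`). An all-zero
#' frame has no defined median and returns `NA`; callers treat that as
#' gate-off.
#'
#' @param frame A `"spectral_frame"` from [spectrum()].
#' @param weighting `"magnitude"` (default) or `"power"`.
#' @return Median frequency in Hz, or `NA_real_` for an all-zero frame.
#' @export
median_frequency <- function(frame, weighting = frame$weighting) {
  w <- frame_weights(frame, weighting)
  tot <- sum(w)
  if (tot <= 0) return(NA_real_)
  frame$freq_hz[which(cumsum(w) >= tot / 2)[1]]
}

#' Mean frequency of a spectral frame
#'
#' Magnitude-weighted mean of the retained bin-center frequencies; the
#' alternative feature that was considered alongside the median frequency.
#'
#' @inheritParams median_frequency
#' @return Mean frequency in Hz, or `NA_real_` for an all-zero frame.
#' @export
mean_frequency <- function(frame, weighting = frame$weighting) {
  w <- frame_weights(frame, weighting)
  tot <- sum(w)
  if (tot <= 0) return(NA_real_)
  sum(frame$freq_hz * w) / tot
}

#' Total spectral magnitude of a frame
#'
#' Sum of retained bin magnitudes from bin 1 to the Nyquist bin (DC
#' excluded), in millivolts. This is the "total signal energy" quantity
#' compared against the stimulation gate threshold.
#'
#' @param frame A `"spectral_frame"`.
#' @return Total retained magnitude in mV (>= 0).
#' @export
total_magnitude <- function(frame) {
  sum(frame$magnitudes[-1])
}

#' Sliding-window feature trace of a stream
#'
#' Runs the full spectral stage over a stream: sliding 2048-sample windows
#' every 128 samples (at defaults), one FFT per window, bin exclusions, and
#' per-window median frequency, mean frequency and total magnitude. Each row
#' is stamped with the window-end time; at defaults rows are 128/6000 s
#' (~21.3 ms) apart, i.e. a ~50 Hz feature update rate.
#'
#' @param stream An [audio_stream()].
#' @param config A [spectral_config()]; its `rate_hz` should match the
#'   stream's.
#' @return A data frame of class `"feature_trace"` with columns `t_s`,
#'   `median_hz`, `mean_hz`, `total_mag_mv`. Silent windows carry
#'   `NA` median/mean and zero total magnitude. The config is attached as
#'   attribute `"config"`.
#' @export
feature_trace <- function(stream, config = spectral_config()) {
  stopifnot(inherits(stream, "audio_stream"))
  frames <- frame_stream(stream, config$fft_size, config$hop)
  nwin <- ncol(frames)
  if (nwin == 0) {
    out <- data.frame(t_s = numeric(0), median_hz = numeric(0),
                      mean_hz = numeric(0), total_mag_mv = numeric(0))
    return(structure(out, class = c("feature_trace", "data.frame"),
                     config = config))
  }
  mag <- window_magnitudes(frames, config, stream$scale_mv_per_count)
  w <- if (identical(config$weighting, "power")) mag^2 else mag
  freqs <- bin_freqs(config)
  totw <- colSums(w)
  total <- colSums(mag[-1, , drop = FALSE])
  med <- rep(NA_real_, nwin)
  pos <- which(totw > 0)
  if (length(pos)) {
    cs <- apply(w[, pos, drop = FALSE], 2, cumsum)
    hit <- cs >= rep(totw[pos] / 2, each = nrow(cs))
    med[pos] <- freqs[apply(hit, 2, which.max)]
  }
  mean_hz <- rep(NA_real_, nwin)
  mean_hz[pos] <- colSums(freqs * w[, pos, drop = FALSE]) / totw[pos]
  t_s <- (config$fft_size + (seq_len(nwin) - 1) * config$hop) / config$rate_hz
  out <- data.frame(t_s = t_s, median_hz = med, mean_hz = mean_hz,
                    total_mag_mv = total)
  structure(out, class = c("feature_trace", "data.frame"), config = config)
}

#' @export
print.feature_trace <- function(x, ...) {
  cat(sprintf("<feature_trace> %d windows, %.3f-%.3f s\n", nrow(x),
              if (nrow(x)) min(x$t_s) else NA, if (nrow(x)) max(x$t_s) else NA))
  NextMethod()
}

#' Plot a feature trace
#'
#' Two stacked panels: median frequency over time (gated-on windows only)
#' and total spectral magnitude with the gate threshold.
#'
#' @param x A `"feature_trace"`.
#' @param gate_threshold_mv Gate threshold to draw (default 300 mV).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.feature_trace <- function(x, gate_threshold_mv = 300, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  on_idx <- x$total_mag_mv > gate_threshold_mv
  graphics::plot(x$t_s[on_idx], x$median_hz[on_idx], type = "p", pch = 16,
                 cex = 0.5, xlab = "time (s)", ylab = "median freq (Hz)", ...)
  graphics::plot(x$t_s, x$total_mag_mv, type = "l", xlab = "time (s)",
                 ylab = "total magnitude (mV)")
  graphics::abline(h = gate_threshold_mv, lty = 2)
  invisible(x)
}

#' Write a feature trace to CSV
#'
#' Columns: `t_s, median_hz, mean_hz, total_mag_mv`.
#'
#' @param trace A `"feature_trace"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Per-window signal envelope (exploratory stub)
#'
#' Root-mean-square amplitude per analysis window, in millivolts. The
#' envelope was an alternative feature that discriminated textures poorly
#' compared to the median frequency; it is kept only as a stub for
#' comparison plots.
#'
#' @inheritParams feature_trace
#' @return Data frame with columns `t_s`, `rms_mv`.
#' @export
signal_envelope <- function(stream, config = spectral_config()) {
  frames <- frame_stream(stream, config$fft_size, config$hop)
  nwin <- ncol(frames)
  t_s <- (config$fft_size + (seq_len(nwin) - 1) * config$hop) / config$rate_hz
  data.frame(
    t_s = t_s,
    rms_mv = sqrt(colMeans(frames^2)) * stream$scale_mv_per_count
  )
}
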