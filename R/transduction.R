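#' Transfer-function and gating parameters
#'
#' Constants of the linear map from audio median frequency to stimulation
#' frequency, and of the energy gate that enables stimulation only during
#' surface contact. Defaults are the empirically chosen deployment values:
#' `stim = (medianf - lowerB)/scaling + 5` with `lowerB = 50` Hz and
#' `scaling = 10`, a 5 Hz output floor (the additive offset, which keeps the
#' control loop responsive — a sub-1 Hz pulse rate would stall command
#' updates for over a second), an 80 Hz output cap, and a 300 mV gate on the
#' total spectral magnitude.
#'
#' @param lowerB Lowest audio median frequency treated as relevant (Hz,
#'   default 50).
#' @param scaling Linear compression factor (dimensionless, default 10).
#' @param offset_hz Additive offset = output floor (Hz, default 5; must be at
#'   least 1, the stimulator's minimum rate).
#' @param cap_hz Output cap (Hz, default 80; at most 100, the stimulator's
#'   maximum rate).
#' @param gate_threshold_mv Total-magnitude threshold (mV, default 300) that
#'   must be strictly exceeded for stimulation to be active.
#' @return An object of class `"transfer_params"`.
#' @export
transfer_params <- function(lowerB = 50, scaling = 10, offset_hz = 5,
                            cap_hz = 80, gate_threshold_mv = 300) {
  if (scaling <= 0) stop("scaling must be positive")
  if (offset_hz < 1) stop("offset_hz must be >= 1")
  if (cap_hz > 100) stop("cap_hz must be <= 100 (stimulator maximum)")
  if (cap_hz < offset_hz) stop("cap_hz must be >= offset_hz")
  if (gate_threshold_mv < 0) stop("gate_threshold_mv must be >= 0")
  structure(
    list(lowerB = lowerB, scaling = scaling, offset_hz = offset_hz,
         cap_hz = cap_hz, gate_threshold_mv = gate_threshold_mv),
    class = "transfer_params"
  )
}

#' @export
print.transfer_params <- function(x, ...) {
  cat(sprintf(
    "<transfer_params> stim = (medianf - %g)/%g + %g, clamped to [%g, %g] Hz; gate > %g mV\n",
    x$lowerB, x$scaling, x$offset_hz, x$offset_hz, x$cap_hz,
    x$gate_threshold_mv))
  invisible(x)
}

#' Median frequency to stimulation frequency
#'
#' Applies the linear transfer `(median_hz - lowerB)/scaling + offset_hz`
#' and clamps the result to `[offset_hz, cap_hz]`. With defaults: 50 Hz in
#' gives 5 Hz out, 200 Hz gives 20 Hz, anything at or above 800 Hz saturates
#' at 80 Hz, and inputs below `lowerB` hit the 5 Hz floor. The map is
#' vectorised and monotone non-decreasing.
#'
#' @param median_hz Audio median frequency in Hz (finite, >= 0); vectorised.
#' @param params A [transfer_params()].
#' @return Stimulation frequency in Hz, same length as `median_hz`.
#' @examples
#' transfer_function(c(50, 200, 2000))  # 5, 20, 80
#' @export
transfer_function <- function(median_hz, params = transfer_params()) {
  if (any(!is.finite(median_hz))) stop("median_hz must be finite")
  raw <- (median_hz - params$lowerB) / params$scaling + params$offset_hz
  pmin(pmax(raw, params$offset_hz), params$cap_hz)
}

#' Stimulation energy gate
#'
#' Stimulation is enabled only when the total retained spectral magnitude
#' strictly exceeds the threshold, so that background noise and silence
#' between strokes never stimulate.
#'
#' @param total_mag_mv Total spectral magnitude in mV (>= 0); vectorised.
#' @param params A [transfer_params()].
#' @return Logical vector: `TRUE` where stimulation is enabled.
#' @export
gate <- function(total_mag_mv, params = transfer_params()) {
  total_mag_mv > params$gate_threshold_mv
}

# stimulator amplitude grid: 0.1 .. 10.0 mA in 0.1 mA steps
check_amplitude <- function(amplitude_ma) {
  if (!is.numeric(amplitude_ma) || length(amplitude_ma) != 1L ||
      !is.finite(amplitude_ma) ||
      amplitude_ma < 0.1 - 1e-9 || amplitude_ma > 10 + 1e-9 ||
      abs(amplitude_ma * 10 - round(amplitude_ma * 10)) > 1e-9) {
    stop("amplitude_ma must lie on the stimulator grid ",
         "{0.1, 0.2, ..., 10.0} mA")
  }
  round(amplitude_ma * 10) / 10
}

#' Convert a feature trace into stimulation commands
#'
#' One command per feature sample: the energy gate decides `active`, and for
#' active samples the median frequency passes through [transfer_function()]
#' and is rounded to the stimulator's integer-hertz grid (disable with
#' `round_hz = FALSE` for analysis). The pulse amplitude is the
#' participant-specific comfortable level, supplied as a plain parameter on
#' the stimulator's 0.1 mA grid.
#'
#' @param features A `"feature_trace"` from [feature_trace()].
#' @param params A [transfer_params()].
#' @param amplitude_ma Pulse amplitude in mA on the 0.1 mA grid within
#'   `[0.1, 10]`.
#' @param pulse_width_us Per-phase pulse width in microseconds (default 250).
#' @param round_hz Round command frequencies to integer Hz (default `TRUE`).
#' @return A data frame of class `"stim_trace"` with columns `t_s`, `active`,
#'   `frequency_hz` (`NA` when inactive), `amplitude_ma`, `pulse_width_us`.
#' @export
transduce_trace <- function(features, params = transfer_params(),
                            amplitude_ma = 4.0, pulse_width_us = 250,
                            round_hz = TRUE) {
  amplitude_ma <- check_amplitude(amplitude_ma)
  if (pulse_width_us <= 0) stop("pulse_width_us must be positive")
  active <- gate(features$total_mag_mv, params) & !is.na(features$median_hz)
  freq <- rep(NA_real_, nrow(features))
  if (any(active)) {
    f <- transfer_function(features$median_hz[active], params)
    if (round_hz) f <- pmin(pmax(round(f), params$offset_hz), params$cap_hz)
    freq[active] <- f
  }
  out <- data.frame(
    t_s = features$t_s, active = active, frequency_hz = freq,
    amplitude_ma = amplitude_ma, pulse_width_us = pulse_width_us
  )
  structure(out, class = c("stim_trace", "data.frame"), params = params)
}

#' @export
print.stim_trace <- function(x, ...) {
  cat(sprintf("<stim_trace> %d commands, %d active (%.0f%%)\n", nrow(x),
              sum(x$active), if (nrow(x)) 100 * mean(x$active) else 0))
  NextMethod()
}

#' Write a command trace to CSV
#'
#' Columns: `t_s, active, frequency_hz, amplitude_ma, pulse_width_us`.
#'
#' @param commands A `"stim_trace"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stim_csv <- function(commands, path) {
  utils::write.csv(as.data.frame(commands), path, row.names = FALSE)
  invisible(path)
}

#' Read/write transfer parameters as a key=value config file
#'
#' Plain-text `key=value` lines covering every [transfer_params()] field.
#'
#' @param params A [transfer_params()] (for writing).
#' @param path File path.
#' @return `read_transfer_config()` returns a [transfer_params()];
#'   `write_transfer_config()` returns `path` invisibly.
#' @export
write_transfer_config <- function(params, path) {
  stopifnot(inherits(params, "transfer_params"))
  writeLines(sprintf("%s=%.10g", names(params), unlist(params)), path)
  invisible(path)
}

#' @rdname write_transfer_config
#' @export
read_transfer_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    as.numeric(vapply(kv, `[`, "", 2L)),
    trimws(vapply(kv, `[`, "", 1L))
  )
  do.call(transfer_params, as.list(vals))
}
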