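#' Stimulator communication-latency model
#'
#' Timing contract of the electrical stimulator: commands travel over a
#' serial (UART) link with a fixed delay, and the stimulator accepts an
#' update only after producing the stimulation pulse specified by the last
#' command, so the effective update rate is bounded by the pulse rate in
#' force (200 ms between update opportunities at the 5 Hz floor).
#'
#' @param uart_delay_ms One-way communication delay in milliseconds
#'   (default 20.6).
#' @return An object of class `"latency_model"`.
#' @export
latency_model <- function(uart_delay_ms = 20.6) {
  if (uart_delay_ms < 0) stop("uart_delay_ms must be >= 0")
  structure(list(uart_delay_ms = uart_delay_ms), class = "latency_model")
}

#' Worst-case command-to-effect latency
#'
#' Communication delay plus one full pulse interval at the lowest
#' stimulation frequency: `uart_delay_ms + 1000/min_freq_hz` ms. At the 5 Hz
#' floor with a 20.6 ms link this is 220.6 ms, the pipeline's worst-case
#' total processing time.
#'
#' @param latency A [latency_model()].
#' @param min_freq_hz Lowest stimulation frequency in Hz (>= 1).
#' @return Worst-case latency in milliseconds.
#' @examples
#' worst_case_latency(latency_model(20.6), 5)  # 220.6
#' @export
worst_case_latency <- function(latency = latency_model(), min_freq_hz) {
  if (any(min_freq_hz < 1)) stop("min_freq_hz must be >= 1")
  latency$uart_delay_ms + 1000 / min_freq_hz
}

#' Render stimulation commands into a pulse train
#'
#' Discrete-event simulation of the stimulator. Each command becomes
#' visible to the stimulator `uart_delay_ms` after its timestamp; while a
#' pulse interval is in force, newly visible commands wait (latest one
#' wins) and are adopted only when that interval completes with its pulse.
#' When idle, a newly visible active command is adopted immediately and its
#' first pulse fires at adoption. A deactivating command lets the already
#' scheduled pulse complete and then stops the train.
#'
#' Event times are kept as exact numbers (not sample-quantised) so pulse
#' counts are deterministic.
#'
#' @param commands A `"stim_trace"` (or data frame with columns `t_s`,
#'   `active`, `frequency_hz`, `amplitude_ma`, `pulse_width_us`),
#'   non-decreasing in `t_s`.
#' @param latency A [latency_model()].
#' @param duration_s Simulation horizon in seconds (pulses with onset
#'   `>= duration_s` are not emitted).
#' @return A data frame of class `"pulse_train"` with one row per pulse:
#'   `onset_s`, `frequency_hz` (rate in force from this pulse on, i.e.
#'   `diff(onset_s)` equals `1/frequency_hz` while the train stays active),
#'   `amplitude_ma`, `pulse_width_us`. Attribute `"adoptions"` logs every
#'   command adoption (`t_cmd_s`, `t_visible_s`, `t_adopt_s`, `active`,
#'   `frequency_hz`) for causality checks; attribute `"duration_s"` records
#'   the horizon.
#' @export
schedule <- function(commands, latency = latency_model(), duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s < 0) {
    stop("duration_s must be a single non-negative number")
  }
  cmd <- as.data.frame(commands)
  if (nrow(cmd) && is.unsorted(cmd$t_s)) {
    stop("commands must be non-decreasing in t_s")
  }
  uart_s <- latency$uart_delay_ms / 1000
  vis <- cmd$t_s + uart_s

  onsets <- numeric(0); freqs <- numeric(0)
  amps <- numeric(0); widths <- numeric(0)
  ad_cmd <- numeric(0); ad_vis <- numeric(0); ad_t <- numeric(0)
  ad_act <- logical(0); ad_f <- numeric(0)

  adopt <- function(j, t_adopt) {
    ad_cmd <<- c(ad_cmd, cmd$t_s[j]); ad_vis <<- c(ad_vis, vis[j])
    ad_t <<- c(ad_t, t_adopt); ad_act <<- c(ad_act, cmd$active[j])
    ad_f <<- c(ad_f, cmd$frequency_hz[j])
  }
  fire <- function(t, j) {
    onsets <<- c(onsets, t); freqs <<- c(freqs, cmd$frequency_hz[j])
    amps <<- c(amps, cmd$amplitude_ma[j]); widths <<- c(widths, cmd$pulse_width_us[j])
  }

  i <- 1L; n <- nrow(cmd)
  active <- FALSE; cur <- NA_integer_
  last_pulse <- -Inf  # time of the most recent produced pulse (update unlock)
  seg_start <- NA_real_; seg_k <- 0L  # pulses fired since last adoption:
                                      # event times are seg_start + k/f, so
                                      # intervals do not accumulate error

  while (TRUE) {
    if (!active) {
      if (i > n) break
      # idle: the next visible command is adopted as soon as it is visible
      # (but never before the last produced pulse); among commands visible
      # by then, the latest wins
      t_adopt <- max(vis[i], last_pulse)
      if (t_adopt >= duration_s) break
      j <- i
      while (j < n && vis[j + 1L] <= t_adopt) j <- j + 1L
      adopt(j, t_adopt)
      i <- j + 1L
      if (cmd$active[j] && !is.na(cmd$frequency_hz[j])) {
        active <- TRUE; cur <- j
        fire(t_adopt, j)           # first pulse fires at adoption
        last_pulse <- t_adopt
        seg_start <- t_adopt; seg_k <- 0L
      }
    } else {
      t_next <- seg_start + (seg_k + 1L) / cmd$frequency_hz[cur]
      if (t_next >= duration_s) break
      fire(t_next, cur)            # pulse per the command in force
      last_pulse <- t_next
      seg_k <- seg_k + 1L
      # the interval has completed: adopt the latest command visible by now
      if (i <= n && vis[i] <= t_next) {
        j <- i
        while (j < n && vis[j + 1L] <= t_next) j <- j + 1L
        adopt(j, t_next)
        i <- j + 1L
        if (cmd$active[j] && !is.na(cmd$frequency_hz[j])) {
          cur <- j
          seg_start <- t_next; seg_k <- 0L
          freqs[length(freqs)] <- cmd$frequency_hz[j]  # rate in force onwards
        } else {
          active <- FALSE; cur <- NA_integer_
        }
      }
    }
  }

  out <- data.frame(onset_s = onsets, frequency_hz = freqs,
                    amplitude_ma = amps, pulse_width_us = widths)
  structure(out, class = c("pulse_train", "data.frame"),
            adoptions = data.frame(t_cmd_s = ad_cmd, t_visible_s = ad_vis,
                                   t_adopt_s = ad_t, active = ad_act,
                                   frequency_hz = ad_f),
            duration_s = duration_s, latency = latency)
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses over %.3f s\n", nrow(x),
              attr(x, "duration_s")))
  NextMethod()
}

#' Plot a pulse train
#'
#' Pulse onsets as vertical ticks, with the per-pulse rate overlaid.
#'
#' @param x A `"pulse_train"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pulse_train <- function(x, ...) {
  graphics::plot(x$onset_s, x$frequency_hz, type = "s",
                 xlab = "time (s)", ylab = "pulse rate (Hz)", ...)
  graphics::rug(x$onset_s)
  invisible(x)
}

#' Sample the biphasic current waveform of a pulse train
#'
#' Renders the train as a piecewise-constant current trace: each pulse is a
#' cathodic phase of `-A` mA for `pulse_width_us`, immediately followed by
#' an anodic phase of `+A` mA of equal width (charge-balanced,
#' cathodic-first), zero elsewhere. The sampling rate must resolve each
#' phase with at least 2 samples.
#'
#' @param train A `"pulse_train"` from [schedule()].
#' @param rate_hz Rendering sample rate in Hz.
#' @param duration_s Trace length in seconds (default: the train's
#'   scheduling horizon).
#' @return Numeric vector of instantaneous current in mA.
#' @export
render_waveform <- function(train, rate_hz,
                            duration_s = attr(train, "duration_s")) {
  if (is.null(duration_s)) duration_s <- if (nrow(train)) max(train$onset_s) + 1e-3 else 0
  n <- ceiling(duration_s * rate_hz)
  trace <- numeric(n)
  if (!nrow(train)) return(trace)
  phase_n <- round(train$pulse_width_us * 1e-6 * rate_hz)
  if (any(phase_n < 2)) {
    stop("rate_hz too low to resolve the pulse width (need >= 2 samples per phase)")
  }
  start <- floor(train$onset_s * rate_hz) + 1
  for (k in seq_len(nrow(train))) {
    pn <- phase_n[k]
    i0 <- start[k]
    i1 <- min(i0 + pn - 1, n)
    i2 <- min(i0 + 2 * pn - 1, n)
    if (i0 <= n) trace[i0:i1] <- trace[i0:i1] - train$amplitude_ma[k]
    if (i0 + pn <= n) trace[(i0 + pn):i2] <- trace[(i0 + pn):i2] + train$amplitude_ma[k]
  }
  trace
}

#' Write a pulse log to CSV
#'
#' Columns: `onset_s, frequency_hz, amplitude_ma, pulse_width_us`.
#'
#' @param train A `"pulse_train"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(train, path) {
  utils::write.csv(as.data.frame(train), path, row.names = FALSE)
  invisible(path)
}
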