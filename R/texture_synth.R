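# seeded evaluation without disturbing the caller's RNG state
with_rng <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Synthetic texture profile
#'
#' Description of one surface texture's friction-sound signature in terms of
#' the median-frequency trajectory it should produce under the spectral
#' pipeline: a center trajectory over normalised stroke time, a narrowband
#' spread around it, an amplitude, and per-window jitter. Optionally a
#' bounded random walk replaces the deterministic trajectory (used for
#' irregular textures such as a string mesh).
#'
#' @param name Texture name.
#' @param center_trajectory Function mapping normalised stroke time
#'   `u in [0, 1]` (vectorised) to the target median frequency in Hz; values
#'   must stay within `[20, 3000]` Hz, the observed friction band.
#' @param bandwidth_hz Spectral spread of the narrowband noise around the
#'   center (default 40 Hz).
#' @param amplitude RMS level in ADC counts (default 3000).
#' @param jitter_hz Standard deviation of the per-window random perturbation
#'   of the center frequency (default 5 Hz).
#' @param walk Optional list `list(lo =, hi =, step_sd =)` describing a
#'   reflected random walk (Hz) that replaces `center_trajectory` at
#'   synthesis time.
#' @return An object of class `"texture_profile"`.
#' @export
texture_profile <- function(name, center_trajectory, bandwidth_hz = 40,
                            amplitude = 3000, jitter_hz = 5, walk = NULL) {
  stopifnot(is.function(center_trajectory))
  tv <- center_trajectory(seq(0, 1, length.out = 21))
  if (any(!is.finite(tv)) || any(tv < 20 | tv > 3000)) {
    stop("center_trajectory must stay within [20, 3000] Hz")
  }
  if (amplitude < 0 || amplitude > 20000) {
    stop("amplitude (RMS counts) must be within [0, 20000]")
  }
  structure(
    list(name = name, center_trajectory = center_trajectory,
         bandwidth_hz = bandwidth_hz, amplitude = amplitude,
         jitter_hz = jitter_hz, walk = walk),
    class = "texture_profile"
  )
}

#' Default texture profiles
#'
#' The four canonical friction-sound signatures the simulator reproduces:
#' a texture with a stable high median frequency (~200 Hz), one with a
#' stable low median frequency (~50 Hz), one that ramps up during the stroke
#' (100 to 350 Hz), and one that fluctuates (bounded random walk over
#' 50-250 Hz). By default the stable-high signature is assigned to felt and
#' the stable-low one to sponge; the assignment is configurable because the
#' two readings of the source material disagree (see the package vignette).
#'
#' `separation` linearly shrinks every profile toward a common 150 Hz flat
#' trajectory: 1 keeps the defaults, 0 makes all four textures identical.
#' It exists to probe how discrimination accuracy degrades as the acoustic
#' signatures collapse.
#'
#' @param separation Profile separation factor in `[0, 1]` (default 1).
#' @param assignment `"felt_high"` (default: felt ~200 Hz, sponge ~50 Hz) or
#'   `"sponge_high"` (swapped).
#' @return Named list of four [texture_profile()]s:
#'   felt, sponge, silicone, mesh.
#' @export
default_profiles <- function(separation = 1,
                             assignment = c("felt_high", "sponge_high")) {
  assignment <- match.arg(assignment)
  if (separation < 0 || separation > 1) stop("separation must be in [0, 1]")
  s <- separation
  anchor <- 150
  blend <- function(f) function(u) anchor + s * (f(u) - anchor)
  flat_high <- function(u) rep(200, length(u))
  flat_low  <- function(u) rep(50, length(u))
  ramp      <- function(u) 100 + 250 * u
  high_name <- if (assignment == "felt_high") "felt" else "sponge"
  low_name  <- if (assignment == "felt_high") "sponge" else "felt"
  profs <- list(
    texture_profile(high_name, blend(flat_high), jitter_hz = 6 * s + 1),
    texture_profile(low_name, blend(flat_low), bandwidth_hz = 40 - 10 * s,
                    jitter_hz = 3 * s + 1),
    texture_profile("silicone", blend(ramp), jitter_hz = 6 * s + 1),
    texture_profile("mesh", function(u) rep(anchor, length(u)),
                    jitter_hz = 6 * s + 1,
                    walk = list(lo = anchor - s * 100, hi = anchor + s * 100,
                                step_sd = 15 * s + 0.5))
  )
  names(profs) <- vapply(profs, `[[`, "", "name")
  profs[c("felt", "sponge", "silicone", "mesh")]
}

# --- measured-median calibration -------------------------------------------
# The analysis stage uses a rectangular window, whose magnitude-spectrum
# leakage tails fall off only as 1/distance. For a narrowband cluster the
# upper tail extends to Nyquist while the lower tail is truncated at the
# 20 Hz cut, so the measured median frequency sits above the band center
# (by ~6 Hz at 50 Hz, shrinking with frequency). The generator's contract is
# that the *pipeline-measured* median follows the profile trajectory, so the
# band center is pre-compensated: the expected excluded-bin magnitude
# spectrum of the tone cluster is modelled with Dirichlet kernels, its
# half-mass median computed per the pipeline convention, and the resulting
# center -> measured-median curve inverted. Curves are cached per geometry.

.calibration_cache <- new.env(parent = emptyenv())

expected_cluster_median <- function(center, bandwidth_hz, rate_hz, fft_size,
                                    highpass_hz, notch_hz) {
  n <- fft_size
  k <- 0:(n / 2)
  freqs <- k * rate_hz / n
  tones <- center + seq(-bandwidth_hz / 2, bandwidth_hz / 2,
                        length.out = 9)
  tones <- pmax(tones, 1)
  mag <- numeric(length(k))
  dirichlet <- function(x) {
    # |sin(pi n x) / (n sin(pi x))|, the rectangular-window leakage kernel
    s <- sin(pi * x)
    out <- abs(sin(pi * n * x) / (n * s))
    out[abs(s) < 1e-12] <- 1
    out
  }
  # random-phase tones add incoherently: combine leakage in quadrature
  for (f in tones) {
    mag <- mag + dirichlet(f / rate_hz - k / n)^2 +
      dirichlet(f / rate_hz + k / n)^2
  }
  mag <- sqrt(mag)
  mag[freqs < highpass_hz] <- 0
  mag[which.min(abs(freqs - notch_hz))] <- 0
  tot <- sum(mag)
  freqs[which(cumsum(mag) >= tot / 2)[1]]
}

# inverse calibration: target measured median -> band center to synthesise
calibrated_center <- function(target, bandwidth_hz, rate_hz = 6000,
                              fft_size = 2048, highpass_hz = 20,
                              notch_hz = 50) {
  key <- paste(bandwidth_hz, rate_hz, fft_size, highpass_hz, notch_hz,
               sep = "|")
  curve <- .calibration_cache[[key]]
  if (is.null(curve)) {
    centers <- seq(25, 600, by = 5)
    measured <- vapply(centers, expected_cluster_median, 0,
                       bandwidth_hz = bandwidth_hz, rate_hz = rate_hz,
                       fft_size = fft_size, highpass_hz = highpass_hz,
                       notch_hz = notch_hz)
    measured <- cummax(measured)  # enforce monotone for inversion
    curve <- list(centers = centers, measured = measured)
    .calibration_cache[[key]] <- curve
  }
  out <- stats::approx(curve$measured, curve$centers, xout = target,
                       rule = 2, ties = "ordered")$y
  # beyond the tabulated range the bias is negligible
  high <- target > max(curve$measured)
  out[high] <- target[high]
  pmax(out, 22)
}

# reflected random walk kept inside [lo, hi]
reflect_walk <- function(n, lo, hi, step_sd, start = NULL) {
  if (hi <= lo) return(rep((lo + hi) / 2, n))
  if (is.null(start)) start <- stats::runif(1, lo, hi)
  x <- start + c(0, cumsum(stats::rnorm(n - 1, 0, step_sd)))
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Synthesise one friction-sound stroke
#'
#' Generates narrowband noise whose instantaneous center frequency follows
#' the profile's trajectory across the stroke. The signal is an oscillator
#' bank: `n_components` cosines with fixed random frequency offsets drawn
#' uniformly within the bandwidth and random phases, all sweeping with the
#' trajectory (phase-continuous), plus per-window center jitter. A 50 ms
#' raised-cosine ramp at each end avoids onset clicks. The RMS amplitude is
#' set so that the spectral gate is comfortably exceeded throughout the
#' stroke (at the default 3000-count RMS the total retained magnitude is an
#' order of magnitude above the 300 mV threshold).
#'
#' @param profile A [texture_profile()].
#' @param duration_s Stroke duration in seconds (default 2).
#' @param rate_hz Sampling rate (default 6000).
#' @param seed Optional integer seed; when given, the stream is a pure
#'   function of `(profile, duration_s, rate_hz, seed)` and the caller's RNG
#'   state is untouched. With `seed = NULL` the ambient RNG stream is used.
#' @param n_components Number of oscillator-bank components (default 24).
#' @param scale_mv_per_count Passed through to the returned stream.
#' @return An [audio_stream()] of `round(duration_s * rate_hz)` samples.
#' @export
synth_stroke <- function(profile, duration_s = 2, rate_hz = 6000,
                         seed = NULL, n_components = 24,
                         scale_mv_per_count = 3300 / 32768) {
  stopifnot(inherits(profile, "texture_profile"))
  n <- round(duration_s * rate_hz)
  if (n < 1) stop("duration too short")
  with_rng(seed, function() {
    u <- (seq_len(n) - 0.5) / n
    center <- profile$center_trajectory(u)
    block <- 128L
    nblk <- ceiling(n / block)
    if (!is.null(profile$walk)) {
      wk <- profile$walk
      walk <- reflect_walk(nblk, wk$lo, wk$hi, wk$step_sd)
      center <- rep(walk, each = block)[seq_len(n)]
    }
    jit <- rep(stats::rnorm(nblk, 0, profile$jitter_hz),
               each = block)[seq_len(n)]
    target <- pmax(center + jit, 25)    # stay above the highpass cutoff
    inst <- calibrated_center(target, profile$bandwidth_hz, rate_hz)
    if (profile$amplitude == 0) {
      return(audio_stream(integer(n), rate_hz, scale_mv_per_count))
    }
    offs <- stats::runif(n_components, -profile$bandwidth_hz / 2,
                         profile$bandwidth_hz / 2)
    phases <- stats::runif(n_components, 0, 2 * pi)
    base_phase <- 2 * pi * cumsum(inst) / rate_hz
    t <- seq_len(n) / rate_hz
    x <- numeric(n)
    for (j in seq_len(n_components)) {
      x <- x + cos(phases[j] + base_phase + 2 * pi * offs[j] * t)
    }
    x <- x / stats::sd(x) * profile$amplitude
    # gentle edges: 50 ms raised-cosine fade in/out
    nf <- min(round(0.05 * rate_hz), n %/% 2)
    if (nf > 0) {
      ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nf) - 0.5) / nf)
      x[seq_len(nf)] <- x[seq_len(nf)] * ramp
      x[(n - nf + 1):n] <- x[(n - nf + 1):n] * rev(ramp)
    }
    audio_stream(pmin(pmax(round(x), -32768), 32767), rate_hz,
                 scale_mv_per_count)
  })
}

#' Synthesise a multi-stroke session with ground-truth labels
#'
#' Concatenates seeded strokes separated by silence according to an event
#' schedule and returns the audio together with per-analysis-window texture
#' labels (silence is labelled `"none"`). The evaluation-style pacing is one
#' stroke every 10 s.
#'
#' @param events Data frame with columns `texture`, `onset_s`, `duration_s`;
#'   strokes must not overlap.
#' @param profiles Named list of [texture_profile()]s covering every texture
#'   in `events` (default [default_profiles()]).
#' @param rate_hz Sampling rate (default 6000).
#' @param seed Integer seed; per-stroke sub-seeds are derived from it.
#' @param config [spectral_config()] used for label alignment.
#' @param tail_s Trailing silence after the last stroke (default 1 s).
#' @return List with elements `stream` (an [audio_stream()]) and `labels`
#'   (data frame `t_s`, `texture`: one row per analysis window, stamped at
#'   window end, labelled by the texture covering the window center).
#' @export
synth_session <- function(events, profiles = default_profiles(),
                          rate_hz = 6000, seed = 1,
                          config = spectral_config(), tail_s = 1) {
  stopifnot(is.data.frame(events),
            all(c("texture", "onset_s", "duration_s") %in% names(events)))
  if (nrow(events) > 1) {
    o <- order(events$onset_s)
    ev <- events[o, ]
    ends <- ev$onset_s + ev$duration_s
    if (any(ends[-nrow(ev)] > ev$onset_s[-1] + 1e-12)) {
      stop("stroke events overlap")
    }
  }
  total_s <- if (nrow(events)) max(events$onset_s + events$duration_s) + tail_s
             else tail_s
  n <- round(total_s * rate_hz)
  x <- integer(n)
  stroke_seeds <- with_rng(seed, function() {
    sample.int(.Machine$integer.max, max(nrow(events), 1))
  })
  for (k in seq_len(nrow(events))) {
    tex <- as.character(events$texture[k])
    if (!tex %in% names(profiles)) stop("no profile for texture: ", tex)
    s <- synth_stroke(profiles[[tex]], events$duration_s[k], rate_hz,
                      seed = stroke_seeds[k])
    i0 <- round(events$onset_s[k] * rate_hz) + 1L
    i1 <- min(i0 + length(s$samples) - 1L, n)
    x[i0:i1] <- s$samples[seq_len(i1 - i0 + 1L)]
  }
  stream <- audio_stream(x, rate_hz)
  nwin <- max((n - config$fft_size) %/% config$hop + 1L, 0L)
  t_end <- (config$fft_size + (seq_len(nwin) - 1L) * config$hop) / rate_hz
  t_center <- t_end - config$fft_size / (2 * rate_hz)
  lab <- rep("none", nwin)
  for (k in seq_len(nrow(events))) {
    inside <- t_center >= events$onset_s[k] &
      t_center <= events$onset_s[k] + events$duration_s[k]
    lab[inside] <- as.character(events$texture[k])
  }
  list(stream = stream, labels = data.frame(t_s = t_end, texture = lab))
}

#' Evenly paced stroke schedule
#'
#' Helper building an `events` data frame for [synth_session()]: each
#' texture repeated `cycles` times in a seeded random order, one stroke
#' every `cadence_s` seconds (default 10 s, the paced-evaluation cue
#' interval), with optional +/-20% seeded duration jitter.
#'
#' @param textures Character vector of texture names.
#' @param cycles Strokes per texture.
#' @param cadence_s Inter-onset interval in seconds (default 10).
#' @param duration_s Nominal stroke duration (default 2 s).
#' @param duration_jitter Relative half-range of the uniform duration
#'   jitter (default 0.2).
#' @param seed Integer seed.
#' @return Data frame with columns `texture`, `onset_s`, `duration_s`.
#' @export
stroke_schedule <- function(textures = c("felt", "sponge", "silicone", "mesh"),
                            cycles = 20, cadence_s = 10, duration_s = 2,
                            duration_jitter = 0.2, seed = 1) {
  n <- length(textures) * cycles
  with_rng(seed, function() {
    data.frame(
      texture = sample(rep(textures, cycles)),
      onset_s = (seq_len(n) - 1) * cadence_s,
      duration_s = duration_s * stats::runif(n, 1 - duration_jitter,
                                             1 + duration_jitter)
    )
  })
}

#' Write session labels to CSV
#'
#' Columns: `t_s, texture`.
#'
#' @param labels The `labels` element of a [synth_session()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' Stroke-consistency report
#'
#' Reproduces the paced-evaluation consistency analysis: per-stroke
#' median-frequency traces are restricted to gated-on windows, normalised to
#' a common `[0, 1]` stroke-time axis, and summarised per texture by the
#' pointwise median and the 25%/75% quartile band, together with the
#' distribution of gated stroke durations.
#'
#' @param traces List of `"feature_trace"` objects, one per stroke.
#' @param textures Character vector: texture of each trace (>= 2 strokes per
#'   texture).
#' @param gate_threshold_mv Gate threshold separating stroke from silence
#'   (default 300 mV).
#' @param n_grid Points on the normalised time axis (default 50).
#' @return An object of class `"consistency_report"`: per texture a
#'   `3 x n_grid` matrix of the 25%/50%/75% quantile curves, sorted gated
#'   durations, and the stroke count. Textures are stored in alphabetical
#'   order so the report is invariant to input order.
#' @export
consistency_report <- function(traces, textures, gate_threshold_mv = 300,
                               n_grid = 50) {
  stopifnot(length(traces) == length(textures))
  textures <- as.character(textures)
  grid <- seq(0, 1, length.out = n_grid)
  tex_names <- sort(unique(textures))
  bands <- list(); durations <- list(); n_strokes <- integer(0)
  for (tex in tex_names) {
    idx <- which(textures == tex)
    if (length(idx) < 2) stop("need >= 2 strokes per texture (", tex, ")")
    rows <- matrix(NA_real_, nrow = length(idx), ncol = n_grid)
    durs <- numeric(length(idx))
    for (r in seq_along(idx)) {
      tr <- traces[[idx[r]]]
      on_idx <- which(tr$total_mag_mv > gate_threshold_mv &
                        !is.na(tr$median_hz))
      if (length(on_idx) < 2) {
        durs[r] <- 0
        next
      }
      tt <- tr$t_s[on_idx]; mm <- tr$median_hz[on_idx]
      durs[r] <- max(tt) - min(tt)
      uu <- (tt - min(tt)) / (max(tt) - min(tt))
      rows[r, ] <- stats::approx(uu, mm, xout = grid, rule = 2,
                                 ties = mean)$y
    }
    keep <- stats::complete.cases(rows)
    bands[[tex]] <- apply(rows[keep, , drop = FALSE], 2, stats::quantile,
                          probs = c(0.25, 0.5, 0.75), names = FALSE)
    durations[[tex]] <- sort(durs)
    n_strokes[tex] <- length(idx)
  }
  structure(
    list(grid = grid, textures = tex_names, bands = bands,
         durations = durations, n_strokes = n_strokes),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report>\n")
  for (tex in x$textures) {
    b <- x$bands[[tex]]
    mid <- ceiling(ncol(b) / 2)
    cat(sprintf(
      "  %-10s %d strokes; mid-stroke median %.0f Hz (IQR %.0f-%.0f); median gated duration %.2f s\n",
      tex, x$n_strokes[[tex]], b[2, mid], b[1, mid], b[3, mid],
      stats::median(x$durations[[tex]])))
  }
  invisible(x)
}

#' Plot a consistency report
#'
#' One panel per texture: pointwise median trace with the 25-75% quartile
#' band over normalised stroke time.
#'
#' @param x A `"consistency_report"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.consistency_report <- function(x, ...) {
  k <- length(x$textures)
  op <- graphics::par(mfrow = c(ceiling(k / 2), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ylim <- range(unlist(x$bands))
  for (tex in x$textures) {
    b <- x$bands[[tex]]
    graphics::plot(x$grid, b[2, ], type = "n", ylim = ylim,
                   xlab = "normalised stroke time",
                   ylab = "median freq (Hz)", main = tex, ...)
    graphics::polygon(c(x$grid, rev(x$grid)), c(b[1, ], rev(b[3, ])),
                      col = grDevices::grey(0.85), border = NA)
    graphics::lines(x$grid, b[2, ], lwd = 2)
  }
  invisible(x)
}
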