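#' Discrimination-protocol specification
#'
#' Structure of the three-phase texture-discrimination protocol: a training
#' phase in which the observer sees the true texture alongside its
#' stimulation trace, a with-feedback phase in which the true texture is
#' revealed after each response, and a without-feedback phase with frozen
#' templates. Each phase presents every texture `cycles_per_texture` times
#' in a seeded random order (4 x 20 = 80 trials per phase at defaults), and
#' up to `max_extra_repeats` extra presentations of the same texture may be
#' requested per trial.
#'
#' @param textures Character vector of 4 texture names.
#' @param cycles_per_texture Presentations of each texture per phase
#'   (default 20).
#' @param phases Ordered subset of
#'   `c("training", "with_feedback", "without_feedback")`.
#' @param max_extra_repeats Extra presentations allowed per trial
#'   (default 2).
#' @param seed Integer seed governing stroke synthesis, trial order and any
#'   observer randomness.
#' @return An object of class `"protocol_spec"`.
#' @export
protocol_spec <- function(textures = c("felt", "sponge", "silicone", "mesh"),
                          cycles_per_texture = 20,
                          phases = c("training", "with_feedback",
                                     "without_feedback"),
                          max_extra_repeats = 2, seed = 1) {
  all_phases <- c("training", "with_feedback", "without_feedback")
  if (!all(phases %in% all_phases)) stop("unknown phase name")
  if (is.unsorted(match(phases, all_phases))) {
    stop("phases must keep the order training, with_feedback, without_feedback")
  }
  if (length(textures) != length(unique(textures))) {
    stop("textures must be distinct")
  }
  if (cycles_per_texture < 1) stop("cycles_per_texture must be >= 1")
  if (max_extra_repeats < 0) stop("max_extra_repeats must be >= 0")
  structure(
    list(textures = as.character(textures),
         cycles_per_texture = as.integer(cycles_per_texture),
         phases = phases, max_extra_repeats = as.integer(max_extra_repeats),
         seed = as.integer(seed)),
    class = "protocol_spec"
  )
}

#' Simulated observers
#'
#' Stand-ins for the human participant, who perceives only the stimulation
#' frequency trace. `template_observer()` is the default: it learns one
#' summary template per texture during training (median stimulation
#' frequency, trend slope over normalised stroke time, interquartile
#' spread), classifies by nearest template in feature-scaled Euclidean
#' distance, requests a repeat when the margin between the best and
#' second-best match falls below `confidence_threshold`, and (during the
#' with-feedback phase) nudges the true texture's template toward the
#' observed trace with weight `learning_rate`. `oracle_observer()` always
#' answers the truth (an upper bound / harness check); `random_observer()`
#' guesses uniformly (the 25% chance-level control).
#'
#' The repeat-request rule is a modelling stand-in: how human participants
#' decided to ask for repetitions is unknowable, so a confidence-margin
#' trigger is used.
#'
#' @param confidence_threshold Margin below which a repeat is requested
#'   (default 0.2; the margin is `(d2 - d1)/(d1 + d2)` over template
#'   distances, in `[0, 1]`).
#' @param learning_rate Template update weight during the with-feedback
#'   phase (default 0.1; 0 disables updating).
#' @return An object of class `"texture_observer"`.
#' @export
template_observer <- function(confidence_threshold = 0.2,
                              learning_rate = 0.1) {
  structure(list(type = "template",
                 confidence_threshold = confidence_threshold,
                 learning_rate = learning_rate),
            class = "texture_observer")
}

#' @rdname template_observer
#' @export
oracle_observer <- function() {
  structure(list(type = "oracle"), class = "texture_observer")
}

#' @rdname template_observer
#' @export
random_observer <- function() {
  structure(list(type = "random"), class = "texture_observer")
}

#' Summary signature of a stimulation trace
#'
#' The three statistics the template observer perceives in a stroke's
#' stimulation-frequency trace: the median active frequency (level, Hz),
#' the least-squares slope of frequency against normalised stroke time
#' (trend, Hz per stroke), and the interquartile range of the active
#' frequencies (spread, Hz). Returns `NULL` for a trace with no active
#' commands (fully gated off).
#'
#' @param stim A `"stim_trace"` from [transduce_trace()].
#' @return Named numeric vector `c(level, slope, spread)`, or `NULL`.
#' @export
trace_signature <- function(stim) {
  act <- which(stim$active & !is.na(stim$frequency_hz))
  if (!length(act)) return(NULL)
  f <- stim$frequency_hz[act]
  t <- stim$t_s[act]
  span <- max(t) - min(t)
  u <- if (span > 0) (t - min(t)) / span else rep(0.5, length(t))
  slope <- if (length(f) >= 2 && stats::var(u) > 0) {
    stats::cov(u, f) / stats::var(u)
  } else 0
  c(level = stats::median(f), slope = slope, spread = stats::IQR(f))
}

# nearest-template classification; scale = per-feature spread across templates
classify_signature <- function(sig, templates, scale) {
  d <- apply(templates, 1, function(tmpl) {
    sqrt(sum(((sig - tmpl) / scale)^2))
  })
  ord <- order(d)
  conf <- (d[ord[2]] - d[ord[1]]) / (d[ord[1]] + d[ord[2]] + 1e-9)
  list(texture = rownames(templates)[ord[1]], confidence = conf)
}

template_scale <- function(templates) {
  pmax(apply(templates, 2, stats::sd), 1e-3)
}

#' Run the three-phase discrimination protocol on synthetic strokes
#'
#' Simulates the full experiment for one "participant" (one seed): strokes
#' are synthesised per trial from the texture profiles, pushed through the
#' spectral and transduction stages, and their stimulation traces are judged
#' by the observer. The training phase fits per-texture templates from
#' labelled traces; the with-feedback phase reveals the truth after each
#' response (the template observer may update its templates); the
#' without-feedback phase runs with templates frozen. All randomness derives
#' from `spec$seed`, making the run bit-reproducible.
#'
#' @param spec A [protocol_spec()].
#' @param observer A [template_observer()], [oracle_observer()] or
#'   [random_observer()].
#' @param profiles Named list of [texture_profile()]s (default
#'   [default_profiles()]).
#' @param params A [transfer_params()].
#' @param amplitude_ma Stimulation amplitude (participant comfort level) in
#'   mA on the 0.1 mA grid.
#' @param stroke_duration_s Nominal stroke duration (default 2 s; each
#'   stroke gets +/-20% seeded duration jitter, mimicking manual stroking).
#' @param config A [spectral_config()].
#' @return An object of class `"texture_protocol"`: list with `records`
#'   (data frame `phase`, `true`, `response`, `n_presentations`, `correct`),
#'   `confusion` (one matrix per response phase from [confusion_matrix()]),
#'   `templates` (post-training and final), and `spec`.
#' @export
run_protocol <- function(spec = protocol_spec(),
                         observer = template_observer(),
                         profiles = default_profiles(),
                         params = transfer_params(),
                         amplitude_ma = 4.0, stroke_duration_s = 2,
                         config = spectral_config()) {
  stopifnot(inherits(spec, "protocol_spec"),
            inherits(observer, "texture_observer"))
  missing_prof <- setdiff(spec$textures, names(profiles))
  if (length(missing_prof)) {
    stop("no profile for texture(s): ", paste(missing_prof, collapse = ", "))
  }
  needs_templates <- identical(observer$type, "template")
  if (needs_templates && !"training" %in% spec$phases) {
    stop("the template observer requires a training phase")
  }

  with_rng(spec$seed, function() {
    textures <- spec$textures
    present <- function(texture) {
      dur <- stroke_duration_s * stats::runif(1, 0.8, 1.2)
      stream <- synth_stroke(profiles[[texture]], dur,
                             rate_hz = config$rate_hz)
      st <- transduce_trace(feature_trace(stream, config), params,
                            amplitude_ma)
      trace_signature(st)
    }

    templates <- NULL; scale <- NULL
    templates_post_training <- NULL
    records <- list()

    if ("training" %in% spec$phases) {
      sig_by_tex <- lapply(textures, function(tex) {
        sigs <- replicate(spec$cycles_per_texture, present(tex),
                          simplify = FALSE)
        sigs <- sigs[!vapply(sigs, is.null, TRUE)]
        if (!length(sigs)) stop("training produced no gated trace for ", tex)
        colMeans(do.call(rbind, sigs))
      })
      templates <- do.call(rbind, sig_by_tex)
      rownames(templates) <- textures
      scale <- template_scale(templates)
      templates_post_training <- templates
      records[["training"]] <- data.frame(
        phase = "training",
        true = rep(textures, each = spec$cycles_per_texture),
        response = rep(textures, each = spec$cycles_per_texture),
        n_presentations = 1L, correct = TRUE
      )
    }

    run_phase <- function(phase) {
      order_tex <- sample(rep(textures, spec$cycles_per_texture))
      n <- length(order_tex)
      resp <- character(n); npres <- integer(n)
      for (k in seq_len(n)) {
        truth <- order_tex[k]
        sigs <- list()
        answer <- NA_character_
        first_sig <- NULL
        pres <- 0L
        repeat {
          pres <- pres + 1L
          sig <- present(truth)
          if (!is.null(sig)) {
            sigs[[length(sigs) + 1L]] <- sig
            if (is.null(first_sig)) first_sig <- sig
          }
          decided <- FALSE
          if (observer$type == "oracle") {
            answer <- truth; decided <- TRUE
          } else if (observer$type == "random") {
            answer <- sample(textures, 1); decided <- TRUE
          } else if (length(sigs)) {
            agg <- colMeans(do.call(rbind, sigs))
            cl <- classify_signature(agg, templates, scale)
            answer <- cl$texture
            decided <- cl$confidence >= observer$confidence_threshold
          }
          if (decided || pres > spec$max_extra_repeats) break
        }
        if (is.na(answer)) answer <- sample(textures, 1)  # total abstention
        resp[k] <- answer; npres[k] <- pres
        if (phase == "with_feedback" && observer$type == "template" &&
            observer$learning_rate > 0 && !is.null(first_sig)) {
          lr <- observer$learning_rate
          templates[truth, ] <<- (1 - lr) * templates[truth, ] +
            lr * first_sig
          scale <<- template_scale(templates)
        }
      }
      data.frame(phase = phase, true = order_tex, response = resp,
                 n_presentations = npres, correct = resp == order_tex)
    }

    for (phase in intersect(c("with_feedback", "without_feedback"),
                            spec$phases)) {
      records[[phase]] <- run_phase(phase)
    }

    rec <- do.call(rbind, records)
    rownames(rec) <- NULL
    confusion <- lapply(
      intersect(c("with_feedback", "without_feedback"), spec$phases),
      function(ph) confusion_matrix(rec, ph, textures)
    )
    names(confusion) <- intersect(c("with_feedback", "without_feedback"),
                                  spec$phases)
    structure(
      list(records = rec, confusion = confusion,
           templates = list(post_training = templates_post_training,
                            final = templates),
           spec = spec),
      class = "texture_protocol"
    )
  })
}

#' Confusion matrix of a response phase
#'
#' Counts of responses by true texture: rows are the presented texture,
#' columns the response. Row sums equal `cycles_per_texture` by
#' construction.
#'
#' @param records A protocol `records` data frame.
#' @param phase Phase to tabulate (default `"without_feedback"`).
#' @param textures Texture order for the matrix (default: sorted unique
#'   true textures).
#' @return Integer matrix with textures as row and column names.
#' @export
confusion_matrix <- function(records, phase = "without_feedback",
                             textures = sort(unique(records$true))) {
  r <- records[records$phase == phase, ]
  unknown <- setdiff(unique(r$response), textures)
  if (length(unknown)) {
    stop("observer returned unknown texture(s): ",
         paste(unknown, collapse = ", "))
  }
  m <- table(factor(r$true, levels = textures),
             factor(r$response, levels = textures))
  m <- matrix(as.integer(m), nrow = length(textures),
              dimnames = list(true = textures, response = textures))
  m
}

#' @export
print.texture_protocol <- function(x, ...) {
  cat(sprintf("<texture_protocol> seed %d, phases: %s\n", x$spec$seed,
              paste(x$spec$phases, collapse = ", ")))
  for (ph in names(x$confusion)) {
    r <- x$records[x$records$phase == ph, ]
    cat(sprintf("  %-17s accuracy %.1f%%, mean presentations %.2f\n", ph,
                100 * mean(r$correct), mean(r$n_presentations)))
  }
  invisible(x)
}

#' Plot protocol confusion matrices
#'
#' Heatmap of row-normalised confusion percentages per response phase.
#'
#' @param x A `"texture_protocol"`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.texture_protocol <- function(x, ...) {
  k <- length(x$confusion)
  op <- graphics::par(mfrow = c(1, k), mar = c(5, 5, 3, 1))
  on.exit(graphics::par(op))
  for (ph in names(x$confusion)) {
    m <- x$confusion[[ph]]
    pct <- 100 * m / rowSums(m)
    nt <- nrow(m)
    graphics::image(seq_len(nt), seq_len(nt), t(pct[nt:1, ]),
                    col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE),
                    axes = FALSE, xlab = "response", ylab = "true",
                    main = ph, zlim = c(0, 100))
    graphics::axis(1, seq_len(nt), colnames(m), las = 2)
    graphics::axis(2, seq_len(nt), rev(rownames(m)), las = 2)
    for (i in seq_len(nt)) for (j in seq_len(nt)) {
      graphics::text(j, nt + 1 - i, sprintf("%.0f", pct[i, j]),
                     col = if (pct[i, j] > 50) "white" else "black")
    }
  }
  invisible(x)
}

#' Run the protocol over several seeds
#'
#' Repeats [run_protocol()] with independent sub-seeds derived from `seed`,
#' modelling a cohort of simulated participants: inter-participant variance
#' maps onto seed variance.
#'
#' @param n_runs Number of simulated participants (default 10).
#' @param seed Master integer seed.
#' @param ... Passed to [run_protocol()] (`observer`, `profiles`, ...).
#' @param phases Phases to run (default all three).
#' @param cycles_per_texture Presentations per texture per phase.
#' @param textures Texture names.
#' @return List of class `"texture_study"`: the `"texture_protocol"` runs,
#'   plus the derived seeds.
#' @export
run_discrimination_study <- function(n_runs = 10, seed = 1,
                                     phases = c("training", "with_feedback",
                                                "without_feedback"),
                                     cycles_per_texture = 20,
                                     textures = c("felt", "sponge",
                                                  "silicone", "mesh"),
                                     ...) {
  run_seeds <- with_rng(seed, function() {
    sample.int(.Machine$integer.max, n_runs)
  })
  runs <- lapply(run_seeds, function(s) {
    run_protocol(protocol_spec(textures = textures,
                               cycles_per_texture = cycles_per_texture,
                               phases = phases, seed = s), ...)
  })
  structure(list(runs = runs, seeds = run_seeds), class = "texture_study")
}

#' @export
print.texture_study <- function(x, ...) {
  cat(sprintf("<texture_study> %d simulated participants\n", length(x$runs)))
  print(accuracy_summary(x))
  invisible(x)
}

#' Accuracy summary across simulated participants
#'
#' Per-texture and overall accuracy statistics over the runs of a study
#' (median and 25%/75% quartiles of per-run accuracy in percent, plus the
#' mean number of presentations per trial), for one response phase.
#' Accuracies are summarised by medians because per-participant accuracy is
#' not normally distributed.
#'
#' @param study A `"texture_study"` from [run_discrimination_study()], or a
#'   plain list of `"texture_protocol"` runs.
#' @param phase Response phase to summarise (default `"without_feedback"`).
#' @return Data frame with one row per texture plus an `"overall"` row:
#'   columns `texture`, `median_acc_pct`, `q25_pct`, `q75_pct`,
#'   `mean_presentations`, `n_runs`.
#' @export
accuracy_summary <- function(study, phase = "without_feedback") {
  runs <- if (inherits(study, "texture_study")) study$runs else study
  recs <- lapply(runs, function(r) {
    rr <- r$records
    rr[rr$phase == phase, ]
  })
  if (!all(vapply(recs, nrow, 0L) > 0)) {
    stop("phase ", phase, " not present in every run")
  }
  textures <- sort(unique(recs[[1]]$true))
  per_run_acc <- function(sel) {
    vapply(recs, function(r) {
      r <- r[sel(r), ]
      100 * mean(r$correct)
    }, 0)
  }
  per_run_pres <- function(sel) {
    vapply(recs, function(r) {
      r <- r[sel(r), ]
      mean(r$n_presentations)
    }, 0)
  }
  rows <- lapply(c(textures, "overall"), function(tex) {
    sel <- if (tex == "overall") function(r) rep(TRUE, nrow(r))
           else function(r) r$true == tex
    acc <- per_run_acc(sel)
    q <- stats::quantile(acc, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(texture = tex, median_acc_pct = q[2], q25_pct = q[1],
               q75_pct = q[3], mean_presentations = mean(per_run_pres(sel)),
               n_runs = length(recs))
  })
  do.call(rbind, rows)
}

#' Write protocol records to CSV
#'
#' Columns: `phase, true, response, n_presentations, correct`.
#'
#' @param result A `"texture_protocol"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(result, path) {
  utils::write.csv(result$records, path, row.names = FALSE)
  invisible(path)
}
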