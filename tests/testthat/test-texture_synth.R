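# seeded synthetic friction-sound strokes and sessions

test_that("stroke synthesis is a pure function of its seed", {
  p <- default_profiles()$mesh
  a <- synth_stroke(p, 1.5, seed = 100)
  b <- synth_stroke(p, 1.5, seed = 100)
  c <- synth_stroke(p, 1.5, seed = 101)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("seeded synthesis leaves the caller's RNG stream untouched", {
  set.seed(1)
  r1 <- runif(1)
  set.seed(1)
  invisible(synth_stroke(default_profiles()$felt, 0.5, seed = 9))
  expect_identical(runif(1), r1)
})

test_that("profile trajectories are reproduced by the pipeline", {
  profs <- default_profiles()
  ft_felt <- feature_trace(synth_stroke(profs$felt, 2, seed = 21))
  expect_lt(abs(mid_stroke_median(ft_felt) - 200), 0.15 * 200)

  ft_sil <- feature_trace(synth_stroke(profs$silicone, 2, seed = 22))
  on <- ft_sil$total_mag_mv > 300
  fit <- lm(ft_sil$median_hz[on] ~ ft_sil$t_s[on])
  expect_gt(coef(fit)[2], 0)  # ramps up during the stroke

  silent <- texture_profile("off", function(u) rep(200, length(u)),
                            amplitude = 0)
  ft0 <- feature_trace(synth_stroke(silent, 2, seed = 23))
  expect_true(all(ft0$total_mag_mv == 0))
})

test_that("mid-stroke medians land within 15% of the target trajectory", {
  profs <- default_profiles()
  targets <- c(felt = 200, sponge = 50, silicone = 225)
  for (tex in names(targets)) {
    hits <- vapply(1:50, function(s) {
      ft <- feature_trace(synth_stroke(profs[[tex]], 2, seed = 3000 + s))
      abs(mid_stroke_median(ft) - targets[[tex]]) <= 0.15 * targets[[tex]]
    }, TRUE)
    expect_gte(mean(hits), 0.9)
  }
})

test_that("stable-high and stable-low textures are separated by >= 100 Hz", {
  profs <- default_profiles()
  hi <- mid_stroke_median(feature_trace(synth_stroke(profs$felt, 2,
                                                     seed = 31)))
  lo <- mid_stroke_median(feature_trace(synth_stroke(profs$sponge, 2,
                                                     seed = 31)))
  expect_gte(hi - lo, 100)
})

test_that("the texture-to-signature assignment is configurable", {
  swapped <- default_profiles(assignment = "sponge_high")
  hi <- mid_stroke_median(feature_trace(synth_stroke(swapped$sponge, 2,
                                                     seed = 32)))
  lo <- mid_stroke_median(feature_trace(synth_stroke(swapped$felt, 2,
                                                     seed = 32)))
  expect_gt(hi, 150)
  expect_lt(lo, 100)
})

test_that("sessions concatenate strokes with aligned labels", {
  # empty schedule: pure silence, all labels "none"
  empty <- synth_session(data.frame(texture = character(),
                                    onset_s = numeric(),
                                    duration_s = numeric()), seed = 4)
  expect_true(all(empty$stream$samples == 0))
  expect_true(all(empty$labels$texture == "none"))

  ev <- data.frame(texture = c("felt", "sponge", "silicone", "mesh"),
                   onset_s = c(0, 10, 20, 30), duration_s = 2)
  ses <- synth_session(ev, seed = 4)
  ft <- feature_trace(ses$stream)
  expect_equal(nrow(ft), nrow(ses$labels))
  # gate-on fraction ~ stroke time / session time
  frac <- mean(ft$total_mag_mv > 300)
  expect_lt(abs(frac - 8 / (32 + 1)), 0.1)
  # labelled windows carry signal, "none" windows are quiet
  expect_gt(mean(ft$total_mag_mv[ses$labels$texture != "none"] > 300), 0.8)
  expect_lt(mean(ft$total_mag_mv[ses$labels$texture == "none"] > 300), 0.1)

  # determinism and overlap rejection
  ses2 <- synth_session(ev, seed = 4)
  expect_identical(ses$stream$samples, ses2$stream$samples)
  bad <- data.frame(texture = c("felt", "sponge"), onset_s = c(0, 1),
                    duration_s = 2)
  expect_error(synth_session(bad, seed = 4), "overlap")
})

test_that("silence never triggers the gate at the default threshold", {
  ft <- feature_trace(audio_stream(integer(30000)))
  expect_true(all(!gate(ft$total_mag_mv)))
})

test_that("consistency reports summarise quartile bands per texture", {
  profs <- default_profiles()
  # identical strokes: zero-width quartile band
  same <- replicate(5, feature_trace(synth_stroke(profs$felt, 1.5,
                                                  seed = 77)),
                    simplify = FALSE)
  rep0 <- consistency_report(same, rep("felt", 5))
  expect_equal(rep0$bands$felt[1, ], rep0$bands$felt[3, ])

  # felt vs sponge: non-overlapping bands at mid-stroke
  traces <- list(); tex <- character()
  for (s in 1:8) {
    traces[[length(traces) + 1]] <-
      feature_trace(synth_stroke(profs$felt, 1.5, seed = 200 + s))
    tex <- c(tex, "felt")
    traces[[length(traces) + 1]] <-
      feature_trace(synth_stroke(profs$sponge, 1.5, seed = 300 + s))
    tex <- c(tex, "sponge")
  }
  rp <- consistency_report(traces, tex)
  mid <- ceiling(length(rp$grid) / 2)
  expect_gt(rp$bands$felt[1, mid], rp$bands$sponge[3, mid])

  # shuffled stroke order gives an identical report
  set.seed(5)
  perm <- sample(seq_along(traces))
  rp2 <- consistency_report(traces[perm], tex[perm])
  expect_identical(rp, rp2)

  expect_error(consistency_report(traces[1], "felt"), ">= 2 strokes")
})
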