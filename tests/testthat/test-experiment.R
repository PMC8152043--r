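# three-phase discrimination protocol with simulated observers

test_that("protocol structure conserves trial counts", {
  spec <- protocol_spec(seed = 11)
  expect_equal(length(spec$textures) * spec$cycles_per_texture, 80)
  res <- run_protocol(protocol_spec(seed = 11, cycles_per_texture = 5,
                                    phases = c("training",
                                               "without_feedback")),
                      observer = oracle_observer(), stroke_duration_s = 0.6)
  r <- res$records
  for (ph in unique(r$phase)) {
    expect_equal(sum(r$phase == ph), 20)
    expect_equal(as.vector(table(r$true[r$phase == ph])), rep(5, 4))
  }
  cm <- res$confusion$without_feedback
  expect_equal(unname(rowSums(cm)), rep(5, 4))
  expect_true(all(cm >= 0))
})

test_that("an oracle observer produces an identity confusion matrix", {
  res <- run_protocol(protocol_spec(seed = 12, cycles_per_texture = 4,
                                    phases = c("training", "with_feedback",
                                               "without_feedback")),
                      observer = oracle_observer(), stroke_duration_s = 0.6)
  for (cm in res$confusion) {
    expect_equal(unname(cm), diag(4L) * 4L)
  }
  expect_true(all(res$records$correct))
  expect_true(all(res$records$n_presentations == 1))
})

test_that("a uniform-random observer sits at the 25% chance level", {
  runs <- lapply(1:3, function(s) {
    run_protocol(protocol_spec(seed = 400 + s,
                               phases = "without_feedback"),
                 observer = random_observer(), stroke_duration_s = 0.5)
  })
  rec <- do.call(rbind, lapply(runs, `[[`, "records"))
  for (tex in unique(rec$true)) {
    n <- sum(rec$true == tex)
    k <- sum(rec$correct[rec$true == tex])
    # 99% binomial band around chance at n = 20 x 3
    lo <- qbinom(0.005, n, 0.25)
    hi <- qbinom(0.995, n, 0.25)
    expect_gte(k, lo)
    expect_lte(k, hi)
  }
})

test_that("the template observer discriminates well above chance", {
  res <- run_protocol(protocol_spec(seed = 13,
                                    phases = c("training",
                                               "without_feedback")),
                      stroke_duration_s = 1.2)
  r <- res$records[res$records$phase == "without_feedback", ]
  # binomial test against 25% chance at n = 80
  pval <- binom.test(sum(r$correct), nrow(r), 0.25,
                     alternative = "greater")$p.value
  expect_lt(pval, 1e-6)
  expect_true(all(r$n_presentations <= 3))
})

test_that("templates never update during the without-feedback phase", {
  res <- run_protocol(protocol_spec(seed = 14, cycles_per_texture = 5,
                                    phases = c("training",
                                               "without_feedback")),
                      stroke_duration_s = 0.8)
  expect_identical(res$templates$post_training, res$templates$final)
  # ... while the with-feedback phase may adapt them
  res2 <- run_protocol(protocol_spec(seed = 14, cycles_per_texture = 5),
                       stroke_duration_s = 0.8)
  expect_false(identical(res2$templates$post_training,
                         res2$templates$final))
})

test_that("a fixed seed makes the whole experiment bit-reproducible", {
  a <- run_protocol(protocol_spec(seed = 15, cycles_per_texture = 3,
                                  phases = c("training",
                                             "without_feedback")),
                    stroke_duration_s = 0.6)
  b <- run_protocol(protocol_spec(seed = 15, cycles_per_texture = 3,
                                  phases = c("training",
                                             "without_feedback")),
                    stroke_duration_s = 0.6)
  expect_identical(a$records, b$records)
  expect_identical(a$templates, b$templates)
})

test_that("unknown responses are rejected when tabulated", {
  rec <- data.frame(phase = "without_feedback",
                    true = c("felt", "mesh"),
                    response = c("felt", "velvet"),
                    n_presentations = 1, correct = c(TRUE, FALSE))
  expect_error(confusion_matrix(rec, textures = c("felt", "mesh")),
               "unknown")
})

test_that("accuracy summaries match direct percentile computation", {
  fake_run <- function(acc_pct, n = 20) {
    k <- round(acc_pct / 100 * n)
    rec <- data.frame(
      phase = "without_feedback",
      true = rep("felt", n),
      response = c(rep("felt", k), rep("mesh", n - k)),
      n_presentations = 1,
      correct = c(rep(TRUE, k), rep(FALSE, n - k))
    )
    list(records = rec)
  }
  runs <- lapply(c(70, 85, 90), fake_run)
  sm <- accuracy_summary(runs)
  expect_equal(sm$median_acc_pct[sm$texture == "overall"], 85)

  # all-correct records: accuracy 100%, IQR width 0
  runs100 <- lapply(c(100, 100, 100), fake_run)
  sm100 <- accuracy_summary(runs100)
  expect_equal(sm100$median_acc_pct, rep(100, nrow(sm100)))
  expect_equal(sm100$q75_pct - sm100$q25_pct, rep(0, nrow(sm100)))

  # quartiles agree with a hand-rolled type-7 percentile on random sets
  set.seed(61)
  accs <- round(runif(7, 50, 100) / 5) * 5
  runs <- lapply(accs, fake_run)
  sm <- accuracy_summary(runs)
  oracle_pct <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  ov <- sm[sm$texture == "overall", ]
  expect_equal(ov$median_acc_pct, oracle_pct(accs, 0.5))
  expect_equal(ov$q25_pct, oracle_pct(accs, 0.25))
  expect_equal(ov$q75_pct, oracle_pct(accs, 0.75))
})

test_that("records CSV export has the documented columns", {
  csv <- withr::local_tempfile(fileext = ".csv")
  res <- run_protocol(protocol_spec(seed = 16, cycles_per_texture = 2,
                                    phases = c("training",
                                               "without_feedback")),
                      observer = oracle_observer(), stroke_duration_s = 0.5)
  write_records_csv(res, csv)
  df <- read.csv(csv)
  expect_named(df, c("phase", "true", "response", "n_presentations",
                     "correct"))
})
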