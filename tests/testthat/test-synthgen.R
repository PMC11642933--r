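test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- cohort_config(n_patients = 1, duration_s = 900, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$recordings[[1]]$channels$NP$samples,
                   b$recordings[[1]]$channels$NP$samples)
  expect_identical(a$annotations[[1]], b$annotations[[1]])
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("recordings match the configured regime", {
  coh <- test_cohort()
  rec <- coh$recordings[[1]]
  expect_setequal(names(rec$channels), namts:::CANONICAL_CHANNELS)
  for (nm in names(rec$channels))
    expect_equal(rec$channels[[nm]]$rate, namts:::NATIVE_RATES[[nm]])
  expect_true(all(rec$channels$SPO2$samples <= 100))
  expect_true(mean(rec$channels$SPO2$samples) > 90)
  expect_true(all(rec$channels$HR$samples > 50 &
                    rec$channels$HR$samples < 240))
  expect_true(abs(mean(rec$channels$PCO2$samples) - 41) < 4)
  ## ground truth: signature onset precedes event onset
  gt <- coh$ground_truth
  expect_true(all(gt$signature_onset_s < gt$onset_s))
})

test_that("per-recording adverse event counts stay in the Poisson band", {
  ## nominal rate 30/h over 2 h -> mean 60; 3 sigma of Poisson(60) ~ 23
  counts <- c()
  for (s in 1:3) {
    coh <- generate_cohort(cohort_config(n_patients = 2, duration_s = 7200,
                                         event_rate_per_h = 30, seed = s))
    counts <- c(counts, vapply(coh$annotations, function(a)
      sum(a$kind %in% namts:::ADVERSE_KINDS), numeric(1)))
  }
  expect_true(all(abs(counts - 60) <= 3 * sqrt(60)))
  ## events respect the 25 s minimum onset gap
  coh <- generate_cohort(cohort_config(n_patients = 1, duration_s = 7200,
                                       seed = 9))
  adv <- coh$annotations[[1]]
  adv <- adv[adv$kind %in% namts:::ADVERSE_KINDS, ]
  expect_true(all(diff(sort(adv$start_s)) >= 25 - 1e-9))
})

test_that("zero signature strength leaves pre-event windows unremarkable", {
  ## two-sample test on NP window means, pre-event vs control, alpha 0.01
  ws <- test_window_set(strength = 0)
  np_means <- rowMeans(ws$x$NP)
  expect_gt(sum(ws$label == 1), 20)
  expect_gt(t.test(np_means[ws$label == 1], np_means[ws$label == 0])$p.value,
            0.01)
  ## same for the SpO2 level, where the planted dip would otherwise show
  sp_means <- rowMeans(ws$x$SPO2)
  expect_gt(t.test(sp_means[ws$label == 1], sp_means[ws$label == 0])$p.value,
            0.01)
})

test_that("strong signatures separate pre-event windows", {
  ws <- test_window_set()
  sp_means <- rowMeans(ws$x$SPO2)
  expect_lt(t.test(sp_means[ws$label == 1], sp_means[ws$label == 0])$p.value,
            1e-4)
  expect_lt(mean(sp_means[ws$label == 1]), mean(sp_means[ws$label == 0]))
})

test_that("cohort_summary reports rates, durations and window counts", {
  coh <- test_cohort()
  s <- cohort_summary(coh$annotations, coh$recordings)
  expect_equal(nrow(s), 4)
  ## rate column is the count over the recording duration
  expect_equal(s$events_per_h,
               s$n_events / unname(vapply(coh$recordings, `[[`, numeric(1),
                                          "duration_s")) * 3600)
  expect_true(all(s$events_per_h > 5 & s$events_per_h < 70))
  expect_true(all(s$median_event_dur_s >= 3 & s$median_event_dur_s <= 7))
  expect_true(all(s$n_target <= s$n_events))
  expect_true(all(s$n_control > 0))

  ## degenerate inputs
  empty <- cohort_summary(list(annotations()), duration_s = 3600)
  expect_equal(empty$n_events, 0)
  expect_equal(empty$events_per_h, 0)
  expect_equal(empty$median_event_dur_s, 0)

  one <- cohort_summary(list(annotations("central_apnea", 100, 105)),
                        duration_s = 3600)
  expect_equal(one$events_per_h, 1)
  expect_equal(one$median_event_dur_s, 5)
})

test_that("downstream detectability is monotone in signature strength", {
  ## chance at strength 0, intermediate when weak, high when strong, on
  ## matched cohort seeds (event placements coincide; signal noise differs)
  aucs <- vapply(c(0, 0.35, 1), function(s) {
    coh <- generate_cohort(cohort_config(n_patients = 5, duration_s = 3600,
                                         signature_strength = s, seed = 21))
    ds <- cohort_window_set(coh$recordings, coh$annotations)
    loocv(ds, "nam",
          cfg = eval_config(train = train_config(batch_size = 8),
                            n_perm = 99, seed = 1))$aggregate$mean_auroc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_lt(aucs[1], 0.6)
  expect_gt(aucs[3], 0.8)
})

test_that("too-short recordings are rejected", {
  expect_error(cohort_config(duration_s = 120), "too short")
})
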