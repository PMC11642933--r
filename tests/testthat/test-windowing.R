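mk_rec <- function(duration, patient = "T") {
  ## 1 Hz carrier channel is enough for pure interval logic
  recording(patient, list(channel("HR", rep(120, duration), 1)))
}

wcfg <- windowing_config()

test_that("build_mask merges intervals and ignores hypoxia", {
  ann <- annotations(c("central_apnea", "obstructive_apnea"),
                     c(10, 12), c(14, 20))
  m <- build_mask(ann, wcfg, 100)
  expect_equal(m$start, 10)
  expect_equal(m$end, 20)

  expect_equal(nrow(build_mask(annotations("hypoxia", 5, 15), wcfg, 100)), 0)

  m2 <- build_mask(annotations("movement", 0, 5), wcfg, 100)
  expect_equal(m2$start, 0)
  expect_equal(m2$end, 5)

  ## clipping to the recording
  m3 <- build_mask(annotations("movement", 90, 300), wcfg, 100)
  expect_equal(m3$end, 100)
})

test_that("the single-event worked example yields 1 target and 20 controls", {
  rec <- mk_rec(1000)
  ann <- annotations("obstructive_apnea", 500, 505)
  w <- extract_windows(rec, ann, wcfg)
  lab <- vapply(w, `[[`, character(1), "label")
  tgt <- w[lab == "target"]
  ctl <- w[lab == "control"]
  expect_length(tgt, 1)
  expect_equal(tgt[[1]]$start_s, 455)
  expect_equal(tgt[[1]]$end_s, 485)
  expect_length(ctl, 20)
  starts <- sort(vapply(ctl, `[[`, numeric(1), "start_s"))
  expect_equal(starts, c(seq(0, 270, 30), seq(685, 955, 30)))
})

test_that("boundary and clustered-event cases", {
  ## candidate window would start before the recording
  w <- extract_windows(mk_rec(400), annotations("central_apnea", 30, 34),
                       wcfg)
  expect_length(w[vapply(w, `[[`, character(1), "label") == "target"], 0)

  ## second clustered event's candidate hits the first event's mask
  ann <- annotations(c("central_apnea", "central_apnea"),
                     c(600, 620), c(605, 625))
  w <- extract_windows(mk_rec(1300), ann, wcfg)
  tgt <- w[vapply(w, `[[`, character(1), "label") == "target"]
  expect_length(tgt, 1)
  expect_equal(tgt[[1]]$start_s, 555)

  ## overlapping candidates from close events: earlier event wins
  ann2 <- annotations(c("central_apnea", "central_apnea"),
                      c(600, 610), c(602, 612))
  w2 <- extract_windows(mk_rec(1300), ann2, wcfg)
  tgt2 <- w2[vapply(w2, `[[`, character(1), "label") == "target"]
  expect_length(tgt2, 1)
  expect_equal(tgt2[[1]]$start_s, 555)
})

test_that("windows have exact native sample counts and avoid masks", {
  coh <- test_cohort(n = 1, dur = 1800)
  ws <- extract_windows(coh$recordings[[1]], coh$annotations[[1]], wcfg)
  expect_gt(length(ws), 0)
  mask <- build_mask(coh$annotations[[1]], wcfg,
                     coh$recordings[[1]]$duration_s)
  for (w in ws) {
    for (nm in names(w$channels))
      expect_length(w$channels[[nm]], 30 * w$rates[[nm]])
    expect_false(any(mask$start < w$end_s & mask$end > w$start_s))
  }
  ## target count <= adverse count; controls pairwise disjoint
  lab <- vapply(ws, `[[`, character(1), "label")
  expect_lte(sum(lab == "target"),
             sum(coh$annotations[[1]]$kind %in% namts:::ADVERSE_KINDS))
  ctl <- ws[lab == "control"]
  starts <- sort(vapply(ctl, `[[`, numeric(1), "start_s"))
  if (length(starts) > 1) expect_true(all(diff(starts) >= 30 - 1e-9))
})

test_that("windows containing NaN samples are dropped", {
  rec <- mk_rec(1000)
  rec$channels$HR$samples[460] <- NA  # inside the sole target window
  ann <- annotations("obstructive_apnea", 500, 505)
  w <- extract_windows(rec, ann, wcfg)
  lab <- vapply(w, `[[`, character(1), "label")
  expect_equal(sum(lab == "target"), 0)
  expect_equal(sum(lab == "control"), 20)
})

test_that("extraction agrees with the brute-force oracle on random timelines", {
  set.seed(77)
  kinds_pool <- c(namts:::ADVERSE_KINDS, "movement", "hypoxia")
  for (i in 1:30) {
    duration <- sample(300:1200, 1)
    n_ev <- sample(0:8, 1)
    if (n_ev == 0) {
      ev <- data.frame(kind = character(), start = numeric(),
                       end = numeric())
    } else {
      start <- sort(sample(0:(duration - 20), n_ev))
      ev <- data.frame(kind = sample(kinds_pool, n_ev, replace = TRUE),
                       start = start,
                       end = start + sample(2:15, n_ev, replace = TRUE))
    }
    oracle <- windows_bruteforce(ev, duration)
    ann <- if (nrow(ev)) annotations(ev$kind, ev$start, ev$end)
           else annotations()
    got <- extract_windows(mk_rec(duration), ann, wcfg)
    lab <- vapply(got, `[[`, character(1), "label")
    starts <- vapply(got, `[[`, numeric(1), "start_s")
    expect_equal(sort(starts[lab == "target"]), sort(oracle$targets),
                 info = sprintf("targets, case %d", i))
    expect_equal(sort(starts[lab == "control"]), sort(oracle$controls),
                 info = sprintf("controls, case %d", i))
  }
})

test_that("sweep_horizon shifts targets and leaves controls fixed", {
  rec <- mk_rec(1000)
  ann <- annotations("obstructive_apnea", 500, 505)
  sw <- sweep_horizon(rec, ann, wcfg, horizons = c(0, 15))
  get <- function(ws, what) {
    lab <- vapply(ws, `[[`, character(1), "label")
    sort(vapply(ws[lab == what], `[[`, numeric(1), "start_s"))
  }
  expect_equal(get(sw[["0"]], "target"), 470)
  expect_equal(get(sw[["15"]], "target"), 455)
  expect_identical(get(sw[["0"]], "control"), get(sw[["15"]], "control"))

  ## horizon longer than the recording allows -> no targets
  sw2 <- sweep_horizon(mk_rec(400), annotations("central_apnea", 350, 355),
                       wcfg, horizons = 600)
  expect_equal(length(get(sw2[["600"]], "target")), 0)

  expect_length(sweep_horizon(rec, ann, wcfg, horizons = numeric(0)), 0)
})
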