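# Shared synthetic cohorts, generated once per test run.
.cohort_cache <- new.env(parent = emptyenv())

test_cohort <- function(strength = 1, seed = 11, n = 4, dur = 3600,
                        mods = c("NP", "TA", "SPO2", "HR")) {
  key <- paste(strength, seed, n, dur, paste(mods, collapse = ""), sep = "|")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(cohort_config(
      n_patients = n, duration_s = dur, signature_strength = strength,
      signature_modalities = mods, seed = seed))
  .cohort_cache[[key]]
}

test_window_set <- function(..., horizon = 15) {
  key <- paste("ws", paste(c(...), collapse = "|"), horizon, sep = "|")
  if (is.null(.cohort_cache[[key]])) {
    coh <- test_cohort(...)
    .cohort_cache[[key]] <- cohort_window_set(
      coh$recordings, coh$annotations, windowing_config(horizon_s = horizon))
  }
  .cohort_cache[[key]]
}

# A single clean raw window built directly (no cohort machinery): smooth
# oscillations, no NaN, native rates.
toy_raw_window <- function(label = "control", seed = 1) {
  set.seed(seed)
  mk <- function(rate, f = 1)
    sin(2 * pi * f * (0:(30 * rate - 1)) / rate) + rnorm(30 * rate, sd = 0.1)
  structure(list(
    patient_id = "T", start_s = 0, end_s = 30, label = label,
    horizon_s = 15,
    channels = list(NP = mk(200), THOR = mk(50), ABD = mk(50),
                    HR = 140 + rnorm(30), PPG = mk(100, 2),
                    SPO2 = 96 + rnorm(60, sd = 0.3),
                    PCO2 = 41 + rnorm(60, sd = 0.3)),
    rates = c(NP = 200, THOR = 50, ABD = 50, HR = 1, PPG = 100,
              SPO2 = 2, PCO2 = 2)),
    class = "namts_raw_window")
}

# Small random window set for model mechanics tests (not physiologic).
toy_window_set <- function(n, seed = 1, Tfast = 150, Tslow = 30,
                           separable = FALSE) {
  set.seed(seed)
  x <- list()
  for (m in c("NP", "TA", "PPG")) x[[m]] <- matrix(rnorm(n * Tfast), n, Tfast)
  for (m in c("HR", "SPO2", "PCO2")) x[[m]] <- matrix(rnorm(n * Tslow), n, Tslow)
  label <- rep_len(c(1L, 0L), n)
  if (separable) {
    for (i in which(label == 1)) {
      x$SPO2[i, ] <- x$SPO2[i, ] - 1.5
      x$NP[i, 75:150] <- x$NP[i, 75:150] * 3
    }
  }
  structure(list(x = x, label = label,
                 patient = rep(paste0("P", 1:4), length.out = n),
                 start_s = seq_len(n) * 30),
            class = "namts_window_set")
}
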