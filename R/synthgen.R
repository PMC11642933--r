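#' Configuration for a synthetic polysomnography cohort
#'
#' The generator emulates the descriptive regime of overnight neonatal
#' recordings in infants at risk of upper-airway obstruction: six signal
#' modalities at their native rates (nasal pressure 200 Hz, thoracic and
#' abdominal effort 50 Hz, PPG 100 Hz, heart rate 1 Hz, SpO2 and PCO2 2 Hz),
#' apnea/hypopnea events placed by a thinned Poisson process with optional
#' clustering, movement artifacts, and a planted pre-event signature whose
#' strength is under experimental control. The signal model is
#' phenomenological (amplitude/frequency-modulated oscillators plus smooth
#' AR(1) wander and white noise); it guarantees the statistical contrasts a
#' window classifier should detect, not neonatal biophysics.
#'
#' @param n_patients Number of patients.
#' @param duration_s Recording duration per patient, seconds (>= 600).
#' @param event_rate_per_h Adverse (apnea/hypopnea) events per hour before
#'   thinning; thinning enforces a 25 s minimum onset-to-onset gap, and
#'   clustering adds follow-up events 60-180 s after an event with
#'   probability `cluster_prob`.
#' @param event_duration_s Length-2 numeric, min and max event duration (s).
#' @param cluster_prob Probability an event is followed by another within
#'   60-180 s.
#' @param movement_rate_per_h Movement artifacts per hour (masked, never
#'   adverse).
#' @param signature_strength Nonnegative scalar scaling all planted
#'   pre-event signatures; 0 disables them entirely, making pre-event signal
#'   statistically indistinguishable from baseline.
#' @param signature_span_s Seconds before each event onset during which the
#'   signature ramps in; the default 45 covers the default target window
#'   `[onset-45, onset-15)`.
#' @param signature_modalities Which modalities carry a signature. `"NP"`
#'   gets breathing-amplitude irregularity at full strength, `"TA"` the same
#'   at 40% strength on both effort belts, `"SPO2"` a saturation dip and
#'   `"HR"` a small heart-rate perturbation. Restricting to `"NP"` gives the
#'   single-informative-modality recovery setting.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A list of class `namts_cohort_config`.
#' @export
cohort_config <- function(n_patients = 8, duration_s = 7200,
                          event_rate_per_h = 30,
                          event_duration_s = c(3, 7), cluster_prob = 0.25,
                          movement_rate_per_h = 10,
                          signature_strength = 1, signature_span_s = 45,
                          signature_modalities = c("NP", "TA", "SPO2", "HR"),
                          seed = 1L) {
  stopifnot(n_patients >= 1, event_rate_per_h >= 0, movement_rate_per_h >= 0,
            signature_strength >= 0, signature_span_s > 0,
            length(event_duration_s) == 2,
            event_duration_s[1] > 0,
            event_duration_s[2] >= event_duration_s[1])
  if (duration_s < 600)
    stop("duration_s too short to host events and control regions (need >= 600)")
  sig_mods <- match.arg(signature_modalities, c("NP", "TA", "SPO2", "HR"),
                        several.ok = TRUE)
  structure(list(n_patients = as.integer(n_patients),
                 duration_s = duration_s,
                 event_rate_per_h = event_rate_per_h,
                 event_duration_s = event_duration_s,
                 cluster_prob = cluster_prob,
                 movement_rate_per_h = movement_rate_per_h,
                 signature_strength = signature_strength,
                 signature_span_s = signature_span_s,
                 signature_modalities = sig_mods,
                 seed = as.integer(seed)),
            class = "namts_cohort_config")
}

## Smooth stationary wander: AR(1) generated at `gen_rate` Hz, linearly
## interpolated to the target sample grid. sd is the marginal sd.
ar1_wander <- function(n_out, out_rate, gen_rate = 0.2, phi = 0.95, sd = 1) {
  n_gen <- max(4L, ceiling(n_out / out_rate * gen_rate) + 2L)
  e <- rnorm(n_gen, sd = sd * sqrt(1 - phi^2))
  ## stationary initialization: the recording starts mid-night, not at the
  ## process mean (a zero start would make early windows systematically
  ## calmer, a time-of-night artifact a classifier could exploit)
  z <- as.numeric(stats::filter(e, phi, method = "recursive",
                                init = rnorm(1, 0, sd)))
  t_gen <- (seq_len(n_gen) - 1) / gen_rate
  t_out <- (seq_len(n_out) - 1) / out_rate
  approx(t_gen, z, xout = pmin(t_out, max(t_gen)))$y
}

## Place adverse events. Apneas and hypopneas occur in clusters: event
## intensity alternates between active episodes (mean 10 min) and quiet
## stretches (mean 15 min), so long event-free control regions exist, as in
## real overnight recordings where control windows outnumber targets.
## The in-episode intensity is calibrated to the realized active time and
## compensated for minimum-gap thinning and the expected cluster additions,
## so the per-recording event count is centered on
## `event_rate_per_h * duration`. Cluster follow-ups 60-180 s after an
## event are added with probability `cluster_prob`.
place_events <- function(cfg) {
  dur <- cfg$duration_s
  margin <- 60                     # keep events off the recording edges
  active_mean <- 600; quiet_mean <- 900
  ## alternating quiet/active episodes covering the recording; the chain
  ## starts in its stationary state (exponential lengths are memoryless,
  ## so a random initial phase only needs a random initial state)
  t <- 0; episodes <- NULL
  active <- runif(1) < active_mean / (active_mean + quiet_mean)
  while (t < dur) {
    len <- rexp(1, 1 / (if (active) active_mean else quiet_mean))
    if (active) episodes <- rbind(episodes, c(t, min(t + len, dur)))
    t <- t + len
    active <- !active
  }
  if (is.null(episodes))           # degenerate draw: one central episode
    episodes <- rbind(c(dur / 3, 2 * dur / 3))
  ep_a <- pmax(episodes[, 1], margin)
  ep_b <- pmin(episodes[, 2], dur - margin)
  keep_ep <- ep_b > ep_a
  ep_a <- ep_a[keep_ep]; ep_b <- ep_b[keep_ep]
  if (!length(ep_a)) { ep_a <- dur / 3; ep_b <- 2 * dur / 3 }
  active_total <- sum(ep_b - ep_a)
  ## every recording keeps a minimum active fraction: the emulated regime
  ## has no event-free nights, and short recordings would otherwise draw
  ## them regularly (deterministic extension, no extra RNG draws)
  required <- 0.15 * dur
  if (active_total < required) {
    i <- which.max(ep_b - ep_a)
    grow <- required - active_total
    new_b <- min(ep_b[i] + grow, dur - margin)
    grow <- grow - (new_b - ep_b[i])
    ep_b[i] <- new_b
    if (grow > 0) ep_a[i] <- max(margin, ep_a[i] - grow)
    active_total <- sum(ep_b - ep_a)
  }
  n_target <- cfg$event_rate_per_h * dur / 3600
  lam0 <- n_target / (1 + 0.8 * cfg$cluster_prob) / active_total
  lam <- lam0 / max(1 - 25 * lam0, 0.2)               # thinning compensation
  onsets <- numeric(0)
  for (i in seq_along(ep_a)) {
    n0 <- rpois(1, lam * (ep_b[i] - ep_a[i]))
    onsets <- c(onsets, runif(n0, ep_a[i], ep_b[i]))
  }
  onsets <- sort(onsets)
  kept <- numeric(0)
  for (t in onsets) {
    if (!length(kept) || t - kept[length(kept)] >= 25) kept <- c(kept, t)
  }
  extra <- numeric(0)
  for (t in kept) {
    if (runif(1) < cfg$cluster_prob) {
      t2 <- t + runif(1, 60, 180)
      if (t2 < dur - margin && all(abs(t2 - c(kept, extra)) >= 25))
        extra <- c(extra, t2)
    }
  }
  onsets <- sort(c(kept, extra))
  durs <- runif(length(onsets), cfg$event_duration_s[1], cfg$event_duration_s[2])
  kinds <- sample(ADVERSE_KINDS, length(onsets), replace = TRUE,
                  prob = c(0.15, 0.25, 0.10, 0.15, 0.35))
  list(onset = onsets, dur = durs, kind = kinds)
}

## Per-event signature ramp evaluated on a time grid: 0 outside
## [onset - span, onset), rising linearly to 1 at onset.
signature_ramp <- function(t, onsets, span) {
  w <- numeric(length(t))
  for (t0 in onsets) {
    i <- which(t >= t0 - span & t < t0)
    if (length(i)) w[i] <- pmax(w[i], (t[i] - (t0 - span)) / span)
  }
  w
}

## Amplitude-irregularity multiplier for breathing signals: smooth
## zero-mean roughness plus 1-2 short near-pause dips per event, all scaled
## by strength * ramp. Returns a positive envelope multiplier.
breath_irregularity <- function(t, rate, onsets, span, strength) {
  if (strength <= 0 || !length(onsets)) return(rep(1, length(t)))
  w <- signature_ramp(t, onsets, span)
  rough <- ar1_wander(length(t), rate, gen_rate = 2, phi = 0.75, sd = 1)
  mult <- 1 + strength * w * pmax(rough, -0.9)
  for (t0 in onsets) {
    ## short near-pauses scattered over the signature span, deepening
    ## toward the event onset (pre-apnea breathing instability)
    n_dip <- 2L + rbinom(1, 2, 0.5)
    centers <- t0 - span * c(0.08, 0.35, 0.6, 0.85)[seq_len(n_dip)] -
      runif(n_dip, 0, 0.05 * span)
    for (ct in centers) {
      wc <- max(0, (ct - (t0 - span)) / span)
      depth <- pmin(0.95, 0.9 * strength * (0.4 + 0.6 * wc))
      if (depth > 0)
        mult <- mult * (1 - depth * exp(-((t - ct) / 1.2)^2))
    }
  }
  pmax(mult, 0.02)
}

gen_patient <- function(cfg, patient_id, seed) {
  set.seed(seed)
  dur <- cfg$duration_s
  s <- cfg$signature_strength
  span <- cfg$signature_span_s
  mods <- cfg$signature_modalities
  ev <- place_events(cfg)
  onsets <- ev$onset

  ## movements
  n_mv <- rpois(1, cfg$movement_rate_per_h * dur / 3600)
  mv_start <- sort(runif(n_mv, 0, dur - 12))
  mv_dur <- runif(n_mv, 2, 10)

  ## shared breathing phase (0.6-1.2 Hz wandering) at 200 Hz
  n200 <- dur * 200
  t200 <- (seq_len(n200) - 1) / 200
  f_breath <- pmin(1.2, pmax(0.6, 0.9 + 0.12 * ar1_wander(n200, 200)))
  phase <- cumsum(2 * pi * f_breath / 200)
  env <- pmax(0.2, 1 + 0.18 * ar1_wander(n200, 200))

  irr_np <- if ("NP" %in% mods)
    breath_irregularity(t200, 200, onsets, span, s) else rep(1, n200)
  np <- env * irr_np * sin(phase) + rnorm(n200, sd = 0.15)

  ## effort belts at 50 Hz share the phase; TA signature at 40% strength
  i50 <- seq(1, n200, by = 4)
  t50 <- t200[i50]
  irr_ta <- if ("TA" %in% mods)
    breath_irregularity(t50, 50, onsets, span, 0.4 * s) else
      rep(1, length(i50))
  base50 <- env[i50] * irr_ta
  thor <- 1.1 * base50 * sin(phase[i50] - 0.1) +
    rnorm(length(i50), sd = 0.15)
  abd <- 0.9 * base50 * sin(phase[i50] - 0.25) +
    rnorm(length(i50), sd = 0.15)

  ## heart rate (1 Hz) around 140 bpm with slow wander
  n1 <- dur
  t1 <- seq_len(n1) - 1
  hr <- 140 + 8 * ar1_wander(n1, 1) + rnorm(n1, sd = 1)
  if ("HR" %in% mods && s > 0 && length(onsets)) {
    wr <- signature_ramp(t1, onsets, span)
    hr <- hr + 6 * s * wr * sin(2 * pi * t1 / 8)
  }
  hr <- pmin(220, pmax(80, hr))

  ## PPG at 100 Hz: cardiac-band oscillation at hr/60 Hz + baseline wander
  n100 <- dur * 100
  t100 <- (seq_len(n100) - 1) / 100
  f_card <- approx(t1, hr / 60, xout = pmin(t100, max(t1)))$y
  ppg <- (1 + 0.1 * ar1_wander(n100, 100)) * sin(cumsum(2 * pi * f_card / 100)) +
    0.3 * ar1_wander(n100, 100, gen_rate = 0.5) + rnorm(n100, sd = 0.1)

  ## SpO2 at 2 Hz: ~97% baseline; pre-event dip scaled by strength; post-
  ## event desaturation carry-over (clusters make this informative)
  n2 <- dur * 2
  t2 <- (seq_len(n2) - 1) / 2
  spo2 <- 97 + 0.8 * ar1_wander(n2, 2) + rnorm(n2, sd = 0.2)
  if ("SPO2" %in% mods && s > 0 && length(onsets)) {
    w2 <- signature_ramp(t2, onsets, span)
    spo2 <- spo2 - 4 * s * w2^1.5
  }
  ## post-event desaturation carry-over, scaled with the signature
  ## strength so that a strength-0 cohort carries no predictive structure
  ## at all (clusters otherwise make pre-event SpO2 genuinely informative)
  if ("SPO2" %in% mods && s > 0) {
    for (j in seq_along(onsets)) {
      e_end <- onsets[j] + ev$dur[j]
      i <- which(t2 >= e_end & t2 < e_end + 30)
      if (length(i))
        spo2[i] <- spo2[i] - 3 * s * exp(-(t2[i] - e_end) / 10)
    }
  }
  spo2 <- pmin(100, pmax(70, spo2))

  ## PCO2 at 2 Hz: ~41 mmHg, slow drift only
  pco2 <- 41 + 1.2 * ar1_wander(n2, 2, gen_rate = 0.05) + rnorm(n2, sd = 0.15)

  rec <- recording(patient_id, list(
    channel("NP", np, 200), channel("THOR", thor, 50),
    channel("ABD", abd, 50), channel("HR", hr, 1),
    channel("PPG", ppg, 100), channel("SPO2", spo2, 2),
    channel("PCO2", pco2, 2)), duration_s = dur)

  ## annotations: adverse events, hypoxia after ~half of them, movements
  kinds <- ev$kind
  a_start <- onsets
  a_end <- onsets + ev$dur
  hyp <- which(runif(length(onsets)) < 0.5)
  ann <- annotations(
    c(kinds, rep("hypoxia", length(hyp)), rep("movement", n_mv)),
    c(a_start, a_end[hyp] + 1, mv_start),
    c(a_end, pmin(a_end[hyp] + 11, dur), pmin(mv_start + mv_dur, dur)))

  gt <- data.frame(patient = patient_id,
                   onset_s = onsets, kind = kinds,
                   signature_onset_s = onsets - span,
                   stringsAsFactors = FALSE)
  list(recording = rec, annotations = ann, ground_truth = gt)
}

#' Generate a synthetic polysomnography cohort
#'
#' @param cfg A [cohort_config()].
#' @return A list with `recordings` (list of [recording()]),
#'   `annotations` (list of [annotations()] tables, same order) and
#'   `ground_truth` (data.frame of per-event onset, kind and signature onset,
#'   with a `patient` column). Deterministic given `cfg` (bit-exact).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "namts_cohort_config"))
  recs <- vector("list", cfg$n_patients)
  anns <- vector("list", cfg$n_patients)
  gts <- vector("list", cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    out <- gen_patient(cfg, pid, seed = cfg$seed * 1000L + p)
    recs[[p]] <- out$recording
    anns[[p]] <- out$annotations
    gts[[p]] <- out$ground_truth
  }
  names(recs) <- names(anns) <- vapply(recs, `[[`, character(1), "patient_id")
  list(recordings = recs, annotations = anns,
       ground_truth = do.call(rbind, gts))
}

#' Summarize a cohort's annotation tracks
#'
#' @param anns List of [annotations()] tables, one per patient.
#' @param recordings Optional list of matching [recording()]s; if supplied,
#'   extracted window counts per patient are included (delegating to
#'   [extract_windows()]).
#' @param cfg A [windowing_config()] used for window counts.
#' @param duration_s Optional per-patient recording duration(s) in seconds
#'   (recycled); taken from `recordings` when those are given, else from the
#'   last annotation end.
#' @return data.frame, one row per patient: `events_per_h` (adverse events
#'   only), `median_event_dur_s`, and when recordings are given `n_target`,
#'   `n_control`.
#' @export
cohort_summary <- function(anns, recordings = NULL,
                           cfg = windowing_config(), duration_s = NULL) {
  stopifnot(length(anns) >= 1)
  if (!is.null(duration_s))
    duration_s <- rep_len(duration_s, length(anns))
  rows <- lapply(seq_along(anns), function(p) {
    a <- anns[[p]]
    adv <- a[a$kind %in% ADVERSE_KINDS, , drop = FALSE]
    dur_h <- if (!is.null(recordings)) recordings[[p]]$duration_s / 3600
             else if (!is.null(duration_s)) duration_s[p] / 3600
             else if (nrow(a)) max(a$end_s) / 3600 else 1
    row <- data.frame(
      patient = names(anns)[p] %||% as.character(p),
      n_events = nrow(adv),
      events_per_h = nrow(adv) / dur_h,
      median_event_dur_s = if (nrow(adv))
        median(adv$end_s - adv$start_s) else 0)
    if (!is.null(recordings)) {
      w <- extract_windows(recordings[[p]], a, cfg)
      row$n_target <- sum(vapply(w, `[[`, character(1), "label") == "target")
      row$n_control <- length(w) - row$n_target
    }
    row
  })
  do.call(rbind, rows)
}
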