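## Decimation stage cache: Chebyshev designs per factor.
.decim_cache <- new.env(parent = emptyenv())

cheby_stage <- function(factor) {
  key <- as.character(factor)
  if (!is.null(.decim_cache[[key]])) return(.decim_cache[[key]])
  filt <- signal::cheby1(8, 0.01, 0.8 / factor)
  ## normalize to exactly unit DC gain (type-I even-order filters otherwise
  ## attenuate DC by the passband ripple)
  dc <- sum(filt$b) / sum(filt$a)
  filt$b <- filt$b / dc
  .decim_cache[[key]] <- filt
  filt
}

## Zero-phase IIR filtering: odd-reflection extension at both ends plus
## steady-state initial conditions (so a constant propagates exactly),
## forward pass then time-reversed pass. Equivalent in kind to the standard
## forward-backward filtering used for anti-aliased decimation.
filtfilt_zerophase <- function(filt, x) {
  b <- filt$b; a <- filt$a
  n <- length(x)
  p <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  pass <- function(z) {
    z1 <- z[1]
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z1, length(b) - 1L),
                              init.y = rep(z1 * sum(b) / sum(a),
                                           length(a) - 1L)))
  }
  y <- rev(pass(rev(pass(ext))))
  y[(p + 1):(p + n)]
}

#' Anti-aliased decimation
#'
#' Decimates a signal with an order-8 Chebyshev type-I low-pass (0.01 dB
#' passband ripple, cutoff 0.8 of the target Nyquist frequency) applied
#' zero-phase (forward-backward), factored into integer stages of at most 10
#' (e.g. 200 to 5 Hz runs as 10 then 4). The filter is normalized to unit DC
#' gain. Only integer overall decimation factors are supported, which covers
#' every rate pair in this pipeline.
#'
#' @param x Numeric samples.
#' @param in_rate,out_rate Input and output sampling rates (Hz);
#'   `in_rate / out_rate` must be a positive integer.
#' @return Decimated samples of length `round(length(x) * out_rate / in_rate)`.
#' @export
decimate <- function(x, in_rate, out_rate) {
  if (out_rate > in_rate)
    stop("out_rate must not exceed in_rate")
  q <- in_rate / out_rate
  if (abs(q - round(q)) > 1e-9)
    stop("in_rate/out_rate must be an integer decimation factor")
  q <- as.integer(round(q))
  if (q == 1L) return(as.numeric(x))
  x <- as.numeric(x)
  for (f in decim_stages(q)) {
    x <- filtfilt_zerophase(cheby_stage(f), x)
    x <- x[seq(1, length(x), by = f)]
  }
  x
}

## Factor q into stages each <= 10 (greedy, largest divisor first).
decim_stages <- function(q) {
  stages <- integer()
  while (q > 10L) {
    f <- max(Filter(function(d) q %% d == 0L, 2:10))
    if (!length(f)) stop(sprintf("cannot factor decimation %d into stages <= 10", q))
    stages <- c(stages, f)
    q <- q %/% f
  }
  c(stages, q)
}

#' Per-window standardization
#'
#' `(x - mean) / sd` with the population (ddof 0) standard deviation. If the
#' sd is below `1e-12` the zero-variance guard returns all zeros, so constant
#' windows never produce NaN.
#'
#' @param x Numeric samples (nonempty).
#' @return Standardized samples.
#' @export
zscore <- function(x) {
  stopifnot(length(x) > 0)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - m) / s
}

#' Summed respiratory effort
#'
#' Thoracic and abdominal effort are highly correlated; they are combined by
#' standardizing each, summing pointwise, and standardizing the result again.
#'
#' @param thor,abd Equal-length numeric samples.
#' @return Standardized summed effort ("TA").
#' @export
sum_effort <- function(thor, abd) {
  if (length(thor) != length(abd))
    stop("thor and abd must have equal length")
  zscore(zscore(thor) + zscore(abd))
}

#' Fixed-range normalization to \[-1, 1\]
#'
#' Clamps to `[lo, hi]`, then maps affinely with `lo` to -1 and `hi` to +1.
#' Out-of-range samples are treated as sensor artifacts and saturate.
#'
#' @param x Numeric samples.
#' @param lo,hi Physiologic range; `hi > lo`.
#' @return Samples in `[-1, 1]`.
#' @export
range_normalize <- function(x, lo, hi) {
  if (hi <= lo) stop("hi must exceed lo")
  x <- pmin(pmax(x, lo), hi)
  2 * (x - lo) / (hi - lo) - 1
}

#' Turn a raw window into a fixed-shape model input
#'
#' Applies the per-modality pipeline: nasal pressure 200 to 5 Hz then
#' standardized; thoracic and abdominal effort 50 to 5 Hz then combined via
#' [sum_effort()]; PPG 100 to 5 Hz then standardized; heart rate left at
#' 1 Hz and range-normalized 50-240 bpm; SpO2 and PCO2 2 to 1 Hz and
#' range-normalized 60-100% and 30-70 mmHg. Output shapes for a 30 s window:
#' 150 samples for NP/TA/PPG, 30 for HR/SPO2/PCO2.
#'
#' @param w A `namts_raw_window` from [extract_windows()].
#' @param ranges Named list overriding the normalization ranges.
#' @return A list of class `namts_model_input` with one numeric vector per
#'   modality (`NP`, `TA`, `PPG`, `HR`, `SPO2`, `PCO2`) plus `label` and
#'   provenance fields.
#' @export
prepare_window <- function(w, ranges = RANGE_NORM) {
  stopifnot(inherits(w, "namts_raw_window"))
  need <- c("NP", "THOR", "ABD", "HR", "PPG", "SPO2", "PCO2")
  missing <- setdiff(need, names(w$channels))
  if (length(missing)) stop(sprintf("missing channel %s", missing[1]))
  if (any(vapply(w$channels, anyNA, logical(1))))
    stop("window contains NA samples; drop it upstream")
  r <- w$rates
  ## a constant raw channel carries no waveform: short-circuit to the
  ## zero-variance guard output rather than standardizing decimation
  ## roundoff (~1e-9) into unit-variance noise
  is_const <- function(x) diff(range(x)) < 1e-9 * (abs(mean(x)) + 1)
  dz <- function(x, rate) {
    if (is_const(x)) rep(0, round(length(x) * 5 / rate))
    else zscore(decimate(x, rate, 5))
  }
  out <- list(
    NP = dz(w$channels$NP, r[["NP"]]),
    TA = if (is_const(w$channels$THOR) && is_const(w$channels$ABD))
           rep(0, round(length(w$channels$THOR) * 5 / r[["THOR"]]))
         else sum_effort(decimate(w$channels$THOR, r[["THOR"]], 5),
                         decimate(w$channels$ABD, r[["ABD"]], 5)),
    PPG = dz(w$channels$PPG, r[["PPG"]]),
    HR = range_normalize(w$channels$HR, ranges$HR[1], ranges$HR[2]),
    SPO2 = range_normalize(decimate(w$channels$SPO2, r[["SPO2"]], 1),
                           ranges$SPO2[1], ranges$SPO2[2]),
    PCO2 = range_normalize(decimate(w$channels$PCO2, r[["PCO2"]], 1),
                           ranges$PCO2[1], ranges$PCO2[2]))
  structure(c(out, list(label = w$label, patient_id = w$patient_id,
                        start_s = w$start_s, horizon_s = w$horizon_s)),
            class = "namts_model_input")
}

#' Stack model inputs into a training-ready window set
#'
#' @param inputs List of `namts_model_input` objects.
#' @return A `namts_window_set`: per-modality matrices (windows in rows),
#'   integer labels (1 = target, 0 = control), patient ids and window start
#'   times.
#' @export
window_set <- function(inputs) {
  stopifnot(length(inputs) > 0)
  x <- lapply(setNames(MODALITIES, MODALITIES), function(m)
    do.call(rbind, lapply(inputs, `[[`, m)))
  structure(list(
    x = x,
    label = vapply(inputs, function(w) as.integer(w$label == "target"),
                   integer(1)),
    patient = vapply(inputs, `[[`, character(1), "patient_id"),
    start_s = vapply(inputs, `[[`, numeric(1), "start_s")),
    class = "namts_window_set")
}

#' Extract and preprocess a whole cohort into one window set
#'
#' @param recordings List of [recording()]s.
#' @param anns Matching list of [annotations()] tables.
#' @param cfg A [windowing_config()].
#' @return A `namts_window_set` over all patients, or `NULL` if no windows
#'   survive extraction.
#' @export
cohort_window_set <- function(recordings, anns, cfg = windowing_config()) {
  inputs <- list()
  for (p in seq_along(recordings)) {
    ws <- extract_windows(recordings[[p]], anns[[p]], cfg)
    inputs <- c(inputs, lapply(ws, prepare_window))
  }
  if (!length(inputs)) return(NULL)
  window_set(inputs)
}

subset_window_set <- function(ds, idx) {
  structure(list(
    x = lapply(ds$x, function(m) m[idx, , drop = FALSE]),
    label = ds$label[idx], patient = ds$patient[idx],
    start_s = ds$start_s[idx]), class = "namts_window_set")
}

n_windows <- function(ds) length(ds$label)
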