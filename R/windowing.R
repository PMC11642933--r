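#' Window-extraction configuration
#'
#' Windows are 30 s by default. A target window ends `horizon_s` seconds
#' before an adverse event onset; a control window lies at least
#' `control_buffer_s` seconds from every adverse event boundary. All
#' intervals are half-open `[start, end)` in seconds.
#'
#' @param window_len_s Window length, seconds.
#' @param horizon_s Prediction horizon: gap between window end and event
#'   onset, seconds.
#' @param control_buffer_s Minimum distance of every control-window point
#'   from every adverse event's start and end, seconds.
#' @param adverse_kinds Event kinds counted as adverse (targets anchor to
#'   these; controls keep their distance from these). Intermittent hypoxia is
#'   deliberately not included: it is neither adverse nor masked.
#' @param mask_kinds Event kinds whose intervals are removed from the signal
#'   before windowing (adverse kinds plus movement by default).
#' @return A list of class `namts_windowing_config`.
#' @export
windowing_config <- function(window_len_s = 30, horizon_s = 15,
                             control_buffer_s = 180,
                             adverse_kinds = ADVERSE_KINDS,
                             mask_kinds = c(adverse_kinds, "movement")) {
  stopifnot(window_len_s > 0, horizon_s >= 0, control_buffer_s >= 0)
  structure(list(window_len_s = window_len_s, horizon_s = horizon_s,
                 control_buffer_s = control_buffer_s,
                 adverse_kinds = adverse_kinds, mask_kinds = mask_kinds),
            class = "namts_windowing_config")
}

## Merge a set of possibly overlapping [start, end) intervals into disjoint
## sorted intervals, clipped to [0, duration_s).
merge_intervals <- function(start, end, duration_s = Inf) {
  if (!length(start)) return(data.frame(start = numeric(), end = numeric()))
  start <- pmax(start, 0)
  end <- pmin(end, duration_s)
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  if (!length(start)) return(data.frame(start = numeric(), end = numeric()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Build the masked-interval set for a recording
#'
#' Returns the merged union of all annotation intervals whose kind is in
#' `cfg$mask_kinds`, clipped to the recording. Hypoxia intervals are not
#' masked (and are not adverse).
#'
#' @param ann An [annotations()] table.
#' @param cfg A [windowing_config()].
#' @param duration_s Recording duration, seconds.
#' @return data.frame with columns `start`, `end`: disjoint sorted intervals.
#' @export
build_mask <- function(ann, cfg = windowing_config(), duration_s = Inf) {
  m <- ann[ann$kind %in% cfg$mask_kinds, , drop = FALSE]
  merge_intervals(m$start_s, m$end_s, duration_s)
}

interval_intersects <- function(a_start, a_end, ivs) {
  if (!nrow(ivs)) return(FALSE)
  any(ivs$start < a_end & ivs$end > a_start)
}

## Half-open slice of a channel: samples covering [start_s, start_s+len_s).
## Sample k (1-based) covers [(k-1)/r, k/r); returns exactly len_s*r samples
## or NULL if out of range.
slice_channel <- function(ch, start_s, len_s) {
  n <- round(len_s * ch$rate)
  k0 <- ceiling(start_s * ch$rate - 1e-9) + 1  # first sample fully inside
  if (k0 < 1 || k0 + n - 1 > length(ch$samples)) return(NULL)
  ch$samples[k0:(k0 + n - 1)]
}

make_raw_window <- function(rec, start_s, label, cfg) {
  L <- cfg$window_len_s
  slices <- lapply(rec$channels, slice_channel, start_s = start_s, len_s = L)
  if (any(vapply(slices, is.null, logical(1)))) return(NULL)
  if (any(vapply(slices, anyNA, logical(1)))) return(NULL)
  structure(list(patient_id = rec$patient_id, start_s = start_s,
                 end_s = start_s + L, label = label,
                 horizon_s = cfg$horizon_s, channels = slices,
                 rates = vapply(rec$channels, `[[`, numeric(1), "rate")),
            class = "namts_raw_window")
}

#' Extract labeled target and control windows from a recording
#'
#' Targets: for each adverse event with onset `t` (in time order), the
#' candidate window `[t - horizon - L, t - horizon)` is emitted iff it lies
#' inside the recording, intersects no masked interval, and does not overlap
#' a previously emitted target. Controls: maximal regions whose every point
#' is unmasked and at least `control_buffer_s` from every adverse event
#' boundary are tiled left-to-right with non-overlapping windows; tails
#' shorter than a window are discarded. Windows containing any `NA` sample
#' are dropped.
#'
#' @param rec A [recording()].
#' @param ann An [annotations()] table.
#' @param cfg A [windowing_config()].
#' @return List of `namts_raw_window` objects (possibly empty), each holding
#'   per-channel raw slices at native rates plus label and provenance.
#' @export
extract_windows <- function(rec, ann, cfg = windowing_config()) {
  L <- cfg$window_len_s
  dur <- rec$duration_s
  if (dur < L) return(list())
  mask <- build_mask(ann, cfg, dur)
  adverse <- ann[ann$kind %in% cfg$adverse_kinds, , drop = FALSE]
  out <- list()

  ## targets, in event-time order; earlier event wins on overlap
  emitted <- data.frame(start = numeric(), end = numeric())
  for (i in seq_len(nrow(adverse))) {
    t0 <- adverse$start_s[i]
    ws <- t0 - cfg$horizon_s - L
    we <- ws + L
    if (ws < 0 || we > dur) next
    if (interval_intersects(ws, we, mask)) next
    if (interval_intersects(ws, we, emitted)) next
    w <- make_raw_window(rec, ws, "target", cfg)
    if (is.null(w)) next
    emitted <- rbind(emitted, data.frame(start = ws, end = we))
    out[[length(out) + 1]] <- w
  }

  ## control-eligible regions: complement of mask and of buffered adverse
  ## boundaries [b - buffer, b + buffer] around every event start and end
  buf <- cfg$control_buffer_s
  bounds <- c(adverse$start_s, adverse$end_s)
  excl <- merge_intervals(c(mask$start, bounds - buf),
                          c(mask$end, bounds + buf), dur)
  free_s <- c(0, excl$end)
  free_e <- c(excl$start, dur)
  for (r in seq_along(free_s)) {
    a <- free_s[r]; b <- free_e[r]
    n_w <- floor((b - a) / L + 1e-9)
    for (k in seq_len(max(0, n_w))) {
      w <- make_raw_window(rec, a + (k - 1) * L, "control", cfg)
      if (!is.null(w)) out[[length(out) + 1]] <- w
    }
  }
  out
}

#' Re-extract windows over a set of prediction horizons
#'
#' Controls do not depend on the horizon and are identical across entries.
#'
#' @param rec A [recording()].
#' @param ann An [annotations()] table.
#' @param cfg A [windowing_config()]; its `horizon_s` is overridden.
#' @param horizons Numeric vector of horizons (s).
#' @return Named list mapping horizon to the [extract_windows()] result.
#' @export
sweep_horizon <- function(rec, ann, cfg = windowing_config(),
                          horizons = c(0, 15, 150)) {
  stopifnot(all(horizons >= 0))
  out <- lapply(horizons, function(h) {
    cfg$horizon_s <- h
    extract_windows(rec, ann, cfg)
  })
  names(out) <- as.character(horizons)
  out
}
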