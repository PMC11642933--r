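# Independent oracles used across tests. They deliberately avoid the
# implementation paths they check.

# O(n^2) pairwise AuROC: fraction of positive/negative pairs won, ties 1/2.
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Brute-force window extraction on a 1-second grid of candidate starts.
# Mirrors the contract (per-event targets in time order, control tiling of
# eligible regions) but tests every point exhaustively instead of interval
# arithmetic.
windows_bruteforce <- function(events, duration, L = 30, horizon = 15,
                               buffer = 180) {
  # events: data.frame kind, start, end
  mask_kinds <- c(namts:::ADVERSE_KINDS, "movement")
  masked <- function(a, b) {       # does [a,b) hit any masked interval?
    for (i in seq_len(nrow(events))) {
      if (!(events$kind[i] %in% mask_kinds)) next
      if (events$start[i] < b && events$end[i] > a) return(TRUE)
    }
    FALSE
  }
  adverse <- events[events$kind %in% namts:::ADVERSE_KINDS, , drop = FALSE]
  adverse <- adverse[order(adverse$start), , drop = FALSE]
  targets <- numeric(0)
  for (i in seq_len(nrow(adverse))) {
    ws <- adverse$start[i] - horizon - L
    if (ws < 0 || ws + L > duration) next
    if (masked(ws, ws + L)) next
    overlap <- FALSE
    for (t0 in targets) if (t0 < ws + L && t0 + L > ws) overlap <- TRUE
    if (!overlap) targets <- c(targets, ws)
  }
  # eligible control points: >= buffer from every adverse boundary, unmasked
  eligible <- function(x) {
    for (i in seq_len(nrow(adverse)))
      if (abs(x - adverse$start[i]) < buffer ||
          abs(x - adverse$end[i]) < buffer) return(FALSE)
    for (i in seq_len(nrow(events))) {
      if (!(events$kind[i] %in% mask_kinds)) next
      if (x >= events$start[i] && x < events$end[i]) return(FALSE)
    }
    TRUE
  }
  # a whole candidate window [x, x+L) is valid iff it avoids the OPEN
  # buffered zone (b - buffer, b + buffer) around every adverse boundary
  # and every masked interval (interval checks, not just grid points)
  win_ok <- function(x) {
    if (x < 0 || x + L > duration) return(FALSE)
    for (i in seq_len(nrow(adverse)))
      for (b in c(adverse$start[i], adverse$end[i]))
        if (x < b + buffer && x + L > b - buffer) return(FALSE)
    !masked(x, x + L)
  }
  # maximal eligible regions located on a 1 s scan (all boundaries are
  # integers in the generated cases), then tiled greedily from the left
  controls <- numeric(0)
  x <- 0
  while (x <= duration - L) {
    if (eligible(x)) {
      while (win_ok(x)) { controls <- c(controls, x); x <- x + L }
      while (x < duration && eligible(x)) x <- x + 1   # skip the tail
    } else x <- x + 1
  }
  list(targets = targets, controls = controls)
}

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration of all
# 2^n sign assignments (midranks for ties).
wilcoxon_enumerate <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  ws <- vapply(0:(2^n - 1), function(code) {
    signs <- as.integer(intToBits(code))[1:n]
    sum(rk[signs == 1])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Minimal EDF writer (16-bit, single data-record duration) used only to
# round-trip-test the reader.
write_edf <- function(path, channels, record_dur = 1) {
  # channels: list of list(label, samples, rate, unit, phys_min, phys_max)
  ns <- length(channels)
  n_records <- max(vapply(channels, function(ch)
    ceiling(length(ch$samples) / (ch$rate * record_dur)), numeric(1)))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.24", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_records, 8)
  wr(format(record_dur), 8); wr(ns, 4)
  for (ch in channels) wr(ch$label, 16)
  for (ch in channels) wr("", 80)
  for (ch in channels) wr(ch$unit, 8)
  for (ch in channels) wr(format(ch$phys_min), 8)
  for (ch in channels) wr(format(ch$phys_max), 8)
  for (ch in channels) wr(-32768, 8)
  for (ch in channels) wr(32767, 8)
  for (ch in channels) wr("", 80)
  for (ch in channels) wr(ch$rate * record_dur, 8)
  for (ch in channels) wr("", 32)
  for (r in seq_len(n_records)) {
    for (ch in channels) {
      spr <- ch$rate * record_dur
      idx <- ((r - 1) * spr + 1):(r * spr)
      x <- ch$samples[idx]
      x[is.na(x)] <- 0
      dig <- round((x - ch$phys_min) / (ch$phys_max - ch$phys_min) *
                     65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
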