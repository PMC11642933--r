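## Minimal read-only EDF (European Data Format) support.
## EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal of
## per-signal metadata, then fixed-duration data records of little-endian
## 16-bit integers. Digital values are mapped affinely to physical units via
## the per-signal digital/physical min/max. Annotations-in-EDF ("EDF+"
## TAL streams) are not parsed; annotation tracks arrive separately.

read_edf_channels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    x <- readChar(con, n, useBytes = TRUE)
    if (nchar(x, type = "bytes") < n) stop("truncated EDF header")
    trimws(x)
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  rd(8); rd(44)                           # header bytes, reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF: bad signal count")
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- field(16)
  field(80)                               # transducer
  units <- field(8)
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                               # prefilter
  spr <- as.integer(field(8))             # samples per record
  field(32)                               # reserved
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)))
    stop("unreadable EDF: malformed signal header")
  total_per_rec <- sum(spr)
  raw <- readBin(con, integer(), n = n_records * total_per_rec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * total_per_rec)
    stop("unreadable EDF: truncated data records")
  offsets <- c(0L, cumsum(spr))
  out <- list()
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[i]) + offsets[i],
                           (seq_len(n_records) - 1L) * total_per_rec, `+`))
    dig <- raw[idx]
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    out[[labels[i]]] <- list(
      samples = phys_min[i] + (dig - dig_min[i]) * scale,
      rate = spr[i] / record_dur,
      unit = units[i])
  }
  out
}
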