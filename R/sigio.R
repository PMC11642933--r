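#' Construct a single-channel signal
#'
#' A `channel` is one modality of a recording: a numeric sample vector at a
#' fixed sampling rate. Missing samples are encoded as `NA`/`NaN` and are
#' never imputed; windows containing them are dropped during extraction.
#'
#' @param name Canonical modality label, one of
#'   `NP`, `THOR`, `ABD`, `HR`, `PPG`, `SPO2`, `PCO2`.
#' @param samples Numeric vector of samples. Sample `k` (1-based) covers the
#'   half-open time interval `[(k-1)/rate, k/rate)` seconds.
#' @param rate Sampling rate in samples/second (> 0).
#' @param unit Free-text physical unit.
#' @return An object of class `namts_channel`.
#' @export
channel <- function(name, samples, rate, unit = CHANNEL_UNITS[[name]]) {
  name <- match.arg(name, CANONICAL_CHANNELS)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("channel rate must be a positive finite scalar")
  structure(list(name = name, samples = as.numeric(samples),
                 rate = as.numeric(rate), unit = unit),
            class = "namts_channel")
}

#' Construct a multichannel recording
#'
#' @param patient_id Opaque patient identifier.
#' @param channels List of [channel()] objects; each canonical name at most
#'   once.
#' @param duration_s Recording duration in seconds. Defaults to the maximum
#'   channel duration; every channel length must be consistent with it to
#'   within one sample.
#' @return An object of class `namts_recording`.
#' @export
recording <- function(patient_id, channels, duration_s = NULL) {
  stopifnot(length(channels) > 0)
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(names(channels)))
    stop("duplicate canonical channel name in recording")
  durs <- vapply(channels, function(ch) length(ch$samples) / ch$rate,
                 numeric(1))
  if (is.null(duration_s)) duration_s <- max(durs)
  if (duration_s <= 0) stop("recording duration must be positive")
  for (ch in channels) {
    if (abs(length(ch$samples) / ch$rate - duration_s) > 1 / ch$rate + 1e-9)
      stop(sprintf("channel %s length inconsistent with duration %.3f s",
                   ch$name, duration_s))
  }
  structure(list(patient_id = as.character(patient_id), channels = channels,
                 duration_s = duration_s),
            class = "namts_recording")
}

#' @export
print.namts_recording <- function(x, ...) {
  cat(sprintf("<namts_recording> patient %s, %.1f s, %d channels: %s\n",
              x$patient_id, x$duration_s, length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Construct a validated event-annotation table
#'
#' @param kind Character vector of event kinds (apnea/hypopnea subtype,
#'   `hypoxia` or `movement`).
#' @param start_s,end_s Event interval in seconds, half-open
#'   `[start_s, end_s)`.
#' @return A data.frame with columns `kind`, `start_s`, `end_s`, sorted by
#'   `start_s`, of class `namts_annotations`.
#' @export
annotations <- function(kind = character(), start_s = numeric(),
                        end_s = numeric()) {
  kind <- as.character(kind)
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  stopifnot(length(kind) == length(start_s), length(kind) == length(end_s))
  bad_kind <- which(!(kind %in% EVENT_KINDS))
  if (length(bad_kind))
    stop(sprintf("invalid event kind '%s' at row %d", kind[bad_kind[1]],
                 bad_kind[1]))
  bad_iv <- which(!(start_s >= 0 & end_s > start_s))
  if (length(bad_iv))
    stop(sprintf("invalid interval at row %d: start_s=%g end_s=%g",
                 bad_iv[1], start_s[bad_iv[1]], end_s[bad_iv[1]]))
  df <- data.frame(kind = kind, start_s = start_s, end_s = end_s,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start_s, df$end_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("namts_annotations", "data.frame")
  df
}

#' Read a recording from disk
#'
#' Two dialects are supported. `fixture_csv` is the package's bit-exact
#' plain-text reference format: a directory with one `<CHANNEL>.csv` per
#' channel (a `# rate=<float>` metadata line, then a `value` column) and an
#' `annotations.json` file. `edf` reads a European Data Format file
#' (read-only).
#'
#' @param path Directory (fixture dialect) or `.edf` file.
#' @param dialect `"fixture_csv"` or `"edf"`.
#' @param channel_map Named character vector mapping raw channel labels to
#'   canonical names, e.g. `c("Flow Patient" = "NP")`. Canonical labels map
#'   to themselves by default; unmapped channels are dropped with a warning.
#' @param require_all If `TRUE` (default) all seven source channels must be
#'   present; a missing one is an error naming the channel.
#' @return A [recording()].
#' @export
read_recording <- function(path, dialect = c("fixture_csv", "edf"),
                           channel_map = NULL, require_all = TRUE) {
  dialect <- match.arg(dialect)
  raw <- switch(dialect,
    fixture_csv = read_fixture_channels(path),
    edf = read_edf_channels(path))
  map <- stats::setNames(CANONICAL_CHANNELS, CANONICAL_CHANNELS)
  if (!is.null(channel_map)) map[names(channel_map)] <- unname(channel_map)
  chans <- list()
  for (nm in names(raw)) {
    if (nm %in% names(map)) {
      canon <- map[[nm]]
      chans[[canon]] <- channel(canon, raw[[nm]]$samples, raw[[nm]]$rate,
                                unit = raw[[nm]]$unit %||% CHANNEL_UNITS[[canon]])
    } else {
      warning(sprintf("dropping unmapped channel '%s'", nm), call. = FALSE)
    }
  }
  if (require_all) {
    missing <- setdiff(CANONICAL_CHANNELS, names(chans))
    if (length(missing))
      stop(sprintf("missing channel %s", missing[1]))
  }
  pid <- if (dialect == "fixture_csv") basename(normalizePath(path))
         else sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  recording(pid, chans)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_fixture_channels <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: %s", dir))
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop(sprintf("no channel CSVs under %s", dir))
  out <- list()
  for (f in files) {
    nm <- sub("\\.csv$", "", basename(f))
    first <- readLines(f, n = 1L)
    m <- regmatches(first, regexec("^#\\s*rate=([0-9.eE+-]+)", first))[[1]]
    if (length(m) < 2) stop(sprintf("missing '# rate=' header in %s", f))
    rate <- as.numeric(m[2])
    vals <- utils::read.csv(f, comment.char = "#")
    if (!"value" %in% names(vals))
      stop(sprintf("missing 'value' column in %s", f))
    out[[nm]] <- list(samples = as.numeric(vals$value), rate = rate)
  }
  out
}

#' Read an annotation track
#'
#' Accepts JSON (an array of objects with fields `kind`, `start_s`, `end_s`)
#' or CSV with those columns. Rows are validated (known kind,
#' `end_s > start_s`) and returned sorted by start time.
#'
#' @param path Path to a `.json` or `.csv` annotation file.
#' @return A [annotations()] table (possibly empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt)) || trimws(txt) == "[]")
      return(annotations())
    df <- jsonlite::fromJSON(txt)
  } else {
    df <- utils::read.csv(path)
    if (!nrow(df)) return(annotations())
  }
  if (!nrow(df)) return(annotations())
  need <- c("kind", "start_s", "end_s")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns kind, start_s, end_s")
  annotations(df$kind, df$start_s, df$end_s)
}

#' Write a recording and its annotations in the fixture dialect
#'
#' The fixture dialect is the bit-exact plain-text reference format:
#' `read_recording(dir, "fixture_csv")` reproduces the samples bit-exactly
#' and the annotation intervals exactly. Values are serialized with 17
#' significant digits, which round-trips IEEE doubles.
#'
#' @param rec A [recording()].
#' @param ann A [annotations()] table (may be empty).
#' @param dir Output directory, created if needed; files go to
#'   `dir/<patient_id>/`.
#' @return Invisibly, the patient directory written.
#' @export
write_fixture <- function(rec, ann, dir) {
  stopifnot(inherits(rec, "namts_recording"))
  pdir <- file.path(dir, rec$patient_id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(pdir)) stop(sprintf("cannot create directory %s", pdir))
  for (ch in rec$channels) {
    if (!length(ch$samples))
      stop(sprintf("refusing to write 0-length channel %s", ch$name))
    f <- file.path(pdir, paste0(ch$name, ".csv"))
    con <- file(f, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("# rate=%.17g", ch$rate), con)
    writeLines("value", con)
    writeLines(formatC(ch$samples, format = "g", digits = 17), con)
    close(con)
    on.exit()
  }
  ann_list <- if (nrow(ann) == 0) list() else
    lapply(seq_len(nrow(ann)), function(i)
      list(kind = ann$kind[i], start_s = ann$start_s[i], end_s = ann$end_s[i]))
  jsonlite::write_json(ann_list, file.path(pdir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(pdir)
}
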