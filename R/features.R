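## The 24 engineered features for the baseline classifiers: six per
## oscillatory modality (time-domain skewness and excess kurtosis, spectral
## centroid, spread, skewness and raw kurtosis), two per slow modality
## (mean and range). Conventions are pinned by tests: population moments
## throughout; the spectral distribution is the DC-excluded normalized
## periodogram.

#' Canonical names of the 24 engineered features
#' @format Character vector of length 24, `<MODALITY>_<feature>`.
#' @export
FEATURE_NAMES <- c(
  as.vector(t(outer(FAST_MODALITIES,
                    c("time_skewness", "time_kurtosis", "spec_centroid",
                      "spec_spread", "spec_skewness", "spec_kurtosis"),
                    paste, sep = "_"))),
  as.vector(t(outer(SLOW_MODALITIES, c("mean", "range"), paste, sep = "_"))))

#' Time-domain moment features
#'
#' Population skewness `m3/sd^3` and excess kurtosis `m4/sd^4 - 3`. A
#' (near-)constant signal returns `(0, 0)` by guard.
#'
#' @param x Numeric samples, length >= 4.
#' @return Named numeric vector `c(skewness, kurtosis)`.
#' @export
time_moments <- function(x) {
  stopifnot(length(x) >= 4)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 < 1e-24) return(c(skewness = 0, kurtosis = 0))
  c(skewness = mean((x - m)^3) / s2^1.5,
    kurtosis = mean((x - m)^4) / s2^2 - 3)
}

#' Spectral-shape features
#'
#' Treats the DC-excluded, sum-normalized periodogram (squared real-FFT
#' magnitudes up to Nyquist) as a probability distribution over frequency
#' and returns its centroid (Hz), spread (Hz, the distribution's sd), and
#' standardized skewness and *raw* (non-excess) kurtosis. An all-zero signal
#' returns all zeros; a spectrally degenerate one (spread below `1e-12`)
#' returns zero skewness and kurtosis.
#'
#' @param x Numeric samples, length >= 8.
#' @param rate Sampling rate (Hz).
#' @return Named numeric vector `c(centroid, spread, skewness, kurtosis)`.
#' @export
spectral_moments <- function(x, rate) {
  stopifnot(length(x) >= 8)
  n <- length(x)
  sp <- Mod(fft(x))^2
  kmax <- floor(n / 2)
  p <- sp[2:(kmax + 1)]                     # bins 1..Nyquist, DC excluded
  f <- (1:kmax) * rate / n
  tot <- sum(p)
  if (tot < 1e-24)
    return(c(centroid = 0, spread = 0, skewness = 0, kurtosis = 0))
  p <- p / tot
  centroid <- sum(f * p)
  v <- sum((f - centroid)^2 * p)
  spread <- sqrt(max(v, 0))
  if (spread < 1e-12)
    return(c(centroid = centroid, spread = 0, skewness = 0, kurtosis = 0))
  c(centroid = centroid, spread = spread,
    skewness = sum((f - centroid)^3 * p) / spread^3,
    kurtosis = sum((f - centroid)^4 * p) / spread^4)
}

#' Mean and range of a slow modality
#'
#' @param x Numeric samples (nonempty).
#' @return Named numeric vector `c(mean, range)` with
#'   `range = max(x) - min(x)`.
#' @export
slow_features <- function(x) {
  stopifnot(length(x) >= 1)
  c(mean = mean(x), range = max(x) - min(x))
}

#' Compute the 24-feature vector of a model input
#'
#' Features are computed on the preprocessed modalities (post decimation
#' and normalization), so the oscillatory features are scale-invariant by
#' construction. Order: for each of NP, TA, PPG the six
#' time/spectral moments, then for each of HR, SPO2, PCO2 the mean and
#' range; names follow `<MODALITY>_<feature>`.
#'
#' @param m A `namts_model_input` from [prepare_window()].
#' @return Named numeric vector of length 24.
#' @export
featurize <- function(m) {
  stopifnot(inherits(m, "namts_model_input"))
  out <- numeric(0)
  for (mod in FAST_MODALITIES) {
    tm <- time_moments(m[[mod]])
    sm <- spectral_moments(m[[mod]], rate = 5)
    out <- c(out, tm, sm)
  }
  for (mod in SLOW_MODALITIES) out <- c(out, slow_features(m[[mod]]))
  names(out) <- FEATURE_NAMES
  out
}

#' Feature table for a window set
#'
#' @param ds A `namts_window_set`.
#' @return data.frame with the 24 feature columns plus `label` and
#'   `patient`.
#' @export
feature_table <- function(ds) {
  stopifnot(inherits(ds, "namts_window_set"))
  n <- n_windows(ds)
  feats <- matrix(0, n, 24, dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    out <- numeric(0)
    for (mod in FAST_MODALITIES) {
      x <- ds$x[[mod]][i, ]
      out <- c(out, time_moments(x), spectral_moments(x, rate = 5))
    }
    for (mod in SLOW_MODALITIES) out <- c(out, slow_features(ds$x[[mod]][i, ]))
    feats[i, ] <- out
  }
  cbind(as.data.frame(feats),
        data.frame(label = ds$label, patient = ds$patient,
                   stringsAsFactors = FALSE))
}
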