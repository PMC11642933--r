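#' Permutation test of better-than-chance AuROC
#'
#' Builds the null distribution by permuting the class labels `n_perm`
#' times and recomputing the AuROC; the one-sided p-value uses the add-one
#' formula `p = (1 + #(null >= observed)) / (1 + n_perm)`, so it is never
#' zero. Typically applied per patient, permuting labels within that
#' patient's test set only.
#'
#' @param scores,labels As in [auroc()]; both classes must be present.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A `namts_test_result`: `statistic` (observed AuROC), `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test_auroc <- function(scores, labels, n_perm = 999, seed = 0L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("permutation test needs both classes")
  stopifnot(n_perm >= 99)
  r <- rank(scores)                      # fixed under label permutation
  auc_of <- function(pos_idx)
    (sum(r[pos_idx]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  observed <- auc_of(which(labels == 1))
  set.seed(seed)
  n <- length(labels)
  null <- vapply(seq_len(n_perm),
                 function(i) auc_of(sample.int(n, n1)), numeric(1))
  structure(list(statistic = observed,
                 p_value = (1 + sum(null >= observed)) / (1 + n_perm),
                 n_permutations = n_perm, seed = as.integer(seed)),
            class = "namts_test_result")
}

#' Wilcoxon signed-rank test (paired, two-sided)
#'
#' Zero differences are dropped. For up to 25 remaining pairs the null
#' distribution of the positive-rank sum is computed exactly by dynamic
#' programming over the (mid)ranks, which stays exact under ties; above 25
#' pairs a normal approximation with tie correction and continuity
#' correction is used. If all differences are zero the p-value is 1.
#'
#' @param a,b Equal-length paired measurements (e.g. per-patient AuROCs of
#'   two models).
#' @return A `namts_test_result`: `statistic` (positive-rank sum W+),
#'   `p_value`, `n_pairs` (after dropping zeros), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = 0, p_value = 1, n_pairs = 0,
                          method = "degenerate"),
                     class = "namts_test_result"))
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  if (n <= 25) {
    ## exact: distribution of W+ over all 2^n sign assignments via DP on
    ## doubled ranks (midranks may be half-integers)
    r2 <- as.integer(round(2 * rk))
    total <- sum(r2)
    cnt <- numeric(total + 1)            # cnt[s+1] = #assignments with 2W+ = s
    cnt[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), cnt[seq_len(total + 1 - r)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(list(statistic = w, p_value = p, n_pairs = n, method = method),
            class = "namts_test_result")
}

#' @export
print.namts_test_result <- function(x, ...) {
  cat(sprintf("<namts_test_result> statistic %.4f, p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}
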