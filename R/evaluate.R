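#' Per-patient class balancing by undersampling
#'
#' Within each patient the majority class is randomly subsampled without
#' replacement down to the minority count (symmetric: usually controls are
#' the majority, but the rule also covers patients where targets dominate).
#' Patients with only one class contribute nothing and are excluded with a
#' warning.
#'
#' @param ds A `namts_window_set`.
#' @param seed Integer seed; the selection is reproducible.
#' @return A balanced `namts_window_set` (equal class counts per patient).
#' @export
undersample <- function(ds, seed = 0L) {
  stopifnot(inherits(ds, "namts_window_set"))
  set.seed(seed)
  keep <- integer(0)
  for (p in unique(ds$patient)) {
    idx <- which(ds$patient == p)
    pos <- idx[ds$label[idx] == 1]
    neg <- idx[ds$label[idx] == 0]
    m <- min(length(pos), length(neg))
    if (m == 0) {
      warning(sprintf("patient %s has a single class; excluded from training",
                      p), call. = FALSE)
      next
    }
    keep <- c(keep,
              if (length(pos) > m) sample(pos, m) else pos,
              if (length(neg) > m) sample(neg, m) else neg)
  }
  if (!length(keep)) stop("no patient retains both classes")
  subset_window_set(ds, sort(keep))
}

#' Area under the ROC curve
#'
#' The probability that a random positive outscores a random negative,
#' counting ties as 1/2 (equivalently the trapezoidal ROC area), computed
#' from midranks.
#'
#' @param scores Numeric scores (higher = more target-like).
#' @param labels Binary labels (1 = positive).
#' @return AuROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Operating-point metrics at a fixed false positive rate
#'
#' Chooses the smallest score threshold whose empirical FPR does not exceed
#' `fpr_target` (windows scoring at or above the threshold are called
#' positive) and reports the true positive rate, precision, and the 2x2
#' confusion matrix at that threshold.
#'
#' @param scores,labels As in [auroc()].
#' @param fpr_target Maximum tolerated false positive rate in `[0, 1]`.
#' @return List with `threshold`, `tpr`, `precision` (NA when nothing is
#'   called positive), `fpr`, and `confusion` (2x2 matrix, rows = truth,
#'   columns = call).
#' @export
metrics_at_fpr <- function(scores, labels, fpr_target) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("metrics need both classes")
  thr <- Inf
  for (t in sort(unique(scores))) {
    if (mean(neg >= t) <= fpr_target) { thr <- t; break }
  }
  tp <- sum(pos >= thr); fn <- length(pos) - tp
  fp <- sum(neg >= thr); tn <- length(neg) - fp
  list(threshold = thr,
       tpr = tp / length(pos),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       fpr = fp / length(neg),
       confusion = matrix(c(tp, fp, fn, tn), 2, 2,
                          dimnames = list(truth = c("target", "control"),
                                          call = c("target", "control"))))
}

#' Evaluation configuration
#'
#' @param train A [train_config()]; its seed is re-derived per run.
#' @param n_runs Training repetitions per fold (per-patient performances are
#'   averaged over runs).
#' @param inner_k Inner grouped cross-validation folds for hyperparameter
#'   selection (capped at the number of training patients).
#' @param fpr_levels FPR levels for operating-point metrics.
#' @param n_perm Label permutations for the per-patient significance test.
#' @param seed Master seed.
#' @return A list of class `namts_eval_config`.
#' @export
eval_config <- function(train = train_config(), n_runs = 1, inner_k = 5,
                        fpr_levels = c(0.1, 0.2, 0.3), n_perm = 999,
                        seed = 0L) {
  structure(list(train = train, n_runs = n_runs, inner_k = inner_k,
                 fpr_levels = fpr_levels, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "namts_eval_config")
}

## Fit the requested model kind on a (balanced) training window set and
## return a scoring closure. Feature baselines get the 24-feature table.
fit_model_kind <- function(kind, ds_train, hp, tcfg) {
  if (kind %in% c("nam", "blackbox")) {
    model <- if (kind == "nam") build_nam(hp, seed = tcfg$seed)
             else build_blackbox(hp, seed = tcfg$seed)
    model <- train_model(model, ds_train, tcfg)
    list(model = model,
         score = function(ds) net_predict(model, ds)$probability)
  } else {
    ft <- feature_table(ds_train)
    fit <- fit_baseline(kind, ft[, FEATURE_NAMES], ft$label,
                        seed = tcfg$seed)
    list(model = fit,
         score = function(ds)
           predict(fit, feature_table(ds)[, FEATURE_NAMES]))
  }
}

## Inner grouped k-fold hyperparameter selection over `grid`; groups are
## patients. Returns the winning grid index (ties: smaller kernel, then
## fewer channels, then grid order).
select_hyperparams <- function(ds_train, kind, grid, cfg) {
  if (length(grid) == 1) return(1L)
  pts <- unique(ds_train$patient)
  k <- max(2L, min(cfg$inner_k, length(pts)))
  fold_of <- setNames(rep_len(seq_len(k), length(pts)), pts)
  score <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    aucs <- c()
    for (fold in seq_len(k)) {
      val_idx <- which(fold_of[ds_train$patient] == fold)
      if (!length(val_idx)) next
      val <- subset_window_set(ds_train, val_idx)
      if (length(unique(val$label)) < 2) next
      tr <- subset_window_set(ds_train, setdiff(seq_len(n_windows(ds_train)),
                                                val_idx))
      tcfg <- cfg$train
      tcfg$seed <- cfg$seed * 100L + fold
      bal <- suppressWarnings(undersample(tr, seed = tcfg$seed))
      fm <- fit_model_kind(kind, bal, grid[[gi]], tcfg)
      aucs <- c(aucs, auroc(fm$score(val), val$label))
    }
    score[gi] <- if (length(aucs)) mean(aucs) else 0
  }
  best <- which(score == max(score))
  if (length(best) > 1 && kind %in% c("nam", "blackbox")) {
    ks <- vapply(grid[best], `[[`, numeric(1), "kernel_size")
    best <- best[ks == min(ks)]
    hc <- vapply(grid[best], `[[`, numeric(1), "hidden_channels")
    best <- best[hc == min(hc)]
  }
  best[1]
}

#' Patient-based leave-one-out cross-validation
#'
#' For each held-out patient the model is trained on all other patients'
#' windows (class-balanced per patient by [undersample()]) and evaluated on
#' every window of the held-out patient (never rebalanced). When the
#' hyperparameter grid has more than one point, an inner grouped k-fold over
#' the training patients selects it; the held-out patient's windows never
#' enter the inner folds. Training is repeated `n_runs` times with derived
#' seeds; per-patient scores are averaged over runs.
#'
#' @param ds A `namts_window_set` covering >= 3 patients.
#' @param kind `"nam"`, `"blackbox"`, `"logreg"` or `"mlp"`.
#' @param grid List of [hyperparams()] candidates (ignored by feature
#'   baselines beyond its length-1 requirement).
#' @param cfg An [eval_config()].
#' @return A `namts_cv_report`: `per_patient` data.frame (AuROC, TPR and
#'   precision at the configured FPR levels, permutation p-value, chosen
#'   hyperparameters, seeds), `aggregate` summary, `roc` (vertically
#'   averaged ROC on a 101-point FPR grid), and `predictions` (per-window
#'   mean scores, labels, patients, and for NAMs additive contributions).
#' @export
loocv <- function(ds, kind = c("nam", "blackbox", "logreg", "mlp"),
                  grid = list(hyperparams()), cfg = eval_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(ds, "namts_window_set"))
  if (!length(grid)) stop("hyperparameter grid must be nonempty")
  patients <- unique(ds$patient)
  if (length(patients) < 3) stop("leave-one-out needs >= 3 patients")
  fpr_grid <- seq(0, 1, length.out = 101)
  rows <- list(); preds <- list(); tprs <- list(); audit <- list()
  is_nam <- kind == "nam"
  contribs <- NULL
  for (p in patients) {
    test_idx <- which(ds$patient == p)
    train_idx <- which(ds$patient != p)
    stopifnot(length(intersect(test_idx, train_idx)) == 0)
    test <- subset_window_set(ds, test_idx)
    if (length(unique(test$label)) < 2) {
      warning(sprintf("patient %s has a single class in its test set; skipped",
                      p), call. = FALSE)
      next
    }
    tr_full <- subset_window_set(ds, train_idx)
    audit[[p]] <- unique(tr_full$patient)
    gi <- select_hyperparams(tr_full, kind, grid, cfg)
    hp <- grid[[gi]]
    run_auc <- numeric(cfg$n_runs)
    run_scores <- matrix(0, length(test_idx), cfg$n_runs)
    run_metrics <- vector("list", cfg$n_runs)
    run_contrib <- NULL
    for (r in seq_len(cfg$n_runs)) {
      tcfg <- cfg$train
      tcfg$seed <- cfg$seed * 1000L + match(p, patients) * 10L + r
      bal <- suppressWarnings(undersample(tr_full, seed = tcfg$seed))
      fm <- fit_model_kind(kind, bal, hp, tcfg)
      sc <- fm$score(test)
      run_scores[, r] <- sc
      run_auc[r] <- auroc(sc, test$label)
      run_metrics[[r]] <- lapply(cfg$fpr_levels, function(f)
        metrics_at_fpr(sc, test$label, f))
      if (is_nam && r == cfg$n_runs)
        run_contrib <- net_predict(fm$model, test)$contributions
    }
    mean_scores <- rowMeans(run_scores)
    perm <- permutation_test_auroc(mean_scores, test$label,
                                   n_perm = cfg$n_perm,
                                   seed = cfg$seed + match(p, patients))
    row <- data.frame(patient = p, auroc = mean(run_auc),
                      auroc_sd_runs = if (cfg$n_runs > 1) sd(run_auc) else 0,
                      n_windows = length(test_idx),
                      n_target = sum(test$label == 1),
                      p_perm = perm$p_value,
                      kernel_size = if (is.null(hp$kernel_size)) NA else
                        hp$kernel_size,
                      hidden_channels = if (is.null(hp$hidden_channels)) NA
                        else hp$hidden_channels,
                      stringsAsFactors = FALSE)
    for (fi in seq_along(cfg$fpr_levels)) {
      f <- cfg$fpr_levels[fi]
      row[[sprintf("tpr_at_%d", round(100 * f))]] <-
        mean(vapply(run_metrics, function(m) m[[fi]]$tpr, numeric(1)))
      row[[sprintf("precision_at_%d", round(100 * f))]] <-
        mean(vapply(run_metrics, function(m) m[[fi]]$precision, numeric(1)),
             na.rm = TRUE)
    }
    rows[[p]] <- row
    tprs[[p]] <- roc_tpr_at(mean_scores, test$label, fpr_grid)
    preds[[p]] <- data.frame(patient = p, start_s = test$start_s,
                             label = test$label, score = mean_scores,
                             stringsAsFactors = FALSE)
    if (is_nam) contribs <- rbind(contribs, run_contrib)
  }
  if (!length(rows)) stop("no evaluable patients")
  per_patient <- do.call(rbind, rows)
  rownames(per_patient) <- NULL
  tpr_mat <- do.call(rbind, tprs)
  report <- list(
    kind = kind,
    per_patient = per_patient,
    aggregate = list(
      mean_auroc = mean(per_patient$auroc),
      sd_auroc = sd(per_patient$auroc),
      median_auroc = median(per_patient$auroc),
      metrics = aggregate_metrics(per_patient, cfg$fpr_levels)),
    roc = data.frame(fpr = fpr_grid,
                     tpr_mean = colMeans(tpr_mat),
                     tpr_sd = apply(tpr_mat, 2, sd)),
    predictions = do.call(rbind, preds),
    contributions = contribs,
    audit = audit,
    cfg = cfg)
  class(report) <- "namts_cv_report"
  report
}

## Median (25-75%) of the per-patient operating-point metrics, as percent.
aggregate_metrics <- function(per_patient, fpr_levels) {
  out <- list()
  for (f in fpr_levels) {
    for (what in c("tpr", "precision")) {
      col <- sprintf("%s_at_%d", what, round(100 * f))
      q <- quantile(per_patient[[col]], c(0.25, 0.5, 0.75), na.rm = TRUE)
      out[[col]] <- c(median = unname(q[2]) * 100,
                      q25 = unname(q[1]) * 100, q75 = unname(q[3]) * 100)
    }
  }
  out
}

## Staircase TPR at given FPR grid points (vertical ROC averaging).
roc_tpr_at <- function(scores, labels, fpr_grid) {
  o <- order(scores, decreasing = TRUE)
  y <- as.integer(labels)[o]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- cumsum(y == 1) / n1
  fpr <- cumsum(y == 0) / n0
  ## collapse tied scores to their last (most permissive) point
  keep <- rev(!duplicated(rev(scores[o])))
  pts_f <- c(0, fpr[keep], 1)
  pts_t <- c(0, tpr[keep], 1)
  vapply(fpr_grid, function(g) max(pts_t[pts_f <= g + 1e-12]), numeric(1))
}

#' @export
print.namts_cv_report <- function(x, ...) {
  cat(sprintf("<namts_cv_report> %s, %d patients: mean AuROC %.3f (sd %.3f)\n",
              x$kind, nrow(x$per_patient), x$aggregate$mean_auroc,
              x$aggregate$sd_auroc))
  invisible(x)
}

#' Prediction-horizon sweep
#'
#' Re-extracts target windows at each horizon (controls are unaffected) and
#' runs a full [loocv()] per horizon.
#'
#' @param recordings,anns Cohort as from [generate_cohort()].
#' @param horizons Numeric vector of horizons (s).
#' @param kind,grid,cfg Passed to [loocv()].
#' @param wcfg Base [windowing_config()].
#' @return List with `auroc` (named numeric, mean LOOCV AuROC per horizon)
#'   and `reports` (the per-horizon `namts_cv_report`s).
#' @export
horizon_curve <- function(recordings, anns, horizons = c(0, 15, 150),
                          kind = "nam", grid = list(hyperparams()),
                          cfg = eval_config(), wcfg = windowing_config()) {
  stopifnot(all(horizons >= 0))
  reports <- list()
  for (h in horizons) {
    wcfg$horizon_s <- h
    ds <- cohort_window_set(recordings, anns, wcfg)
    if (is.null(ds)) stop(sprintf("no windows at horizon %g", h))
    reports[[as.character(h)]] <- loocv(ds, kind, grid, cfg)
  }
  list(auroc = vapply(reports, function(r) r$aggregate$mean_auroc,
                      numeric(1)),
       reports = reports)
}

#' Modality importance from additive contributions
#'
#' The spread of a modality's additive contributions across windows measures
#' how much it moves the classification; modalities are ranked by the pooled
#' standard deviation, with per-patient standard deviations reported
#' alongside.
#'
#' @param contributions Windows x modalities matrix of additive
#'   contributions (e.g. `loocv(...)$contributions` or
#'   `net_predict(...)$contributions`).
#' @param patients Character vector assigning each row to a patient.
#' @return List with `pooled_sd` (named, sorted decreasing), `ranking`
#'   (modality names, most important first) and `per_patient_sd`
#'   (patients x modalities matrix).
#' @export
modality_importance <- function(contributions, patients) {
  stopifnot(is.matrix(contributions), nrow(contributions) >= 1,
            nrow(contributions) == length(patients))
  pooled <- apply(contributions, 2, function(v) sqrt(mean((v - mean(v))^2)))
  pp <- t(vapply(unique(patients), function(p)
    apply(contributions[patients == p, , drop = FALSE], 2,
          function(v) sqrt(mean((v - mean(v))^2))),
    numeric(ncol(contributions))))
  rownames(pp) <- unique(patients)
  list(pooled_sd = sort(pooled, decreasing = TRUE),
       ranking = names(sort(pooled, decreasing = TRUE)),
       per_patient_sd = pp)
}

#' Single-modality and reduced-model ablation suite
#'
#' Trains and evaluates a single-modality network for each requested
#' modality, plus optional reduced models on modality subsets, each under
#' the full leave-one-patient-out protocol.
#'
#' @param ds A `namts_window_set`.
#' @param modalities Modalities to ablate individually.
#' @param subsets Optional named list of modality subsets for reduced
#'   models.
#' @param grid,cfg As in [loocv()]; each grid point is re-fit with the
#'   restricted modality set.
#' @return Named list of `namts_cv_report`s (one per modality/subset).
#' @export
single_modality_suite <- function(ds, modalities = MODALITIES,
                                  subsets = NULL,
                                  grid = list(hyperparams()),
                                  cfg = eval_config()) {
  runs <- c(as.list(setNames(modalities, modalities)), subsets)
  lapply(runs, function(mods) {
    g <- lapply(grid, function(hp) {
      hp$modalities <- mods
      hp
    })
    loocv(ds, "nam", g, cfg)
  })
}
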