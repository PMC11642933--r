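test_that("undersampling balances classes within each patient", {
  ds <- toy_window_set(50)
  ds$patient <- rep("A", 50)
  ds$label <- c(rep(1L, 10), rep(0L, 40))
  bal <- undersample(ds, seed = 1)
  expect_equal(sum(bal$label == 1), 10)
  expect_equal(sum(bal$label == 0), 10)

  ## symmetric rule: targets can be the majority
  ds$label <- c(rep(1L, 9), rep(0L, 5), rep(1L, 36))
  bal2 <- undersample(ds, seed = 1)
  expect_equal(sum(bal2$label == 1), 5)
  expect_equal(sum(bal2$label == 0), 5)

  ## determinism
  ds$label <- c(rep(1L, 10), rep(0L, 40))
  expect_identical(undersample(ds, seed = 7)$start_s,
                   undersample(ds, seed = 7)$start_s)

  ## single-class patients are excluded with a warning
  ds2 <- toy_window_set(20)
  ds2$patient <- rep(c("A", "B"), each = 10)
  ds2$label <- c(rep(0L, 10), rep(c(0L, 1L), 5))
  expect_warning(bal3 <- undersample(ds2, seed = 1), "single class")
  expect_false("A" %in% bal3$patient)
})

test_that("auroc matches hand values and the pairwise oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_error(auroc(1:5, rep(1, 5)), "both classes")

  set.seed(16)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(auroc(scores, labels),
                     auroc_pairwise(scores, labels))
  }
})

test_that("metrics_at_fpr picks the least strict admissible threshold", {
  ## perfect separation
  m <- metrics_at_fpr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.2)
  expect_equal(m$tpr, 1)
  expect_equal(m$precision, 1)
  expect_equal(sum(m$confusion), 4)

  ## zero tolerated FPR forces the threshold above the best negative
  m2 <- metrics_at_fpr(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0), 0)
  expect_equal(m2$threshold, 0.9)
  expect_equal(m2$tpr, 0.5)
  expect_equal(m2$precision, 1)
  expect_equal(m2$fpr, 0)

  ## with random scores the achieved FPR tracks the target
  set.seed(17)
  sc <- runif(4000)
  lab <- rep(0:1, 2000)
  m3 <- metrics_at_fpr(sc, lab, 0.3)
  expect_lt(abs(m3$tpr - 0.3), 0.05)
  expect_lte(m3$fpr, 0.3)
  expect_gt(m3$fpr, 0.25)

  ## confusion matrix is consistent
  expect_equal(m3$confusion["target", "target"] +
                 m3$confusion["target", "control"], 2000)
})

test_that("loocv keeps patients separated and aggregates correctly", {
  ds <- test_window_set()
  ## logreg keeps this test light; the protocol code is shared across kinds
  rep <- loocv(ds, "logreg", cfg = eval_config(n_perm = 199, seed = 3))
  expect_s3_class(rep, "namts_cv_report")
  expect_equal(nrow(rep$per_patient), 4)

  ## provenance audit: the held-out patient never trains its own fold
  for (p in rep$per_patient$patient)
    expect_false(p %in% rep$audit[[p]])

  ## aggregate statistics are pure functions of per-patient entries
  expect_equal(rep$aggregate$mean_auroc, mean(rep$per_patient$auroc))
  expect_equal(rep$aggregate$sd_auroc, sd(rep$per_patient$auroc))
  q <- quantile(rep$per_patient$tpr_at_20, c(0.25, 0.5, 0.75))
  expect_equal(unname(rep$aggregate$metrics$tpr_at_20), unname(q[c(2, 1, 3)]) * 100)

  ## engineered features separate the strong synthetic cohort
  expect_gt(rep$aggregate$mean_auroc, 0.9)

  ## predictions cover every window of every patient exactly once
  expect_equal(nrow(rep$predictions), length(ds$label))

  expect_error(loocv(ds, "logreg", grid = list()), "nonempty")
})

test_that("nested hyperparameter selection prefers simpler ties", {
  ## every inner validation fold is single-class, so all grid points tie
  ## at score zero and the deterministic tie-break (smaller kernel, then
  ## fewer channels) must decide
  ds <- toy_window_set(40)
  ds$patient <- rep(c("A", "B", "C", "D"), each = 10)
  ds$label <- rep(c(1L, 1L, 0L, 0L), each = 10)
  grid <- list(hyperparams(kernel_size = 9, hidden_channels = 8),
               hyperparams(kernel_size = 5, hidden_channels = 8),
               hyperparams(kernel_size = 5, hidden_channels = 4))
  gi <- namts:::select_hyperparams(ds, "nam", grid, eval_config())
  expect_equal(grid[[gi]]$kernel_size, 5)
  expect_equal(grid[[gi]]$hidden_channels, 4)

  ## real nested selection runs with a multi-point grid (baseline kind
  ## ignores the hyperparameters, so both points tie at identical scores
  ## and the first wins)
  ds2 <- test_window_set()
  gi2 <- namts:::select_hyperparams(ds2, "logreg",
                                    list(hyperparams(), hyperparams()),
                                    eval_config(seed = 2))
  expect_equal(gi2, 1L)
})

test_that("a singleton horizon sweep reproduces the plain protocol", {
  coh <- test_cohort()
  hz <- horizon_curve(coh$recordings, coh$annotations, horizons = 15,
                      kind = "logreg", cfg = eval_config(n_perm = 99,
                                                         seed = 3))
  direct <- loocv(cohort_window_set(coh$recordings, coh$annotations),
                  "logreg", cfg = eval_config(n_perm = 99, seed = 3))
  expect_named(hz$auroc, "15")
  expect_equal(unname(hz$auroc[["15"]]), direct$aggregate$mean_auroc)
  expect_equal(hz$reports[["15"]]$per_patient$auroc,
               direct$per_patient$auroc)
})

test_that("modality importance ranks by contribution spread", {
  set.seed(18)
  contrib <- cbind(NP = rnorm(100, sd = 2), TA = rnorm(100, sd = 0.5),
                   SPO2 = rnorm(100, sd = 1))
  imp <- modality_importance(contrib, rep(c("A", "B"), 50))
  expect_equal(imp$ranking[1], "NP")
  expect_equal(names(imp$pooled_sd), imp$ranking)
  ## pooled sd is recomputable from the stored contributions
  expect_equal(unname(imp$pooled_sd["NP"]),
               sqrt(mean((contrib[, "NP"] - mean(contrib[, "NP"]))^2)))
  expect_equal(dim(imp$per_patient_sd), c(2, 3))

  ## an untrained zeroed model yields all-zero spreads
  zero <- matrix(0, 10, 3, dimnames = list(NULL, c("NP", "TA", "SPO2")))
  imp0 <- modality_importance(zero, rep("A", 10))
  expect_true(all(imp0$pooled_sd == 0))
})

test_that("roc staircase interpolation brackets the AuROC", {
  set.seed(19)
  sc <- runif(200); lab <- rbinom(200, 1, plogis(3 * sc - 1.5))
  if (length(unique(lab)) == 2) {
    tpr <- namts:::roc_tpr_at(sc, lab, seq(0, 1, length.out = 101))
    expect_true(all(diff(tpr) >= 0))
    expect_equal(tpr[101], 1)
    ## trapezoid over the fine grid approximates the exact AuROC
    expect_lt(abs(mean(tpr[-1] + tpr[-101]) / 2 - auroc(sc, lab)), 0.03)
  }
})
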