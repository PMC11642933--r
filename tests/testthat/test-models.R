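hp_small <- hyperparams(kernel_size = 5, hidden_channels = 4,
                        n_conv_layers = 2)

test_that("model construction follows the hyperparameters and seed", {
  nam <- build_nam(hyperparams(), seed = 1)
  expect_length(nam$par$subnets, 6)
  expect_length(nam$par$subnets$NP$layers, 3)
  expect_equal(ncol(nam$par$subnets$NP$layers[[1]]$conv$W), 9 * 20)

  reduced <- build_nam(hyperparams(modalities = c("NP", "TA", "SPO2")), 1)
  expect_setequal(names(reduced$par$subnets), c("NP", "TA", "SPO2"))

  a <- build_nam(hp_small, seed = 7)
  b <- build_nam(hp_small, seed = 7)
  expect_identical(a$par, b$par)
  expect_false(identical(build_nam(hp_small, 8)$par, a$par))

  expect_error(hyperparams(modalities = character(0)))
  expect_error(hyperparams(kernel_size = 8))   # even
  expect_error(hyperparams(kernel_size = 19))  # out of range

  bb <- build_blackbox(hyperparams(), 1)
  expect_equal(nrow(bb$par$mlp1$W), 6 * 20)    # 120 concatenated features
})

test_that("a zeroed network predicts exactly one half", {
  nam <- build_nam(hp_small, 1)
  nam$par <- namts:::walk_params(nam$par, NULL, function(p, g, path) {
    attrs <- attributes(p); p <- 0 * p; attributes(p) <- attrs; p
  })
  m <- prepare_window(toy_raw_window())
  pr <- nam_forward(nam, m)
  expect_equal(pr$probability, 0.5)
  expect_equal(unname(pr$contributions), rep(0, 6))
})

test_that("the additive identities hold to machine precision", {
  nam <- build_nam(hp_small, 2)
  ds <- toy_window_set(8)
  pr <- net_predict(nam, ds, maps = TRUE)
  expect_equal(pr$logit,
               rowSums(pr$contributions) + nam$par$beta,
               tolerance = 1e-12)
  for (m in namts:::MODALITIES)
    expect_equal(colMeans(pr$activation_maps[[m]]),
                 unname(pr$contributions[, m]), tolerance = 1e-12)

  ## single-window path agrees with the batch path
  mi <- prepare_window(toy_raw_window())
  one <- nam_forward(nam, mi)
  expect_equal(one$logit, sum(one$contributions) + one$bias,
               tolerance = 1e-12)
  expect_equal(unname(vapply(one$activation_maps, mean, numeric(1))),
               unname(one$contributions), tolerance = 1e-12)
})

test_that("perturbing one modality moves only its contribution", {
  nam <- build_nam(hp_small, 3)
  ds <- toy_window_set(4)
  base <- net_predict(nam, ds)
  ds2 <- ds
  ds2$x$SPO2 <- ds2$x$SPO2 + 0.5
  pert <- net_predict(nam, ds2)
  delta <- pert$contributions - base$contributions
  expect_true(all(abs(delta[, setdiff(colnames(delta), "SPO2")]) < 1e-12))
  expect_equal(pert$logit - base$logit, unname(delta[, "SPO2"]),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  ds <- toy_window_set(6, Tfast = 12, Tslow = 6)
  for (builder in list(build_nam, build_blackbox)) {
    model <- builder(hyperparams(kernel_size = 5, hidden_channels = 3,
                                 n_conv_layers = 2), seed = 1)
    xb <- namts:::batch_arrays(ds, 1:6, model$hp$modalities)
    loss_of <- function(mod) {
      fwd <- namts:::net_fwd(mod, xb, training = TRUE, cache = TRUE)
      p <- namts:::sigmoid(fwd$logit)
      list(loss = -mean(ds$label * log(p) + (1 - ds$label) * log(1 - p)),
           fwd = fwd)
    }
    lf <- loss_of(model)
    p <- namts:::sigmoid(lf$fwd$logit)
    grads <- namts:::net_bwd(model, lf$fwd, (p - ds$label) / 6)

    ## probe a representative parameter in every block type
    probe <- function(path) {
      g <- grads; pv <- model$par
      for (k in path) {
        kk <- if (!is.null(names(pv)) && k %in% names(pv)) k
              else as.integer(k)
        g <- g[[kk]]; pv <- pv[[kk]]
      }
      j <- 1L
      h <- 1e-5
      poke <- function(par, path, delta) {
        kk <- if (!is.null(names(par)) && path[1] %in% names(par)) path[1]
              else as.integer(path[1])
        if (length(path) == 1) par[[kk]][j] <- par[[kk]][j] + delta
        else par[[kk]] <- poke(par[[kk]], path[-1], delta)
        par
      }
      m2 <- model; m2$par <- poke(model$par, path, h)
      lp <- loss_of(m2)$loss
      m2$par <- poke(model$par, path, -h)
      lm <- loss_of(m2)$loss
      expect_equal(g[j], (lp - lm) / (2 * h), tolerance = 1e-4)
    }
    if (model$kind == "nam") {
      probe(c("subnets", "NP", "layers", "1", "conv", "W"))
      probe(c("subnets", "TA", "layers", "2", "bn_g"))
      probe(c("subnets", "SPO2", "collapse"))
      probe("beta")
    } else {
      probe(c("stacks", "NP", "layers", "1", "conv", "W"))
      probe(c("stacks", "HR", "layers", "2", "bn_b"))
      probe(c("mlp1", "W"))
      probe(c("mlp3", "b"))
    }
  }
})

test_that("training separates a strongly separable set within 10 epochs", {
  ds <- toy_window_set(120, separable = TRUE)
  nam <- train_model(build_nam(hyperparams(), 1), ds,
                     train_config(batch_size = 16, seed = 5))
  sc <- net_predict(nam, ds)$probability
  expect_gt(auroc(sc, ds$label), 0.95)
  expect_lt(tail(nam$training_log$loss, 1), nam$training_log$loss[1])
})

test_that("zero learning rate leaves parameters untouched", {
  ds <- toy_window_set(24)
  m0 <- build_nam(hp_small, 4)
  m1 <- train_model(m0, ds, train_config(lr = 0, seed = 1))
  expect_equal(m1$par$subnets$NP$layers[[1]]$conv$W,
               m0$par$subnets$NP$layers[[1]]$conv$W, tolerance = 1e-12)
  expect_equal(m1$par$beta, 0)
  expect_lt(diff(range(m1$training_log$loss)), 1e-9)
})

test_that("training is deterministic given data and seed", {
  ds <- toy_window_set(40)
  cfg <- train_config(epochs = 3, seed = 9)
  a <- train_model(build_nam(hp_small, 2), ds, cfg)
  b <- train_model(build_nam(hp_small, 2), ds, cfg)
  expect_identical(a$training_log$loss, b$training_log$loss)
  expect_equal(a$par, b$par, tolerance = 0)

  bb1 <- train_model(build_blackbox(hp_small, 2), ds, cfg)
  bb2 <- train_model(build_blackbox(hp_small, 2), ds, cfg)
  expect_identical(bb1$training_log$loss, bb2$training_log$loss)
})

test_that("evaluation-mode scoring is batch-independent", {
  ds <- toy_window_set(30)
  nam <- train_model(build_nam(hp_small, 5), ds,
                     train_config(epochs = 2, seed = 1))
  all_at_once <- net_predict(nam, ds)$probability
  one_by_one <- vapply(seq_len(30), function(i)
    net_predict(nam, namts:::subset_window_set(ds, i))$probability,
    numeric(1))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-12)
})

test_that("training requires both classes", {
  ds <- toy_window_set(10)
  ds$label <- rep(1L, 10)
  expect_error(train_model(build_nam(hp_small, 1), ds), "both classes")
})

test_that("feature baselines fit, predict and respect seeds", {
  ## linearly separable toy set
  set.seed(10)
  x <- matrix(rnorm(200 * 2), 200, 2)
  x <- x[abs(rowSums(x)) > 0.5, ][1:60, ]   # margin keeps it separable
  n <- nrow(x)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  fit <- fit_baseline("logreg", x, y)
  expect_equal(mean((predict(fit, x) > 0.5) == y), 1.0)

  ## permuted labels give chance-level cross-validated AuROC
  set.seed(11)
  xf <- matrix(rnorm(200 * 24), 200, 24)
  yperm <- sample(rep(0:1, each = 100))
  half <- 1:100
  f2 <- fit_baseline("logreg", xf[half, ], yperm[half])
  a <- auroc(predict(f2, xf[-half, ]), yperm[-half])
  expect_gt(a, 0.4); expect_lt(a, 0.6)

  ## MLP determinism under a seed
  m1 <- fit_baseline("mlp", xf[half, ], yperm[half], seed = 3)
  m2 <- fit_baseline("mlp", xf[half, ], yperm[half], seed = 3)
  expect_identical(predict(m1, xf[-half, ]), predict(m2, xf[-half, ]))

  expect_error(fit_baseline("logreg", x, rep(1, n)), "both classes")
})
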