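#' Network hyperparameters
#'
#' @param kernel_size Odd convolution kernel size in `[5, 17]`.
#' @param hidden_channels Hidden channels per convolutional layer.
#' @param n_conv_layers Number of conv/batch-norm/ReLU layers per
#'   subnetwork.
#' @param modalities Subset of the six model modalities the network uses.
#' @return A list of class `namts_hyperparams`.
#' @export
hyperparams <- function(kernel_size = 9, hidden_channels = 20,
                        n_conv_layers = 3, modalities = MODALITIES) {
  stopifnot(kernel_size %% 2 == 1, kernel_size >= 5, kernel_size <= 17,
            hidden_channels >= 1, n_conv_layers >= 1)
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  if (!length(modalities)) stop("modalities must be nonempty")
  structure(list(kernel_size = as.integer(kernel_size),
                 hidden_channels = as.integer(hidden_channels),
                 n_conv_layers = as.integer(n_conv_layers),
                 modalities = modalities),
            class = "namts_hyperparams")
}

#' Build a neural additive model over time-series modalities
#'
#' One fully convolutional subnetwork per selected modality, each ending in
#' a per-timepoint linear combination of channels (the activation map) and
#' global average pooling, plus a single shared additive bias. The
#' per-modality scale factors of the additive formulation are absorbed into
#' each subnetwork's collapse layer, which is equivalent in expressive
#' power; the reported contribution of modality i is the full additive term
#' it feeds into the logit.
#'
#' @param hp A [hyperparams()].
#' @param seed Integer seed; initialization is reproducible.
#' @return A model object of class `namts_nam`.
#' @export
build_nam <- function(hp = hyperparams(), seed = 0L) {
  stopifnot(inherits(hp, "namts_hyperparams"))
  set.seed(seed)
  subnets <- lapply(setNames(hp$modalities, hp$modalities),
                    function(m) init_subnet(hp))
  structure(list(kind = "nam", hp = hp,
                 par = list(subnets = subnets, beta = 0),
                 training_log = NULL, seed = as.integer(seed)),
            class = c("namts_nam", "namts_net"))
}

#' Build the blackbox counterpart network
#'
#' Same per-modality convolutional stacks as the NAM but without the
#' per-timepoint collapse: channel-wise global average pooling yields
#' `hidden_channels` features per modality, which are concatenated and
#' passed through a two-hidden-layer MLP (width 64) to the logit. Trained
#' end-to-end like the NAM; not additive, so no contributions or maps.
#'
#' @inheritParams build_nam
#' @return A model object of class `namts_blackbox`.
#' @export
build_blackbox <- function(hp = hyperparams(), seed = 0L) {
  stopifnot(inherits(hp, "namts_hyperparams"))
  set.seed(seed)
  stacks <- lapply(setNames(hp$modalities, hp$modalities),
                   function(m) init_subnet(hp)["layers"])
  n_feat <- hp$hidden_channels * length(hp$modalities)
  structure(list(kind = "blackbox", hp = hp,
                 par = list(stacks = stacks,
                            mlp1 = init_dense(n_feat, 64),
                            mlp2 = init_dense(64, 64),
                            mlp3 = init_dense(64, 1)),
                 training_log = NULL, seed = as.integer(seed)),
            class = c("namts_blackbox", "namts_net"))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Assemble per-modality (T*B) x 1 input matrices (attr "T_" = window
## length) from a window set subset. A pre-transposed cache (windows in
## columns) avoids re-transposing every minibatch during training.
transpose_cache <- function(ds, modalities) {
  lapply(setNames(modalities, modalities), function(m) t(ds$x[[m]]))
}

batch_arrays <- function(ds, idx, modalities, tcache = NULL) {
  lapply(setNames(modalities, modalities), function(m) {
    xm <- if (is.null(tcache)) t(ds$x[[m]][idx, , drop = FALSE])
          else tcache[[m]][, idx, drop = FALSE]
    T_ <- nrow(xm)
    dim(xm) <- c(length(xm), 1L)
    attr(xm, "T_") <- T_
    xm
  })
}

## Forward pass over a batch; returns logit (B) and per-modality details.
net_fwd <- function(model, xb, training = FALSE, cache = FALSE) {
  if (model$kind == "nam") {
    fs <- list(); fws <- list()
    for (m in model$hp$modalities) {
      T_ <- attr(xb[[m]], "T_"); B <- nrow(xb[[m]]) %/% T_
      fw <- subnet_fwd(model$par$subnets[[m]], xb[[m]], T_, B,
                       training, cache)
      fw$T_ <- T_; fw$B <- B
      model$par$subnets[[m]] <- fw$sub
      fs[[m]] <- fw$f
      fws[[m]] <- fw
    }
    logit <- Reduce(`+`, fs) + model$par$beta
    list(model = model, logit = logit, fws = fws, contributions = fs)
  } else {
    fws <- list(); feats <- list()
    for (m in model$hp$modalities) {
      T_ <- attr(xb[[m]], "T_"); B <- nrow(xb[[m]]) %/% T_
      st <- stack_fwd(model$par$stacks[[m]]$layers, xb[[m]], T_, B,
                      training, cache)
      st$T_ <- T_; st$B <- B
      model$par$stacks[[m]]$layers <- st$layers
      C <- ncol(st$top)
      ## channel-wise global average pooling: B x C
      feats[[m]] <- matrix(.colMeans(st$top, T_, B * C), B, C)
      fws[[m]] <- st
    }
    h0 <- do.call(cbind, feats)
    a1 <- dense_fwd(h0, model$par$mlp1$W, model$par$mlp1$b); h1 <- pmax(a1, 0)
    a2 <- dense_fwd(h1, model$par$mlp2$W, model$par$mlp2$b); h2 <- pmax(a2, 0)
    logit <- as.numeric(dense_fwd(h2, model$par$mlp3$W, model$par$mlp3$b))
    list(model = model, logit = logit, fws = fws,
         mlp_cache = list(h0 = h0, a1 = a1, h1 = h1, a2 = a2, h2 = h2))
  }
}

## Backward pass: gradients mirroring model$par, given dlogit (B).
net_bwd <- function(model, fwd, dlogit) {
  if (model$kind == "nam") {
    g_sub <- lapply(setNames(model$hp$modalities, model$hp$modalities),
                    function(m) {
                      fw <- fwd$fws[[m]]
                      subnet_bwd(model$par$subnets[[m]], fw, dlogit,
                                 fw$T_, fw$B)
                    })
    list(subnets = g_sub, beta = sum(dlogit))
  } else {
    mc <- fwd$mlp_cache
    B <- length(dlogit)
    dl <- matrix(dlogit, B, 1)
    g3 <- list(W = crossprod(mc$h2, dl), b = colSums(dl))
    dh2 <- (dl %*% t(model$par$mlp3$W)) * (mc$a2 > 0)
    g2 <- list(W = crossprod(mc$h1, dh2), b = colSums(dh2))
    dh1 <- (dh2 %*% t(model$par$mlp2$W)) * (mc$a1 > 0)
    g1 <- list(W = crossprod(mc$h0, dh1), b = colSums(dh1))
    dh0 <- dh1 %*% t(model$par$mlp1$W)
    C <- model$hp$hidden_channels
    g_st <- list()
    for (i in seq_along(model$hp$modalities)) {
      m <- model$hp$modalities[i]
      st <- fwd$fws[[m]]
      T_ <- st$T_
      dfeat <- dh0[, ((i - 1) * C + 1):(i * C), drop = FALSE]
      dtop <- matrix(rep(as.numeric(dfeat) / T_, each = T_), T_ * B, C)
      g_st[[m]] <- list(layers = stack_bwd(model$par$stacks[[m]]$layers,
                                           st$caches, dtop, T_, B))
    }
    list(stacks = g_st, mlp1 = g1, mlp2 = g2, mlp3 = g3)
  }
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: 10 epochs of Adam at
#' learning rate 1e-4 with weight decay 0.01 on a class-balanced training
#' set, binary cross-entropy loss. Weight decay applies to convolution,
#' collapse and dense weights, not to biases or batch-norm parameters.
#'
#' @param epochs,lr,weight_decay,batch_size,seed Training settings.
#' @return A list of class `namts_train_config`.
#' @export
train_config <- function(epochs = 10, lr = 1e-4, weight_decay = 0.01,
                         batch_size = 64, seed = 0L) {
  structure(list(epochs = epochs, lr = lr, weight_decay = weight_decay,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "namts_train_config")
}

#' Train a NAM or blackbox network
#'
#' Minimizes binary cross-entropy with Adam. Training uses batch-norm batch
#' statistics; running statistics are updated for deterministic evaluation.
#' Reproducible given the config seed.
#'
#' @param model A [build_nam()] or [build_blackbox()] model.
#' @param ds A `namts_window_set` with both classes present (balance it
#'   first with [undersample()]).
#' @param cfg A [train_config()].
#' @return The trained model; `model$training_log` holds per-epoch mean
#'   loss.
#' @export
train_model <- function(model, ds, cfg = train_config()) {
  stopifnot(inherits(model, "namts_net"),
            inherits(ds, "namts_window_set"))
  y <- ds$label
  if (length(unique(y)) < 2)
    stop("training set must contain both classes")
  set.seed(cfg$seed)
  n <- n_windows(ds)
  opt <- adam_new()
  step <- 0L
  losses <- numeric(cfg$epochs)
  tcache <- transpose_cache(ds, model$hp$modalities)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- batch_arrays(ds, idx, model$hp$modalities, tcache)
      fwd <- net_fwd(model, xb, training = TRUE, cache = TRUE)
      model <- fwd$model
      p <- sigmoid(fwd$logit)
      yb <- y[idx]
      eps <- 1e-12
      ep_loss <- ep_loss -
        sum(yb * log(p + eps) + (1 - yb) * log(1 - p + eps))
      dlogit <- (p - yb) / length(idx)
      grads <- net_bwd(model, fwd, dlogit)
      step <- step + 1L
      model$par <- adam_step(opt, model$par, grads, cfg$lr,
                             cfg$weight_decay, step)
    }
    losses[ep] <- ep_loss / n
  }
  model$training_log <- data.frame(epoch = seq_len(cfg$epochs),
                                   loss = losses)
  model
}

#' Score a window set with a trained network
#'
#' Evaluation mode: batch normalization uses stored running statistics, so
#' predictions are deterministic and each window's score is independent of
#' the batch it is scored in.
#'
#' @param model A trained `namts_net`.
#' @param ds A `namts_window_set`.
#' @param maps If `TRUE` (NAM only) also return per-modality activation
#'   maps.
#' @return List with `probability`, `logit`, and for NAMs `contributions`
#'   (windows x modalities matrix) and optionally `activation_maps` (list of
#'   T x windows matrices).
#' @export
net_predict <- function(model, ds, maps = FALSE) {
  stopifnot(inherits(model, "namts_net"))
  n <- n_windows(ds)
  out <- list(probability = numeric(n), logit = numeric(n))
  if (model$kind == "nam") {
    out$contributions <- matrix(0, n, length(model$hp$modalities),
                                dimnames = list(NULL, model$hp$modalities))
    if (maps) out$activation_maps <-
        lapply(setNames(model$hp$modalities, model$hp$modalities),
               function(m) matrix(0, ncol(ds$x[[m]]), n))
  }
  for (start in seq(1, n, by = 256)) {
    idx <- start:min(start + 255, n)
    xb <- batch_arrays(ds, idx, model$hp$modalities)
    fwd <- net_fwd(model, xb, training = FALSE, cache = FALSE)
    out$logit[idx] <- fwd$logit
    out$probability[idx] <- sigmoid(fwd$logit)
    if (model$kind == "nam") {
      for (m in model$hp$modalities) {
        out$contributions[idx, m] <- fwd$contributions[[m]]
        if (maps) out$activation_maps[[m]][, idx] <- fwd$fws[[m]]$map
      }
    }
  }
  out
}

#' Predict one window with full interpretability output
#'
#' @param model A trained [build_nam()] model.
#' @param m A `namts_model_input`.
#' @return A `namts_nam_prediction`: classification probability, logit,
#'   shared bias, per-modality additive contributions, and per-modality
#'   activation maps at model-input resolution. The logit equals the sum of
#'   contributions plus the bias exactly, and each contribution equals the
#'   time-mean of its activation map exactly.
#' @export
nam_forward <- function(model, m) {
  stopifnot(inherits(model, "namts_nam"), inherits(m, "namts_model_input"))
  for (mod in model$hp$modalities)
    if (is.null(m[[mod]])) stop(sprintf("input lacks modality %s", mod))
  xb <- lapply(setNames(model$hp$modalities, model$hp$modalities),
               function(mod) {
                 X <- matrix(m[[mod]], ncol = 1)
                 attr(X, "T_") <- length(m[[mod]])
                 X
               })
  fwd <- net_fwd(model, xb, training = FALSE, cache = FALSE)
  contributions <- vapply(fwd$contributions, `[`, numeric(1), 1)
  structure(list(
    probability = sigmoid(fwd$logit[1]),
    logit = fwd$logit[1],
    bias = model$par$beta,
    contributions = contributions,
    activation_maps = lapply(fwd$fws, function(f) as.numeric(f$map))),
    class = "namts_nam_prediction")
}

#' @export
print.namts_nam_prediction <- function(x, ...) {
  cat(sprintf("<NAM prediction> p = %.3f (logit %.3f = bias %.3f + sum of:)\n",
              x$probability, x$logit, x$bias))
  print(round(x$contributions, 4))
  invisible(x)
}

#' Fit a feature-based baseline classifier
#'
#' Both baselines consume the 24 engineered features, standardized
#' column-wise with training-set statistics (reused at prediction time).
#' `logreg` is an L2-regularized logistic regression; `mlp` a single-hidden-
#' layer feed-forward network (width 64, weight decay).
#'
#' @param kind `"logreg"` or `"mlp"`.
#' @param features Numeric matrix or data.frame of the 24 feature columns.
#' @param labels Binary labels (1 = target).
#' @param seed Seed for the MLP's random initialization.
#' @param lambda Ridge penalty for `logreg`.
#' @return A `namts_baseline` model.
#' @export
fit_baseline <- function(kind = c("logreg", "mlp"), features, labels,
                         seed = 0L, lambda = 0.01) {
  kind <- match.arg(kind)
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("need both classes to fit a baseline")
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, `/`)
  set.seed(seed)
  fit <- if (kind == "logreg") {
    glmnet::glmnet(xs, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = lambda, standardize = FALSE)
  } else {
    nnet::nnet(xs, y, size = 64, decay = 0.01, maxit = 300,
               entropy = TRUE, MaxNWts = 5000, trace = FALSE)
  }
  structure(list(kind = kind, fit = fit, center = center, scale = scale),
            class = "namts_baseline")
}

#' @rdname fit_baseline
#' @param object A `namts_baseline`.
#' @param newdata Feature matrix to score.
#' @param ... Unused.
#' @return `predict()`: vector of target probabilities.
#' @export
predict.namts_baseline <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, `/`)
  if (object$kind == "logreg")
    as.numeric(predict(object$fit, xs, type = "response"))
  else
    as.numeric(predict(object$fit, xs, type = "raw"))
}
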