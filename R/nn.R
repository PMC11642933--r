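## Minimal neural-network engine for the additive time-series models.
## Activations for one modality of a batch are a flat (T*B) x C matrix:
## row index t + (b-1)*T, so each window's T timepoints are contiguous.
## The hot kernels (convolution and batch-norm passes) live in
## src/nn_kernels.cpp (RcppArmadillo); a 'same' zero-padded convolution is
## one wide matrix product X %*% W (W holds all k taps side by side)
## followed by row-shifted accumulations. Orchestration, Adam and the
## additive bookkeeping stay in R; models are plain serializable lists.

## ---- convolution (RcppArmadillo kernels) ------------------------------

## W: C_in x (k * C_out), tap-j block in columns (j-1)*C_out + 1..C_out,
## tap offsets d_j = j - 1 - (k-1)/2. b: C_out.
conv1d_fwd <- function(X, W, b, T_, B) {
  conv1d_fwd_cpp(X, W, b, T_, B, attr(W, "k"))
}

## Backward: dW, db, dX from dY, using the cached layer input X.
conv1d_bwd <- function(dY, X, W, T_, B) {
  out <- conv1d_bwd_cpp(dY, X, W, T_, B, attr(W, "k"))
  attr(out$dW, "k") <- attr(W, "k")
  out$db <- as.numeric(out$db)
  out
}

## ---- batch normalization ---------------------------------------------

bn_fwd <- function(xm, g, bet, state, training, momentum = 0.1,
                   eps = 1e-5) {
  out <- bn_fwd_cpp(xm, g, bet, state$mean, state$var, training, momentum,
                    eps)
  list(y = out$y, xhat = out$xhat, invstd = as.numeric(out$invstd),
       state = list(mean = as.numeric(out$mean),
                    var = as.numeric(out$var)))
}

bn_bwd <- function(dy, xhat, invstd, g, training) {
  out <- bn_bwd_cpp(dy, xhat, invstd, g, training)
  list(dx = out$dx, dg = as.numeric(out$dg), dbet = as.numeric(out$dbet))
}

dense_fwd <- function(x, W, b) sweep(x %*% W, 2, b, `+`)

## ---- parameter initialization -----------------------------------------

## PyTorch-convention uniform init: bound 1/sqrt(fan_in)
init_conv <- function(k, c_in, c_out) {
  bound <- 1 / sqrt(c_in * k)
  W <- matrix(runif(c_in * k * c_out, -bound, bound), c_in, k * c_out)
  attr(W, "k") <- as.integer(k)
  list(W = W, b = runif(c_out, -bound, bound))
}

init_dense <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = runif(n_out, -bound, bound))
}

new_bn_state <- function(C) list(mean = rep(0, C), var = rep(1, C))

## ---- subnetwork (per-modality FCN) ------------------------------------

## Parameters for one subnetwork: conv layers + batch norms + collapse
init_subnet <- function(hp) {
  lay <- vector("list", hp$n_conv_layers)
  c_in <- 1L
  for (l in seq_len(hp$n_conv_layers)) {
    cv <- init_conv(hp$kernel_size, c_in, hp$hidden_channels)
    lay[[l]] <- list(conv = cv,
                     bn_g = rep(1, hp$hidden_channels),
                     bn_b = rep(0, hp$hidden_channels),
                     bn_state = new_bn_state(hp$hidden_channels))
    c_in <- hp$hidden_channels
  }
  bound <- 1 / sqrt(hp$hidden_channels)
  list(layers = lay,
       collapse = runif(hp$hidden_channels, -bound, bound))
}

## Forward through a conv/bn/relu stack. x: (T*B) x C_in matrix. Returns
## top activations, updated batch-norm state and backprop caches.
stack_fwd <- function(layers, x, T_, B, training = FALSE, cache = FALSE) {
  caches <- if (cache) vector("list", length(layers)) else NULL
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    y <- conv1d_fwd(x, ly$conv$W, ly$conv$b, T_, B)
    bn <- bn_fwd(y, ly$bn_g, ly$bn_b, ly$bn_state, training)
    layers[[l]]$bn_state <- bn$state
    mask <- bn$y > 0
    if (cache)
      caches[[l]] <- list(x_in = x, xhat = bn$xhat, invstd = bn$invstd,
                          mask = mask)
    x <- bn$y * mask
  }
  list(layers = layers, top = x, caches = caches)
}

## Backward through a stack from dtop ((T*B) x C); grads mirror `layers`.
stack_bwd <- function(layers, caches, dtop, T_, B, training = TRUE) {
  grads <- vector("list", length(layers))
  dx <- dtop
  for (l in rev(seq_along(layers))) {
    ca <- caches[[l]]
    dx <- dx * ca$mask
    bnb <- bn_bwd(dx, ca$xhat, ca$invstd, layers[[l]]$bn_g, training)
    cvb <- conv1d_bwd(bnb$dx, ca$x_in, layers[[l]]$conv$W, T_, B)
    grads[[l]] <- list(conv = list(W = cvb$dW, b = cvb$db),
                       bn_g = bnb$dg, bn_b = bnb$dbet)
    dx <- cvb$dX
  }
  grads
}

## Subnetwork = stack + per-timepoint linear collapse + global average
## pooling. Returns the activation map (T x B) and its time-mean f (B),
## which IS the modality's additive contribution.
subnet_fwd <- function(sub, x, T_, B, training = FALSE, cache = FALSE) {
  st <- stack_fwd(sub$layers, x, T_, B, training, cache)
  sub$layers <- st$layers
  map <- matrix(st$top %*% sub$collapse, T_, B)
  list(sub = sub, f = .colMeans(map, T_, B), map = map, top = st$top,
       caches = st$caches)
}

subnet_bwd <- function(sub, fw, df, T_, B, training = TRUE) {
  ## f = colMeans(map): dmap[t,b] = df[b]/T
  dmap <- rep(df / T_, each = T_)
  dcollapse <- as.numeric(crossprod(fw$top, dmap))
  dtop <- dmap %*% matrix(sub$collapse, nrow = 1)
  list(layers = stack_bwd(sub$layers, fw$caches, dtop, T_, B, training),
       collapse = dcollapse)
}

## ---- Adam over nested parameter lists ---------------------------------

## Walk nested lists of numeric leaves in parallel (params + grads).
walk_params <- function(par, grad, fn, path = "") {
  nms <- names(par)
  for (i in seq_along(par)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    if (nm == "bn_state") next
    p <- par[[i]]
    g <- if (is.null(grad)) NULL else grad[[i]]
    if (is.list(p)) par[[i]] <- walk_params(p, g, fn, paste0(path, nm, "."))
    else if (is.numeric(p)) par[[i]] <- fn(p, g, paste0(path, nm))
  }
  par
}

## Weight decay applies to convolution/dense/collapse weights only -- not
## to biases, batch-norm parameters or the additive bias beta.
wd_applies <- function(path) {
  grepl("(conv\\.W|collapse|mlp[0-9]*\\.W)$", path)
}

adam_new <- function() new.env(parent = emptyenv())

adam_step <- function(opt, par, grad, lr, wd, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk_params(par, grad, function(p, g, path) {
    if (is.null(g)) return(p)
    if (wd > 0 && wd_applies(path)) g <- g + wd * p
    st <- opt[[path]]
    if (is.null(st)) st <- list(m = 0 * p, v = 0 * p)
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    opt[[path]] <- st
    mhat <- st$m / (1 - beta1^step)
    vhat <- st$v / (1 - beta2^step)
    pn <- p - lr * mhat / (sqrt(vhat) + eps)
    attributes(pn) <- attributes(p)
    pn
  })
}
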