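# Minimal feed-forward network machinery (dense / batch-norm / SiLU /
# inverted dropout) with explicit forward caches and hand-written backward
# passes, plus Adam. Written against base R matrix ops; gradients flow both
# to parameters (training) and to the input (metabolite attributions).

nn_dense <- function(n_in, n_out, init_sd = sqrt(2 / n_in)) {
  list(type = "dense",
       W = matrix(rnorm(n_in * n_out, sd = init_sd), n_in, n_out),
       b = numeric(n_out))
}
nn_bn <- function(n) {
  list(type = "bn", gamma = rep(1, n), beta = numeric(n),
       rmean = numeric(n), rvar = rep(1, n), momentum = 0.1, eps = 1e-5)
}
nn_silu <- function() list(type = "silu")
nn_dropout <- function(p) list(type = "dropout", p = p)

# block-diagonal dense: E independent per-endpoint maps n_in -> n_out over a
# feature-concatenated input (n x E*n_in) producing (n x E*n_out); keeps the
# per-endpoint heads mathematically separate while letting the elementwise
# layers (batch norm, SiLU, dropout) run fused across endpoints
nn_bdense <- function(n_in, n_out, n_heads, init_sd = sqrt(2 / n_in)) {
  list(type = "bdense",
       W = array(rnorm(n_in * n_out * n_heads, sd = init_sd),
                 dim = c(n_in, n_out, n_heads)),
       b = numeric(n_out * n_heads))
}

# one "block": linear -> batchnorm -> SiLU -> dropout
nn_block <- function(n_in, n_out, dropout = 0, batchnorm = TRUE) {
  layers <- list(nn_dense(n_in, n_out))
  if (batchnorm) layers <- c(layers, list(nn_bn(n_out)))
  layers <- c(layers, list(nn_silu()))
  if (dropout > 0) layers <- c(layers, list(nn_dropout(dropout)))
  layers
}

nn_mlp <- function(n_in, widths, dropout = 0, batchnorm = TRUE) {
  layers <- list()
  d <- n_in
  for (w in widths) {
    layers <- c(layers, nn_block(d, w, dropout, batchnorm))
    d <- w
  }
  layers
}

layer_forward <- function(layer, X, mode) {
  switch(layer$type,
    dense = {
      out <- cpp_add_cols(X %*% layer$W, layer$b)
      list(out = out, cache = list(X = X), layer = layer)
    },
    bdense = {
      d <- dim(layer$W)
      E <- d[3]
      out <- matrix(0, nrow(X), d[2] * E)
      for (e in seq_len(E)) {
        ic <- ((e - 1) * d[1] + 1):(e * d[1])
        oc <- ((e - 1) * d[2] + 1):(e * d[2])
        out[, oc] <- X[, ic, drop = FALSE] %*% layer$W[, , e]
      }
      list(out = cpp_add_cols(out, layer$b), cache = list(X = X),
           layer = layer)
    },
    bn = {
      if (mode == "infer") {
        inv <- 1 / sqrt(layer$rvar + layer$eps)
        res <- cpp_bn_apply(X, layer$rmean, inv, layer$gamma, layer$beta,
                            want_xhat = FALSE)
        list(out = res$out, cache = list(mode = "infer", inv = inv),
             layer = layer)
      } else {
        m <- nrow(X)
        mv <- cpp_col_meanvar(X)
        inv <- 1 / sqrt(mv$var + layer$eps)
        res <- cpp_bn_apply(X, mv$mean, inv, layer$gamma, layer$beta,
                            want_xhat = TRUE)
        if (mode == "stats") { # full-data pass to refresh running stats
          layer$rmean <- mv$mean
          layer$rvar <- mv$var * m / max(m - 1, 1)
        } else {
          mom <- layer$momentum
          layer$rmean <- (1 - mom) * layer$rmean + mom * mv$mean
          layer$rvar <- (1 - mom) * layer$rvar +
            mom * mv$var * m / max(m - 1, 1)
        }
        list(out = res$out,
             cache = list(mode = "train", inv = inv, xhat = res$xhat),
             layer = layer)
      }
    },
    silu = {
      res <- cpp_silu(X, want_sig = TRUE)
      list(out = res$out, cache = list(X = X, s = res$sig), layer = layer)
    },
    dropout = {
      if (mode == "infer" || layer$p == 0) {
        list(out = X, cache = list(mask = NULL), layer = layer)
      } else {
        res <- cpp_dropout(X, 1 - layer$p)
        list(out = res$out, cache = list(mask = res$mask), layer = layer)
      }
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    dense = list(dX = tcrossprod(dY, layer$W),
                 grads = list(W = crossprod(cache$X, dY), b = colSums(dY))),
    bdense = {
      d <- dim(layer$W)
      E <- d[3]
      dX <- matrix(0, nrow(dY), d[1] * E)
      dW <- array(0, dim = d)
      for (e in seq_len(E)) {
        ic <- ((e - 1) * d[1] + 1):(e * d[1])
        oc <- ((e - 1) * d[2] + 1):(e * d[2])
        dYe <- dY[, oc, drop = FALSE]
        dX[, ic] <- tcrossprod(dYe, layer$W[, , e])
        dW[, , e] <- crossprod(cache$X[, ic, drop = FALSE], dYe)
      }
      list(dX = dX, grads = list(W = dW, b = colSums(dY)))
    },
    bn = {
      if (cache$mode == "infer") {
        list(dX = cpp_scale_cols(dY, layer$gamma * cache$inv), grads = NULL)
      } else {
        res <- cpp_bn_backward(dY, cache$xhat, layer$gamma, cache$inv)
        list(dX = res$dX,
             grads = list(gamma = res$dgamma, beta = res$dbeta))
      }
    },
    silu = list(dX = cpp_silu_grad(cache$X, cache$s, dY), grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = cpp_mul(dY, cache$mask), grads = NULL)
    })
}

seq_forward <- function(layers, X, mode) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], X, mode)
    X <- res$out
    caches[[i]] <- res$cache
    layers[[i]] <- res$layer # running stats may have been updated
  }
  list(out = X, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    res <- layer_backward(layers[[i]], caches[[i]], dY)
    dY <- res$dX
    grads[i] <- list(res$grads)
  }
  list(dX = dY, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("dense", "bdense"))
      list(W = list(m = l$W * 0, v = l$W * 0),
           b = list(m = l$b * 0, v = l$b * 0))
    else if (l$type == "bn")
      list(gamma = list(m = l$gamma * 0, v = l$gamma * 0),
           beta = list(m = l$beta * 0, v = l$beta * 0))
    else NULL
  })
}

adam_update_tensor <- function(theta, g, st, lr, t,
                               b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

adam_step_layers <- function(layers, grads, state, lr, t) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      upd <- adam_update_tensor(layers[[i]][[nm]], g[[nm]],
                                state[[i]][[nm]], lr, t)
      layers[[i]][[nm]] <- upd$theta
      state[[i]][[nm]] <- upd$state
    }
  }
  list(layers = layers, state = state)
}

# weight (not running-stat) arithmetic over a layer list, for SWA
layers_weights <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
           dense = list(W = l$W, b = l$b),
           bdense = list(W = l$W, b = l$b),
           bn = list(gamma = l$gamma, beta = l$beta),
           NULL)
  })
}
layers_axpy <- function(acc, w) { # acc + w, elementwise over the skeleton
  if (is.null(acc)) return(w)
  for (i in seq_along(w)) {
    if (is.null(w[[i]])) next
    for (nm in names(w[[i]])) acc[[i]][[nm]] <- acc[[i]][[nm]] + w[[i]][[nm]]
  }
  acc
}
layers_set_weights <- function(layers, w, scale = 1) {
  for (i in seq_along(layers)) {
    if (is.null(w[[i]])) next
    for (nm in names(w[[i]])) layers[[i]][[nm]] <- w[[i]][[nm]] * scale
  }
  layers
}
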