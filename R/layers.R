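# Minimal neural-network layer primitives with explicit forward/backward
# passes. Parameters live in a single flat named list on the model; layers
# store the *names* of their parameters so gradients can be returned as a
# flat named list and fed to the optimiser.
#
# Shapes: activations are T x width matrices (rows = utterances). Linear
# weights are stored out x in, so the forward map is X %*% t(W) + b.

make_linear <- function(prefix, nin, nout, bias = TRUE) {
  layer <- list(kind = "linear", w = paste0(prefix, ".W"),
                b = if (bias) paste0(prefix, ".b") else NULL,
                nin = nin, nout = nout)
  params <- stats::setNames(list(init_mat(nout, nin)), layer$w)
  if (bias) params[[layer$b]] <- numeric(nout)
  list(layer = layer, params = params)
}

make_activation <- function(kind) list(layer = list(kind = kind), params = list())

make_layernorm <- function(prefix, width, affine = TRUE, eps = 1e-5) {
  layer <- list(kind = "layernorm", eps = eps, affine = affine,
                g = if (affine) paste0(prefix, ".gamma") else NULL,
                bt = if (affine) paste0(prefix, ".beta") else NULL)
  params <- list()
  if (affine) {
    params[[layer$g]] <- rep(1, width)
    params[[layer$bt]] <- rep(0, width)
  }
  list(layer = layer, params = params)
}

make_batchnorm <- function(prefix, width, eps = 1e-5, momentum = 0.1) {
  layer <- list(kind = "batchnorm", eps = eps, momentum = momentum,
                g = paste0(prefix, ".gamma"), bt = paste0(prefix, ".beta"),
                rm = paste0(prefix, ".running_mean"),
                rv = paste0(prefix, ".running_var"))
  params <- stats::setNames(list(rep(1, width), rep(0, width)), c(layer$g, layer$bt))
  state <- stats::setNames(list(rep(0, width), rep(1, width)), c(layer$rm, layer$rv))
  list(layer = layer, params = params, state = state)
}

make_dropout <- function(p) list(layer = list(kind = "dropout", p = p), params = list())

# Forward pass through one layer. Returns list(out, cache, state) where
# `state` carries updated running statistics (batchnorm, training mode only).
layer_forward <- function(layer, params, state, X, training) {
  out_state <- NULL
  switch(layer$kind,
    linear = {
      W <- params[[layer$w]]
      Y <- X %*% t(W)
      if (!is.null(layer$b)) Y <- sweep(Y, 2L, params[[layer$b]], "+")
      list(out = Y, cache = list(X = X), state = NULL)
    },
    relu = {
      list(out = X * (X > 0), cache = list(X = X), state = NULL)
    },
    gelu = {
      Phi <- stats::pnorm(X)
      list(out = X * Phi, cache = list(X = X, Phi = Phi), state = NULL)
    },
    layernorm = {
      mu <- rowMeans(X)
      xc <- X - mu
      v <- rowMeans(xc^2)
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- xc * inv
      Y <- xhat
      if (layer$affine) Y <- sweep(sweep(xhat, 2L, params[[layer$g]], "*"), 2L, params[[layer$bt]], "+")
      list(out = Y, cache = list(xhat = xhat, inv = inv), state = NULL)
    },
    batchnorm = {
      if (training) {
        mu <- colMeans(X)
        xc <- sweep(X, 2L, mu)
        v <- colMeans(xc^2)
        mom <- layer$momentum
        out_state <- list()
        out_state[[layer$rm]] <- (1 - mom) * state[[layer$rm]] + mom * mu
        out_state[[layer$rv]] <- (1 - mom) * state[[layer$rv]] + mom * v
      } else {
        mu <- state[[layer$rm]]
        v <- state[[layer$rv]]
        xc <- sweep(X, 2L, mu)
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2L, inv, "*")
      Y <- sweep(sweep(xhat, 2L, params[[layer$g]], "*"), 2L, params[[layer$bt]], "+")
      list(out = Y, cache = list(xhat = xhat, inv = inv, n = nrow(X), training = training),
           state = out_state)
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- matrix(stats::rbinom(length(X), 1L, 1 - layer$p), nrow = nrow(X)) / (1 - layer$p)
        list(out = X * mask, cache = list(mask = mask), state = NULL)
      } else {
        list(out = X, cache = list(mask = NULL), state = NULL)
      }
    },
    stopf("unknown layer kind '%s'", layer$kind)
  )
}

# Backward pass through one layer. Returns list(dX, grads).
layer_backward <- function(layer, params, cache, dY) {
  switch(layer$kind,
    linear = {
      W <- params[[layer$w]]
      grads <- stats::setNames(list(t(dY) %*% cache$X), layer$w)
      if (!is.null(layer$b)) grads[[layer$b]] <- colSums(dY)
      list(dX = dY %*% W, grads = grads)
    },
    relu = list(dX = dY * (cache$X > 0), grads = list()),
    gelu = {
      X <- cache$X
      list(dX = dY * (cache$Phi + X * stats::dnorm(X)), grads = list())
    },
    layernorm = {
      xhat <- cache$xhat
      dxhat <- if (layer$affine) sweep(dY, 2L, params[[layer$g]], "*") else dY
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      dX <- (dxhat - m1 - xhat * m2) * cache$inv
      grads <- list()
      if (layer$affine) {
        grads[[layer$g]] <- colSums(dY * xhat)
        grads[[layer$bt]] <- colSums(dY)
      }
      list(dX = dX, grads = grads)
    },
    batchnorm = {
      xhat <- cache$xhat
      dxhat <- sweep(dY, 2L, params[[layer$g]], "*")
      grads <- list()
      grads[[layer$g]] <- colSums(dY * xhat)
      grads[[layer$bt]] <- colSums(dY)
      if (cache$training) {
        m1 <- colMeans(dxhat)
        m2 <- colMeans(dxhat * xhat)
        dX <- sweep(sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*"), 2L, cache$inv, "*")
      } else {
        dX <- sweep(dxhat, 2L, cache$inv, "*")
      }
      list(dX = dX, grads = grads)
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = list())
      else list(dX = dY * cache$mask, grads = list())
    },
    stopf("unknown layer kind '%s'", layer$kind)
  )
}

mlp_forward <- function(layers, params, state, X, training) {
  caches <- vector("list", length(layers))
  new_state <- list()
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], params, state, X, training)
    X <- fw$out
    caches[[i]] <- fw$cache
    if (!is.null(fw$state)) new_state[names(fw$state)] <- fw$state
  }
  list(out = X, caches = caches, state = new_state)
}

mlp_backward <- function(layers, params, caches, dY) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], params, caches[[i]], dY)
    dY <- bw$dX
    grads <- params_axpy(grads, bw$grads)
  }
  list(dX = dY, grads = grads)
}
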