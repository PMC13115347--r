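# Internal helpers: seed derivation, parameter trees, numerics.

# Derive a reproducible child seed from a base seed. Kept strictly below
# 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(offset) * 7919
  as.integer(s %% 2147483629) + 1L
}

# Numerically safe sigmoid / softmax ---------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Parameter initialisation --------------------------------------------------

init_mat <- function(nout, nin, scale = sqrt(2 / nin)) {
  matrix(stats::rnorm(nout * nin, sd = scale), nrow = nout, ncol = nin)
}

# Flat parameter-list arithmetic (params and grads are named lists of
# numeric arrays; absent gradient entries count as zero).

params_axpy <- function(acc, g, a = 1) {
  for (nm in names(g)) {
    if (is.null(acc[[nm]])) acc[[nm]] <- g[[nm]] * a else acc[[nm]] <- acc[[nm]] + g[[nm]] * a
  }
  acc
}

params_scale <- function(p, a) lapply(p, function(x) x * a)

params_global_norm <- function(g) {
  sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
}

# Clip a flat gradient list to a maximum global L2 norm.
clip_gradients <- function(grads, max_norm) {
  gn <- params_global_norm(grads)
  if (gn > max_norm && gn > 0) grads <- params_scale(grads, max_norm / gn)
  grads
}

# Merge gradient contributions from one session into the running batch
# accumulator.
acc_grads <- function(acc, g) params_axpy(acc, g, 1)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
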