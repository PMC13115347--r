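# The four fusion operators. Each combines a primary stream `ha` with a
# complementary stream `hb` (both T x d, rows = utterances) into a fused
# T x d stream:
#
#   concat    : h = W [ha; hb] + b                      (2d^2 weights + d bias)
#   sum       : h = ha + hb                             (no parameters)
#   gated     : g = sigmoid(Wg [ha; hb] + bg)
#               h = g * ha + (1 - g) * hb               (2d^2 + d)
#   attention : Q = ha Wq', K = hb Wk', A = softmax(QK'/sqrt(d))
#               h = [ha; A hb] Wo'                      (4d^2)
#
# The cross-attention value projection is folded into the complementary half
# of the output map Wo (a composition of two unconstrained d x d linear maps
# is one unconstrained d x d map), giving exactly the 4d^2 parameter
# overhead of the capacity ledger while keeping the function class of the
# usual Q/K/V formulation.
#
# Gated and attention operators are defined generically for any
# (primary, complementary) pair so they can occupy any of the three fusion
# positions; the gate g (and attention map A) is returned for
# interpretability analysis.

FUSION_STRATEGIES <- c("concat", "sum", "gated", "attention")

check_pair <- function(ha, hb) {
  if (!is.matrix(ha) || !is.matrix(hb)) stopf("fusion inputs must be matrices")
  if (nrow(ha) != nrow(hb)) stopf("fusion inputs disagree on utterance count: %d vs %d", nrow(ha), nrow(hb))
  if (ncol(ha) != ncol(hb)) stopf("fusion inputs disagree on width: %d vs %d", ncol(ha), ncol(hb))
  if (nrow(hb) < 1L) stopf("fusion requires at least one utterance")
  invisible(TRUE)
}

#' Initialise parameters for one fusion stage
#'
#' Returns the parameter list consumed by [fuse_concat()], [fuse_gated()]
#' and [fuse_cross_attention()]; `sum` needs none. Gate parameters start at
#' zero so an untrained gate mixes both streams evenly (g = 0.5).
#'
#' @param strategy one of `"concat"`, `"sum"`, `"gated"`, `"attention"`.
#' @param d shared latent width.
#' @param gate `"vector"` (elementwise gate of width `d`, the default) or
#'   `"scalar"` (one gate value per utterance).
#' @return named list of numeric arrays (empty for `"sum"`).
#' @export
init_fusion_params <- function(strategy, d, gate = c("vector", "scalar")) {
  strategy <- match.arg(strategy, FUSION_STRATEGIES)
  gate <- match.arg(gate)
  switch(strategy,
    sum = list(),
    concat = list(W = init_mat(d, 2 * d, scale = sqrt(1 / (2 * d))), b = numeric(d)),
    gated = if (gate == "vector") {
      list(W = matrix(0, d, 2 * d), b = numeric(d))
    } else {
      list(W = matrix(0, 1, 2 * d), b = numeric(1))
    },
    attention = list(
      Wq = init_mat(d, d, scale = sqrt(1 / d)),
      Wk = init_mat(d, d, scale = sqrt(1 / d)),
      Wo = cbind(diag(d), matrix(0, d, d))
    )
  )
}

fusion_forward <- function(strategy, ha, hb, par) {
  check_pair(ha, hb)
  d <- ncol(ha)
  switch(strategy,
    sum = list(out = ha + hb, trace = list(), cache = list()),
    concat = {
      X <- cbind(ha, hb)
      out <- sweep(X %*% t(par$W), 2L, par$b, "+")
      list(out = out, trace = list(), cache = list(X = X))
    },
    gated = {
      X <- cbind(ha, hb)
      pre <- sweep(X %*% t(par$W), 2L, par$b, "+")
      g <- sigmoid(pre)
      gm <- if (ncol(g) == 1L) matrix(g, nrow(ha), d) else g
      out <- gm * ha + (1 - gm) * hb
      list(out = out, trace = list(gate = g),
           cache = list(X = X, g = g, gm = gm, ha = ha, hb = hb))
    },
    attention = {
      Q <- ha %*% t(par$Wq)
      K <- hb %*% t(par$Wk)
      A <- softmax_rows(Q %*% t(K) / sqrt(d))
      C <- A %*% hb
      out <- cbind(ha, C) %*% t(par$Wo)
      list(out = out, trace = list(attention = A),
           cache = list(ha = ha, hb = hb, Q = Q, K = K, A = A, C = C))
    },
    stopf("unknown fusion strategy '%s'", strategy)
  )
}

fusion_backward <- function(strategy, par, cache, dout) {
  d <- ncol(dout)
  switch(strategy,
    sum = list(da = dout, db = dout, grads = list()),
    concat = {
      dX <- dout %*% par$W
      list(da = dX[, 1:d, drop = FALSE], db = dX[, (d + 1):(2 * d), drop = FALSE],
           grads = list(W = t(dout) %*% cache$X, b = colSums(dout)))
    },
    gated = {
      gm <- cache$gm
      da <- gm * dout
      db <- (1 - gm) * dout
      dgm <- dout * (cache$ha - cache$hb)
      dg <- if (ncol(cache$g) == 1L) matrix(rowSums(dgm), ncol = 1L) else dgm
      dpre <- dg * cache$g * (1 - cache$g)
      dX <- dpre %*% par$W
      list(da = da + dX[, 1:d, drop = FALSE], db = db + dX[, (d + 1):(2 * d), drop = FALSE],
           grads = list(W = t(dpre) %*% cache$X, b = colSums(dpre)))
    },
    attention = {
      ha <- cache$ha; hb <- cache$hb; A <- cache$A
      dWo <- t(dout) %*% cbind(ha, cache$C)
      dcat <- dout %*% par$Wo
      da <- dcat[, 1:d, drop = FALSE]
      dC <- dcat[, (d + 1):(2 * d), drop = FALSE]
      dA <- dC %*% t(hb)
      db <- t(A) %*% dC
      dS <- (dA - rowSums(dA * A)) * A / sqrt(d)
      dQ <- dS %*% cache$K
      dK <- t(dS) %*% cache$Q
      list(da = da + dQ %*% par$Wq, db = db + dK %*% par$Wk,
           grads = list(Wq = t(dQ) %*% ha, Wk = t(dK) %*% hb, Wo = dWo))
    },
    stopf("unknown fusion strategy '%s'", strategy)
  )
}

#' Concatenation fusion
#'
#' Fuses two aligned utterance streams by a learned linear map of their
#' concatenation, `h = W [ha; hb] + b`, keeping the shared width `d`.
#'
#' @param ha,hb numeric matrices, T x d (primary / complementary stream).
#' @param params parameter list from [init_fusion_params()] (`W`: d x 2d,
#'   `b`: length d).
#' @return T x d fused matrix.
#' @export
fuse_concat <- function(ha, hb, params) {
  fusion_forward("concat", ha, hb, params)$out
}

#' Summation fusion
#'
#' Parameter-free elementwise sum of two aligned streams.
#'
#' @inheritParams fuse_concat
#' @return T x d fused matrix.
#' @export
fuse_sum <- function(ha, hb) {
  check_pair(ha, hb)
  ha + hb
}

#' Sigmoid-gated fusion
#'
#' Convex elementwise mixing `g * ha + (1 - g) * hb` with a learned gate
#' `g = sigmoid(Wg [ha; hb] + bg)`. The gate is the interpretability signal:
#' values near 1 mean the primary stream dominates.
#'
#' @inheritParams fuse_concat
#' @return list with `fused` (T x d) and `gate` (T x d, or T x 1 for a
#'   scalar gate), every entry strictly in (0, 1).
#' @export
fuse_gated <- function(ha, hb, params) {
  fw <- fusion_forward("gated", ha, hb, params)
  list(fused = fw$out, gate = fw$trace$gate)
}

#' Cross-attention fusion
#'
#' Each primary utterance queries the complementary modality's utterance
#' sequence with scaled dot-product attention (single head, key width `d`);
#' the attended context is concatenated to the primary stream and mapped
#' back to width `d`.
#'
#' @inheritParams fuse_concat
#' @return list with `fused` (T x d) and `attention` (T x T row-stochastic
#'   matrix; row t weights the complementary utterances for query t).
#' @export
fuse_cross_attention <- function(ha, hb, params) {
  fw <- fusion_forward("attention", ha, hb, params)
  list(fused = fw$out, attention = fw$trace$attention)
}

#' Trainable-parameter ledger per fusion stage
#'
#' Exact number of parameters each fusion strategy adds at one stage for a
#' shared latent width `d`: summation adds none, concatenation 2d^2 weights
#' (+ d bias), the elementwise gate 2d^2 + d, cross-attention 4d^2.
#'
#' @param strategy fusion strategy name.
#' @param d shared latent width.
#' @param gate gate granularity for `"gated"` (`"vector"` or `"scalar"`).
#' @return one-row tibble with columns `strategy`, `d`, `weights`, `biases`,
#'   `total`.
#' @export
count_stage_params <- function(strategy, d, gate = c("vector", "scalar")) {
  strategy <- match.arg(strategy, FUSION_STRATEGIES)
  gate <- match.arg(gate)
  counts <- switch(strategy,
    sum = c(0, 0),
    concat = c(2 * d^2, d),
    gated = if (gate == "vector") c(2 * d^2, d) else c(2 * d, 1),
    attention = c(4 * d^2, 0)
  )
  tibble::tibble(strategy = strategy, d = as.integer(d),
                 weights = counts[1], biases = counts[2],
                 total = counts[1] + counts[2])
}
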