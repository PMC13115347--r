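# Shared fixtures: all synthetic, generated in code at test time.

tiny_dims <- list(visual_semantic = 10L, pose = 3L, audio = 6L, text = 8L)

tiny_cfg <- function(seed = 3L, ...) {
  args <- list(n_subjects = 16L, n_positive = 5L,
               utterances_range = c(4L, 7L), dims = tiny_dims, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

tiny_sessions <- function(seed = 3L, ...) simulate_sessions(tiny_cfg(seed, ...))

tiny_fusion_config <- function(vis = "gated", audio = "attention",
                               text = "concat", d = 8L, dropout = 0, ...) {
  fusion_config(vis, audio, text, d = d, dropout = dropout, ...)
}

tiny_model <- function(vis = "gated", audio = "attention", text = "concat",
                       d = 8L, seed = 1L, dropout = 0, ...) {
  fusion_model(tiny_fusion_config(vis, audio, text, d = d, dropout = dropout, ...),
               dims = tiny_dims, seed = seed)
}

# Desk-scale world for the slower recovery/grid tests: paper structure at
# reduced feature widths and session lengths.
desk_cfg <- function(seed = 1L, n_subjects = 200L, n_positive = 35L, ...) {
  args <- list(n_subjects = n_subjects, n_positive = n_positive,
               utterances_range = c(10L, 20L),
               dims = list(visual_semantic = 48L, pose = 3L, audio = 24L,
                           text = 48L),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

rand_pair <- function(T = 5L, d = 6L, seed = 1L) {
  set.seed(seed)
  list(a = matrix(rnorm(T * d), T, d), b = matrix(rnorm(T * d), T, d))
}

# Brute-force pairwise AUC oracle: P(pos > neg) + 0.5 P(tie).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Hand-rolled Kruskal-Wallis H (no tie correction; for tie-free data).
brute_kw_H <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  groups <- as.factor(groups)
  12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
}

# Finite-difference gradient check of a full session loss.
grad_check_model <- function(model, blocks, y = 1, w_pos = 2, training = FALSE,
                             n_per_param = 2L, eps = 1e-5) {
  spec <- train_spec(seed = 1)
  fw <- multifuse:::forward_session_full(model, blocks, training)
  gr <- multifuse:::backward_session(model, fw,
                                     multifuse:::loss_grad_logit(fw$prob, y, w_pos, spec))
  lossfun <- function(m) {
    p <- multifuse:::forward_session_full(m, blocks, training)$prob
    weighted_bce(p, y, w_pos)
  }
  worst <- 0
  for (nm in names(model$params)) {
    pa <- model$params[[nm]]
    for (i in sample(length(pa), min(n_per_param, length(pa)))) {
      m2 <- model; m2$params[[nm]][i] <- pa[i] + eps
      m3 <- model; m3$params[[nm]][i] <- pa[i] - eps
      num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      ana <- if (!is.null(gr[[nm]])) gr[[nm]][i] else 0
      worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
    }
  }
  worst
}
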