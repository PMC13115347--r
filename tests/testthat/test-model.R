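# Model assembly: projections, session forward pass, trace contracts,
# permutation behaviour, identity stages, end-to-end gradients.

test_that("projections map raw widths into the shared latent space", {
  sess <- tiny_sessions()
  m <- tiny_model(d = 8)
  fw <- multifuse:::forward_session_full(m, sess$blocks[[1]])
  # pose block is T x 3 in, T x d out
  proj <- multifuse:::mlp_forward(m$layers$pose, m$params, m$state,
                                  sess$blocks[[1]]$pose, FALSE)
  expect_equal(dim(proj$out), c(sess$t_utt[1], 8L))
  expect_true(is.finite(fw$prob))
})

test_that("shape and missing-block errors are informative", {
  sess <- tiny_sessions()
  m <- tiny_model()
  bl <- sess$blocks[[1]]
  bl$audio <- bl$audio[, 1:3]
  expect_error(forward_session(m, bl), "width 3")
  bl <- sess$blocks[[1]]
  bl$text <- NULL
  expect_error(forward_session(m, bl), "missing the configured 'text'")
})

test_that("evaluation mode is deterministic; dropout only acts in training", {
  sess <- tiny_sessions()
  m <- fusion_model(tiny_fusion_config(dropout = 0.5), dims = tiny_dims, seed = 2)
  m$params <- lapply(m$params, function(x) x + rnorm(length(x), sd = 0.1))
  p1 <- forward_session(m, sess$blocks[[1]])$prob
  p2 <- forward_session(m, sess$blocks[[1]])$prob
  expect_identical(p1, p2)
  set.seed(1); q1 <- forward_session(m, sess$blocks[[1]], training = TRUE)$prob
  set.seed(2); q2 <- forward_session(m, sess$blocks[[1]], training = TRUE)$prob
  expect_false(identical(q1, q2))
})

test_that("untrained model outputs 0.5 and mixes the visual streams evenly", {
  sess <- tiny_sessions()
  m <- tiny_model(vis = "gated")
  fw <- forward_session(m, sess$blocks[[1]])
  expect_equal(fw$prob, 0.5)
  expect_equal(unique(as.vector(fw$trace$gates$vis)), 0.5)
  # zero pooling vector: uniform attention over utterances
  expect_equal(fw$trace$pooling, rep(1 / sess$t_utt[1], sess$t_utt[1]))
})

test_that("trace invariants hold for a trained-like (randomised) model", {
  sess <- tiny_sessions()
  for (vis in c("gated", "attention")) {
    m <- tiny_model(vis = vis, audio = "attention", text = "gated", seed = 5)
    m$params <- lapply(m$params, function(x) x + rnorm(length(x), sd = 0.4))
    for (i in 1:4) {
      tr <- forward_session(m, sess$blocks[[i]])$trace
      for (g in tr$gates) expect_true(all(g > 0 & g < 1))
      for (A in tr$attention)
        expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
      expect_equal(sum(tr$pooling), 1, tolerance = 1e-6)
      expect_true(all(tr$pooling >= 0))
    }
  }
})

test_that("session probability is invariant to utterance permutation", {
  sess <- tiny_sessions()
  set.seed(8)
  for (strategies in list(c("gated", "attention", "concat"),
                          c("sum", "sum", "sum"),
                          c("attention", "gated", "attention"))) {
    m <- tiny_model(strategies[1], strategies[2], strategies[3], seed = 4)
    m$params <- lapply(m$params, function(x) x + rnorm(length(x), sd = 0.3))
    bl <- sess$blocks[[2]]
    perm <- sample(nrow(bl$pose))
    bl_p <- lapply(bl, function(B) B[perm, , drop = FALSE])
    expect_equal(forward_session(m, bl)$prob, forward_session(m, bl_p)$prob,
                 tolerance = 1e-10)
  }
})

test_that("absent modalities are identity stages with no parameters", {
  sess <- tiny_sessions()
  cfg <- tiny_fusion_config(use_audio = FALSE, use_text = FALSE)
  m <- fusion_model(cfg, dims = tiny_dims, seed = 3)
  m$params <- lapply(m$params, function(x) x + rnorm(length(x), sd = 0.2))
  expect_false(any(grepl("^proj\\.(audio|text)\\.", names(m$params))))
  expect_false(any(grepl("^stage\\.(audio|text)\\.", names(m$params))))
  bl <- sess$blocks[[1]]
  p0 <- forward_session(m, bl)$prob
  bl$audio <- bl$audio + 100
  bl$text <- bl$text * -3
  expect_identical(forward_session(m, bl)$prob, p0)
})

test_that("all 64 strategy triples produce finite probabilities", {
  sess <- tiny_sessions()
  bl <- sess$blocks[[1]]
  grid <- expand.grid(v = multifuse:::FUSION_STRATEGIES,
                      a = multifuse:::FUSION_STRATEGIES,
                      t = multifuse:::FUSION_STRATEGIES,
                      stringsAsFactors = FALSE)
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    m <- tiny_model(grid$v[i], grid$a[i], grid$t[i], d = 6L, seed = i)
    forward_session(m, bl)$prob
  }, numeric(1))
  expect_length(probs, 64L)
  expect_true(all(is.finite(probs) & probs > 0 & probs < 1))
})

test_that("model parameter totals track the stage ledger", {
  d <- 12L
  base <- n_model_params(tiny_model("sum", "sum", "sum", d = d))
  for (s in c("concat", "gated", "attention")) {
    m <- tiny_model(s, "sum", "sum", d = d)
    expect_equal(n_model_params(m), base + count_stage_params(s, d)$total)
  }
})

test_that("end-to-end gradients match finite differences", {
  sess <- tiny_sessions()
  m <- tiny_model("gated", "attention", "concat", d = 6, seed = 2)
  set.seed(31)
  m$params <- lapply(m$params, function(x) x + rnorm(length(x), sd = 0.2))
  expect_lt(grad_check_model(m, sess$blocks[[1]], y = 1, w_pos = 3), 1e-3)
  # training mode exercises batch statistics
  m2 <- tiny_model("attention", "gated", "sum", d = 6, seed = 3)
  set.seed(32)
  m2$params <- lapply(m2$params, function(x) x + rnorm(length(x), sd = 0.2))
  expect_lt(grad_check_model(m2, sess$blocks[[2]], y = 0, w_pos = 1,
                             training = TRUE), 1e-3)
})

test_that("temporal attention pooling contracts hold", {
  H <- matrix(rnorm(20), 5, 4)
  # zero weight vector: uniform weights, plain mean
  pf <- multifuse:::pool_forward(H, numeric(4))
  expect_equal(pf$alpha, rep(0.2, 5))
  expect_equal(pf$h, colMeans(H))
  # single utterance
  pf1 <- multifuse:::pool_forward(H[1, , drop = FALSE], rnorm(4))
  expect_equal(pf1$alpha, 1)
  expect_equal(pf1$h, H[1, ])
  # identical rows: output equals the row for any weight vector
  Hs <- matrix(rep(H[1, ], each = 6), 6, 4)
  pfs <- multifuse:::pool_forward(Hs, rnorm(4))
  expect_equal(pfs$h, H[1, ], tolerance = 1e-10)
})
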