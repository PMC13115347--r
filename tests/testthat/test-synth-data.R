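# Synthetic corpus generator: class structure, determinism, planted signal,
# pretraining corpora, fold construction.

test_that("default corpus reproduces the reference class structure", {
  cfg <- synth_config(dims = tiny_dims, seed = 7)  # counts stay 74/13
  sess <- simulate_sessions(cfg)
  expect_equal(nrow(sess), 74L)
  expect_equal(sum(sess$label), 13L)
  expect_equal(sum(sess$label == 0) / sum(sess$label == 1), 61 / 13)
  expect_true(all(sess$t_utt >= 20 & sess$t_utt <= 40))
  # all blocks of a session share T_utt and have no missing rows
  for (i in c(1, 40)) {
    Ts <- vapply(sess$blocks[[i]], nrow, integer(1))
    expect_true(all(Ts == sess$t_utt[i]))
    expect_false(anyNA(unlist(sess$blocks[[i]])))
  }
})

test_that("generation is deterministic given the seed", {
  a <- tiny_sessions(seed = 11)
  b <- tiny_sessions(seed = 11)
  c <- tiny_sessions(seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$blocks[[1]], c$blocks[[1]]))
})

test_that("impossible class counts and invalid knobs are rejected", {
  expect_error(synth_config(n_subjects = 10, n_positive = 10), "n_positive")
  expect_error(synth_config(n_subjects = 10, n_positive = 0), "positive")
  expect_error(tiny_cfg(effect_size = c(visual_semantic = -1, pose = 0,
                                        audio = 0, text = 0)), "effect")
  expect_error(tiny_cfg(utterances_range = c(5L, 2L)), "utterances_range")
})

test_that("zero effect size plants no class signal", {
  cfg <- synth_config(n_subjects = 400, n_positive = 80,
                      utterances_range = c(4L, 8L),
                      dims = list(visual_semantic = 12L, pose = 3L,
                                  audio = 6L, text = 8L),
                      effect_size = c(visual_semantic = 0, pose = 0,
                                      audio = 0, text = 0),
                      seed = 21)
  sess <- simulate_sessions(cfg)
  # project session-mean features onto the generator's own loading (the
  # highest-power direction) and t-test between classes
  u <- multifuse:::modality_structure(cfg, "visual_semantic")$loading
  proj <- vapply(sess$blocks, function(b) mean(b$visual_semantic %*% u), numeric(1))
  p <- t.test(proj[sess$label == 1], proj[sess$label == 0])$p.value
  expect_gt(p, 0.01)
})

test_that("single-modality oracle AUC increases monotonically with effect size", {
  levels <- c(0, 0.4, 0.8, 1.6)
  rho <- vapply(1:3, function(s) {
    aucs <- vapply(levels, function(eff) {
      cfg <- synth_config(n_subjects = 300, n_positive = 60,
                          utterances_range = c(4L, 8L),
                          dims = list(visual_semantic = 12L, pose = 3L,
                                      audio = 6L, text = 8L),
                          effect_size = c(visual_semantic = eff, pose = 0,
                                          audio = 0, text = 0),
                          seed = 100 + s)
      sess <- simulate_sessions(cfg)
      u <- multifuse:::modality_structure(cfg, "visual_semantic")$loading
      score <- vapply(sess$blocks, function(b) mean(b$visual_semantic %*% u),
                      numeric(1))
      roc_auc(score, sess$label)
    }, numeric(1))
    cor(aucs, seq_along(levels), method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0))
})

test_that("pretraining corpus: affect is linearly decodable at delta = 0", {
  cfg <- tiny_cfg(dims = list(visual_semantic = 16L, pose = 3L, audio = 12L,
                              text = 16L))
  corp <- simulate_pretrain_corpus(cfg, "audio", n_samples = 2000, delta = 0)
  expect_s3_class(corp, "pretrain_corpus")
  expect_equal(ncol(corp$features), 12L)
  expect_gte(length(unique(corp$affect_labels)), 2L)
  # independent linear-probe oracle: one-vs-rest least squares
  n <- nrow(corp$features)
  set.seed(1)
  test_idx <- sample(n, n %/% 5)
  Xtr <- cbind(1, corp$features[-test_idx, ])
  Xte <- cbind(1, corp$features[test_idx, ])
  Y <- stats::model.matrix(~ 0 + factor(corp$affect_labels[-test_idx]))
  B <- qr.solve(Xtr, Y)
  acc <- mean(max.col(Xte %*% B) == corp$affect_labels[test_idx])
  chance <- 1 / length(unique(corp$affect_labels))
  expect_gt(acc, chance + 0.1)
})

test_that("domain shift moves the corpus away from the target distribution", {
  cfg <- tiny_cfg(n_subjects = 60, n_positive = 12)
  sess <- simulate_sessions(cfg)
  target_mean <- colMeans(do.call(rbind, lapply(sess$blocks, `[[`, "audio")))
  disc <- vapply(c(0, 5), function(delta) {
    corp <- simulate_pretrain_corpus(cfg, "audio", n_samples = 2000, delta = delta)
    sqrt(sum((colMeans(corp$features) - target_mean)^2))
  }, numeric(1))
  # delta = 0: discrepancy consistent with sampling noise (a few SE per dim)
  n_eff <- 2000
  se <- cfg$noise_sd / sqrt(n_eff)
  expect_lt(disc[1], 6 * se * sqrt(cfg$dims$audio))
  # large delta: strictly larger discrepancy on the same seed
  expect_gt(disc[2], disc[1] * 5)
})

test_that("unknown modality for pretraining corpus errors", {
  expect_error(simulate_pretrain_corpus(tiny_cfg(), "smell"), "unknown modality")
})

test_that("folds are a label-stratified partition of subjects", {
  cfg <- synth_config(dims = tiny_dims, utterances_range = c(2L, 3L), seed = 5)
  sess <- simulate_sessions(cfg)
  folds <- make_subject_folds(sess, k = 5, seed = 2)
  expect_setequal(folds$subject_id, sess$subject_id)
  expect_equal(anyDuplicated(folds$subject_id), 0L)
  pos_per_fold <- tapply(folds$label, folds$fold, sum)
  expect_true(all(pos_per_fold %in% c(2L, 3L)))  # 13 positives over 5 folds
  neg_per_fold <- tapply(1 - folds$label, folds$fold, sum)
  expect_true(all(neg_per_fold >= 1))
  # disjointness of every (train, test) split
  for (f in 1:5) {
    tr <- folds$subject_id[folds$fold != f]
    te <- folds$subject_id[folds$fold == f]
    expect_length(intersect(tr, te), 0)
  }
})

test_that("degenerate fold requests are rejected", {
  sess <- tiny_sessions()
  expect_error(make_subject_folds(sess, k = 1), "k must be >= 2")
  expect_error(make_subject_folds(sess, k = 6), "fewer positive")
  expect_error(make_subject_folds(sess, k = nrow(sess)), "fewer")
})
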