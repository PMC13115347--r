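# Losses, optimisation contracts, early stopping, pretraining transfer
# plumbing.

test_that("pos_weight is the neg/pos ratio of the supplied labels", {
  expect_equal(pos_weight(c(rep(0, 61), rep(1, 13))), 61 / 13)
  expect_equal(round(pos_weight(c(rep(0, 61), rep(1, 13))), 4), 4.6923)
  expect_equal(pos_weight(c(0, 1, 0, 1)), 1)
  expect_equal(pos_weight(c(rep(0, 9), rep(1, 3))), 3)
  expect_error(pos_weight(c(0, 0, 0)), "no positive")
})

test_that("weighted BCE matches closed forms", {
  expect_equal(weighted_bce(c(0.5, 0.5), c(1, 0), w_pos = 1), log(2))
  w <- 61 / 13
  expect_equal(weighted_bce(c(0.5, 0.5), c(1, 0), w_pos = w),
               (w + 1) / 2 * log(2))
  expect_equal(weighted_bce(c(0.5, 0.5), c(1, 0), w_pos = 4.6923),
               (4.6923 + 1) / 2 * log(2))
  expect_equal(weighted_bce(c(0.5, 0.5), c(1, 0), w_pos = 61 / 13), 1.9729,
               tolerance = 1e-4)
  # perfect predictions: loss vanishes up to the clamping constant
  expect_lt(weighted_bce(c(1, 0), c(1, 0), w_pos = 5), 1e-6)
  # w_pos = 1 is exactly unweighted BCE
  set.seed(1)
  p <- runif(20, 0.05, 0.95); y <- rbinom(20, 1, 0.3)
  expect_equal(weighted_bce(p, y, 1), mean(-(y * log(p) + (1 - y) * log(1 - p))))
})

test_that("focal loss reduces to weighted BCE and matches hand values", {
  set.seed(2)
  p <- runif(30, 0.05, 0.95); y <- rbinom(30, 1, 0.3)
  expect_equal(focal_loss(p, y, w_pos = 3.2, alpha = 1, gamma = 0),
               weighted_bce(p, y, w_pos = 3.2))
  expect_equal(focal_loss(0.5, 1, w_pos = 1, alpha = 0.25, gamma = 2),
               0.25 * 0.25 * log(2))
  # near-certain correct positives decay faster than BCE
  ratio <- function(p) focal_loss(p, 1, alpha = 1, gamma = 2) / weighted_bce(p, 1)
  expect_lt(ratio(0.99), ratio(0.9))
  # imbalanced toy: the always-negative classifier is punished more when
  # the minority class is up-weighted
  y <- c(rep(0, 8), rep(1, 2)); p <- rep(0.01, 10)
  expect_gt(weighted_bce(p, y, w_pos = 4), weighted_bce(p, y, w_pos = 1))
})

test_that("gradient clipping bounds the global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(-4, 5))
  gc <- multifuse:::clip_gradients(g, 1.0)
  expect_lte(multifuse:::params_global_norm(gc), 1 + 1e-6)
  # direction preserved
  expect_equal(gc$a / gc$a[1], g$a / g$a[1])
  # already-small gradients untouched
  g2 <- list(a = matrix(1e-3, 2, 2))
  expect_identical(multifuse:::clip_gradients(g2, 1.0), g2)
})

test_that("training separates a high-signal toy and logs clipped norms", {
  cfg <- tiny_cfg(n_subjects = 60, n_positive = 24,
                  utterances_range = c(4L, 8L),
                  effect_size = c(visual_semantic = 3, pose = 0.5,
                                  audio = 1, text = 1),
                  subject_sd = 0.2, seed = 41)
  sess <- simulate_sessions(cfg)
  tr <- sess[1:42, ]; va <- sess[43:60, ]
  fit <- train_fusion_model(tr, va, tiny_fusion_config(dropout = 0.1),
                            train_spec(max_epochs = 50, patience = 50 - 1,
                                       seed = 4))
  pred <- predict_sessions(fit, tr)
  expect_gte(roc_auc(pred$score, pred$label), 0.99)
  expect_true(all(fit$history$grad_norm <= 1 + 1e-6))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$w_pos, pos_weight(tr$label))
})

test_that("early stopping halts before the epoch budget on flat validation", {
  cfg <- tiny_cfg(n_subjects = 30, n_positive = 10,
                  effect_size = c(visual_semantic = 0, pose = 0, audio = 0,
                                  text = 0), seed = 6)
  sess <- simulate_sessions(cfg)
  fit <- train_fusion_model(sess[1:20, ], sess[21:30, ],
                            tiny_fusion_config(),
                            train_spec(max_epochs = 60, patience = 4, seed = 1))
  expect_lt(nrow(fit$history), 60)
})

test_that("subject overlap between train and validation is a hard error", {
  sess <- tiny_sessions()
  expect_error(train_fusion_model(sess[1:10, ], sess[8:16, ],
                                  tiny_fusion_config(), train_spec(seed = 1)),
               "leakage")
})

test_that("training is deterministic given the seed", {
  sess <- tiny_sessions(n_subjects = 24L, n_positive = 8L)
  run <- function() {
    train_fusion_model(sess[1:16, ], sess[17:24, ], tiny_fusion_config(),
                       train_spec(max_epochs = 5, patience = 4, seed = 9))
  }
  f1 <- run(); f2 <- run()
  # identical up to threaded-BLAS reduction order (hardware-stable math)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_equal(f1$model$params, f2$model$params, tolerance = 1e-12)
})

test_that("only model parameters receive updates (no hidden trainables)", {
  sess <- tiny_sessions()
  m <- tiny_model(seed = 7)
  fw <- multifuse:::forward_session_full(m, sess$blocks[[1]], training = TRUE)
  gr <- multifuse:::backward_session(m, fw, 0.3)
  expect_true(all(names(gr) %in% names(m$params)))
  # running statistics are state, never parameters
  expect_false(any(grepl("running_", names(m$params))))
  expect_true(any(grepl("running_", names(m$state))) ||
                !any(vapply(m$layers, function(ls)
                  any(vapply(ls, function(l) l$kind == "batchnorm", logical(1))),
                  logical(1))))
})

test_that("projection pretraining learns affect and round-trips exactly", {
  cfg <- tiny_cfg(dims = list(visual_semantic = 16L, pose = 3L, audio = 10L,
                              text = 12L), seed = 13)
  corp <- simulate_pretrain_corpus(cfg, "audio", n_samples = 600, delta = 0)
  spec <- train_spec(seed = 2)
  proj <- default_projection_specs(cfg$dims, d = 8, dropout = 0)$audio
  ck <- pretrain_projection(corp, proj, spec, epochs = 30)
  expect_s3_class(ck, "projection_checkpoint")
  expect_gt(ck$meta$holdout_accuracy, 1 / ck$meta$n_classes)
  expect_true(all(grepl("^proj\\.audio\\.", names(ck$params))))
  path <- tempfile(fileext = ".json")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  expect_identical(ck$params, ck2$params)
  expect_identical(ck$state[names(ck2$state)], ck2$state)
  # checkpoint initialisation lands in a model and stays trainable
  m <- fusion_model(tiny_fusion_config(d = 8),
                    proj_specs = default_projection_specs(cfg$dims, 8, 0),
                    dims = cfg$dims, seed = 1)
  m2 <- apply_checkpoint(m, ck2)
  expect_equal(m2$params[["proj.audio.l1.W"]], ck$params[["proj.audio.l1.W"]])
  # single-class corpus is rejected
  corp$affect_labels <- rep(1L, length(corp$affect_labels))
  expect_error(pretrain_projection(corp, proj, spec), "single affect class")
})
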