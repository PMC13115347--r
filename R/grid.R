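# Controlled condition grid: 4 fusion strategies at each of 3 positions
# crossed with 3 binary pretraining flags = 512 conditions, executed under
# subject-independent cross-validation.

#' Enumerate grid conditions
#'
#' Full grid: 4^3 fusion-strategy triples x 2^3 pretraining flags = 512
#' conditions, in a deterministic order. Restricting `strategies` (or the
#' flag sets) yields the smaller desk-scale grids.
#'
#' @param strategies fusion strategies to cross over the three positions.
#' @param pretrain_levels logical values each pretraining flag may take.
#' @return tibble: `condition_id`, `vis_fusion`, `audio_fusion`,
#'   `text_fusion`, `pt_visual`, `pt_audio`, `pt_text`, `n_pretrained`.
#' @export
enumerate_conditions <- function(strategies = FUSION_STRATEGIES,
                                 pretrain_levels = c(FALSE, TRUE)) {
  stopifnot(all(strategies %in% FUSION_STRATEGIES))
  grid <- tidyr::expand_grid(vis_fusion = strategies,
                             audio_fusion = strategies,
                             text_fusion = strategies,
                             pt_visual = pretrain_levels,
                             pt_audio = pretrain_levels,
                             pt_text = pretrain_levels)
  grid |>
    dplyr::mutate(condition_id = sprintf("C%03d", dplyr::row_number()),
                  n_pretrained = .data$pt_visual + .data$pt_audio + .data$pt_text) |>
    dplyr::select("condition_id", dplyr::everything())
}

spec_hash <- function(spec) {
  paste(vapply(spec, function(x) paste(format(x), collapse = ","), character(1)),
        collapse = "|")
}

checkpoint_for <- function(checkpoints, flag, modality) {
  if (!flag) return(NULL)
  ck <- checkpoints[[modality]]
  if (is.null(ck))
    stopf("condition requires a pretraining checkpoint for modality '%s' but none was supplied",
          modality)
  ck
}

#' Run one grid condition under subject-independent cross-validation
#'
#' For each fold: the fold is held out as test, the next fold rotates in as
#' validation (early stopping), the rest trains. The positive-class weight
#' is recomputed from each training fold's labels. Flagged modalities are
#' initialised from the supplied checkpoints.
#'
#' @param condition one row of [enumerate_conditions()].
#' @param sessions sessions tibble.
#' @param folds fold assignment from [make_subject_folds()].
#' @param spec a [train_spec()]; its `seed` drives this condition's training.
#' @param checkpoints named list of `projection_checkpoint`s
#'   (`visual_semantic`, `audio`, `text`) for the flagged modalities.
#' @param d shared latent width of the models.
#' @param use_audio,use_text include the acoustic / text branches.
#' @return tibble with one row per fold: metrics (`auc`, `pr_auc`, `f1`,
#'   `balanced_accuracy`, `sensitivity`, `specificity`), `gate_delta` (mean
#'   per-subject semantic-minus-pose gate difference at the intra-visual
#'   stage; NA unless that stage is gated), condition labels and `seed`.
#' @export
run_condition <- function(condition, sessions, folds, spec = train_spec(),
                          checkpoints = list(), d = 32L,
                          use_audio = TRUE, use_text = TRUE) {
  condition <- as.list(condition)
  k <- attr(folds, "k") %||% max(folds$fold)
  cfg <- fusion_config(condition$vis_fusion, condition$audio_fusion,
                       condition$text_fusion, use_audio = use_audio,
                       use_text = use_text, d = d)
  cks <- purrr::compact(list(
    visual_semantic = checkpoint_for(checkpoints, condition$pt_visual, "visual_semantic"),
    audio = checkpoint_for(checkpoints, condition$pt_audio, "audio"),
    text = checkpoint_for(checkpoints, condition$pt_text, "text")))
  fold_of <- stats::setNames(folds$fold, folds$subject_id)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    val_f <- f %% k + 1L
    s_fold <- fold_of[sessions$subject_id]
    test <- sessions[s_fold == f, ]
    val <- sessions[s_fold == val_f, ]
    train <- sessions[!s_fold %in% c(f, val_f), ]
    fit <- train_fusion_model(train, val, cfg, spec = spec,
                              checkpoints = cks,
                              w_pos = pos_weight(train$label))
    pred <- predict_sessions(fit, test, with_trace = TRUE)
    tm <- threshold_metrics(pred$score, pred$label)
    gate_delta <- NA_real_
    if (condition$vis_fusion == "gated") {
      g_means <- vapply(pred$trace, function(tr) mean(tr$gates$vis), numeric(1))
      gate_delta <- mean(2 * g_means - 1)
    }
    res[[f]] <- tibble::tibble(
      condition_id = condition$condition_id, fold = f,
      auc = roc_auc(pred$score, pred$label),
      pr_auc = pr_auc(pred$score, pred$label),
      f1 = tm$f1, balanced_accuracy = tm$balanced_accuracy,
      sensitivity = tm$sensitivity, specificity = tm$specificity,
      gate_delta = gate_delta,
      vis_fusion = condition$vis_fusion, audio_fusion = condition$audio_fusion,
      text_fusion = condition$text_fusion, pt_visual = condition$pt_visual,
      pt_audio = condition$pt_audio, pt_text = condition$pt_text,
      n_pretrained = condition$n_pretrained, seed = spec$seed,
      spec_hash = spec_hash(spec[setdiff(names(spec), "seed")]))
  }
  dplyr::bind_rows(res)
}

#' Run a set of grid conditions
#'
#' Executes [run_condition()] for every row of `conditions`, deriving one
#' training seed per condition from `seed`. All conditions share the same
#' architecture and training hyperparameters (constancy is auditable via the
#' `spec_hash` column).
#'
#' @inheritParams run_condition
#' @param conditions tibble from [enumerate_conditions()] (possibly a
#'   subset).
#' @param seed base seed; condition i trains with child seed i.
#' @param verbose print progress.
#' @return long results tibble (rows = condition x fold).
#' @export
run_grid <- function(conditions, sessions, folds, spec = train_spec(),
                     checkpoints = list(), d = 32L, seed = 1L,
                     use_audio = TRUE, use_text = TRUE, verbose = FALSE) {
  res <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    sp <- spec
    sp$seed <- child_seed(seed, 5000L + i)
    if (verbose)
      message(sprintf("[%d/%d] %s", i, nrow(conditions), conditions$condition_id[i]))
    res[[i]] <- run_condition(conditions[i, ], sessions, folds, sp,
                              checkpoints = checkpoints, d = d,
                              use_audio = use_audio, use_text = use_text)
  }
  aggregate_results(res)
}

#' Validate and combine per-condition results
#'
#' Binds per-condition result tables into one long table, rejecting empty
#' input and duplicate (condition, fold, seed) rows.
#'
#' @param results a results tibble or list of them.
#' @return long results tibble.
#' @export
aggregate_results <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  out <- dplyr::bind_rows(results)
  if (nrow(out) == 0) stopf("no results to aggregate")
  key <- paste(out$condition_id, out$fold, out$seed)
  if (anyDuplicated(key))
    stopf("duplicate (condition, fold, seed) rows: %s",
          key[which(duplicated(key))[1]])
  out
}
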