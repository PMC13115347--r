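# Configuration and file round-trips. Configs are YAML or JSON; datasets
# round-trip as a JSON manifest plus a flat long CSV (text-only, portable);
# checkpoints and models round-trip as JSON at full double precision.

default_run_config <- function() {
  list(
    seed = 1L,
    data = list(n_subjects = 74L, n_positive = 13L,
                utterances_range = c(20L, 40L),
                dims = list(visual_semantic = 768L, pose = 3L, audio = 88L,
                            text = 1024L),
                effect_size = list(visual_semantic = 1.0, pose = 0.35,
                                   audio = 0.6, text = 0.6),
                subject_sd = 0.6, noise_sd = 1.0, mu = 1.0,
                pretrain_shift = list(visual_semantic = 0, audio = 0, text = 0)),
    model = list(d = 256L, dropout = 0.3, gate = "vector", use_audio = TRUE,
                 use_text = TRUE),
    train = list(lr = 1e-3, weight_decay = 1e-4, grad_clip_norm = 1.0,
                 max_epochs = 100L, patience = 10L, batch_size = 8L,
                 loss = "weighted_bce", focal_alpha = 0.25, focal_gamma = 2.0),
    grid = list(strategies = FUSION_STRATEGIES, k_folds = 5L,
                pretrain_corpus_n = 2000L)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stopf("unknown config key '%s%s'", path, unknown[1])
  for (nm in names(user)) {
    here <- paste0(path, nm)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) stopf("config key '%s' must be a mapping", here)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], paste0(here, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  # constructors perform the cross-field checks
  do.call(synth_config, c(cfg$data, list(seed = cfg$seed)))
  do.call(train_spec, c(cfg$train, list(seed = cfg$seed)))
  if (!cfg$model$gate %in% c("vector", "scalar")) stopf("config key 'model.gate' invalid")
  if (!all(cfg$grid$strategies %in% FUSION_STRATEGIES))
    stopf("config key 'grid.strategies' invalid")
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`, needs the yaml package) or JSON config,
#' fills every omitted key with its default (shared latent width 256,
#' AdamW lr 1e-3 / weight decay 1e-4 / clip 1.0, the 74/13 corpus), rejects
#' unknown keys by name, and applies cross-field checks.
#'
#' @param path config file path, or NULL for the full default tree.
#' @return validated, fully defaulted config list.
#' @export
load_run_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stopf("the 'yaml' package is required for YAML configs")
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else stopf("config must be .yaml, .yml or .json (got .%s)", ext)
    if (is.null(user)) user <- list()
  }
  validate_run_config(merge_config(default_run_config(), user))
}

#' Write a run configuration
#'
#' @param cfg config list (as from [load_run_config()]).
#' @param path output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the 'yaml' package is required for YAML configs")
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# Array (de)serialisation for JSON checkpoints. Values are written as C99
# hex-float strings so the round-trip is bit-exact (decimal JSON numbers can
# lose the last ulp).

pack_array <- function(x) list(dim = dim(x) %||% length(x),
                               values = sprintf("%a", as.vector(x)))

unpack_array <- function(p) {
  v <- as.numeric(unlist(p$values))
  d <- as.integer(unlist(p$dim))
  if (length(d) > 1) array(v, dim = d) else v
}

pack_params <- function(params) lapply(params, pack_array)

unpack_params <- function(packed) lapply(packed, unpack_array)

#' Save / load a projection checkpoint
#'
#' JSON serialisation at full double precision; round-trips are exact.
#'
#' @param checkpoint a `projection_checkpoint`.
#' @param path file path.
#' @return `path` invisibly (save); the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "projection_checkpoint"))
  jsonlite::write_json(list(modality = checkpoint$modality,
                            params = pack_params(checkpoint$params),
                            state = pack_params(checkpoint$state),
                            meta = checkpoint$meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(modality = x$modality, params = unpack_params(x$params),
                 state = unpack_params(x$state), meta = x$meta),
            class = "projection_checkpoint")
}

#' Save / load a fusion model
#'
#' Serialises configuration, projection specs and all parameter/state arrays
#' to JSON; loading rebuilds the architecture and restores the arrays.
#'
#' @param model a `fusion_model` (or `fusion_fit`, whose model is saved).
#' @param path file path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  if (inherits(model, "fusion_fit")) model <- model$model
  stopifnot(inherits(model, "fusion_model"))
  jsonlite::write_json(
    list(config = unclass(model$config),
         proj_specs = lapply(model$proj_specs, unclass),
         params = pack_params(model$params), state = pack_params(model$state),
         seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path)
  cfg <- do.call(fusion_config, x$config[c("vis_fusion", "audio_fusion",
                                           "text_fusion", "use_audio",
                                           "use_text", "d", "gate", "dropout")])
  specs <- lapply(x$proj_specs, function(s) {
    do.call(projection_spec, s[c("modality", "input_dim", "output_dim",
                                 "hidden", "norm", "activation", "dropout",
                                 "n_blocks", "pre_norm")])
  })
  model <- fusion_model(cfg, proj_specs = specs, seed = x$seed %||% 1L)
  params <- unpack_params(x$params)
  state <- unpack_params(x$state)
  stopifnot(setequal(names(params), names(model$params)))
  model$params <- params[names(model$params)]
  model$state <- state[names(model$state)]
  model
}

# Dataset round-trip --------------------------------------------------------

#' Write / read a session dataset
#'
#' One directory per corpus: `manifest.json` (subject ids, labels, dims,
#' config echo) plus `features.csv`, a flat long table
#' (`subject_id`, `utterance_idx`, `modality`, `feature_idx`, `value`) for
#' interoperability. Intended for small corpora; large corpora should be
#' regenerated from their config and seed.
#'
#' @param sessions sessions tibble from [simulate_sessions()].
#' @param dir output directory (created).
#' @param config optional config echoed into the manifest.
#' @return `dir` invisibly (write); the sessions tibble (read).
#' @export
write_session_dataset <- function(sessions, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- lapply(sessions$blocks[[1]], ncol)
  manifest <- list(subject_id = sessions$subject_id, label = sessions$label,
                   t_utt = sessions$t_utt, dims = dims,
                   config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- purrr::map2_dfr(sessions$subject_id, sessions$blocks, function(sid, bl) {
    purrr::map_dfr(names(bl), function(m) {
      B <- bl[[m]]
      tibble::tibble(subject_id = sid,
                     utterance_idx = rep(seq_len(nrow(B)), times = ncol(B)),
                     modality = m,
                     feature_idx = rep(seq_len(ncol(B)), each = nrow(B)),
                     value = as.vector(B))
    })
  })
  readr::write_csv(flat, file.path(dir, "features.csv"))
  invisible(dir)
}

#' @rdname write_session_dataset
#' @export
read_session_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  flat <- readr::read_csv(file.path(dir, "features.csv"),
                          show_col_types = FALSE)
  blocks <- purrr::map(manifest$subject_id, function(sid) {
    sub <- flat[flat$subject_id == sid, ]
    bl <- lapply(split(sub, sub$modality), function(s) {
      Tn <- max(s$utterance_idx); Dn <- max(s$feature_idx)
      M <- matrix(NA_real_, Tn, Dn)
      M[cbind(s$utterance_idx, s$feature_idx)] <- s$value
      M
    })
    bl[intersect(names(manifest$dims), names(bl))]
  })
  tibble::tibble(subject_id = manifest$subject_id,
                 label = as.integer(manifest$label),
                 t_utt = as.integer(manifest$t_utt), blocks = blocks)
}

#' Run the full analysis pipeline
#'
#' Function-level equivalent of the simulate / pretrain / run-grid / analyze
#' / report command surface: simulates the target corpus and folds, pretrains
#' flagged projection heads on their auxiliary corpora, runs the requested
#' condition grid under subject-independent CV, analyses the results and
#' writes `results.csv`, `report.json` (+ CSV tables) and a `manifest.json`
#' tying the artifacts together.
#'
#' @param config config list from [load_run_config()] (NULL = defaults).
#' @param out_dir output directory.
#' @param conditions condition tibble (NULL = full 512-condition grid).
#' @param d latent width override for the executed models (the full-width
#'   default is expensive; desk-scale analyses use a small `d`).
#' @param verbose print progress.
#' @return list with `results`, `report` and output paths.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("mfrun"),
                         conditions = NULL, d = NULL, verbose = FALSE) {
  cfg <- if (is.null(config)) load_run_config(NULL) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(synth_config, c(cfg$data, list(seed = cfg$seed)))
  sessions <- simulate_sessions(scfg)
  folds <- make_subject_folds(sessions, k = cfg$grid$k_folds, seed = cfg$seed)
  if (is.null(conditions)) conditions <- enumerate_conditions(cfg$grid$strategies)
  if (is.null(d)) d <- cfg$model$d
  spec <- do.call(train_spec, c(cfg$train, list(seed = cfg$seed)))
  proj <- default_projection_specs(cfg$data$dims, d, cfg$model$dropout)
  need <- c(visual_semantic = any(conditions$pt_visual),
            audio = any(conditions$pt_audio), text = any(conditions$pt_text))
  checkpoints <- list()
  for (m in names(need)[need]) {
    corpus <- simulate_pretrain_corpus(scfg, m, n_samples = cfg$grid$pretrain_corpus_n)
    checkpoints[[m]] <- pretrain_projection(corpus, proj[[m]], spec)
  }
  results <- run_grid(conditions, sessions, folds, spec,
                      checkpoints = checkpoints, d = d, seed = cfg$seed,
                      use_audio = cfg$model$use_audio,
                      use_text = cfg$model$use_text, verbose = verbose)
  report <- analyze_results(results)
  results_path <- file.path(out_dir, "results.csv")
  report_path <- file.path(out_dir, "report.json")
  readr::write_csv(results, results_path)
  write_stat_report(report, report_path)
  jsonlite::write_json(
    list(seed = cfg$seed, n_conditions = nrow(conditions), d = d,
         config = cfg, outputs = list(results = results_path,
                                      report = report_path)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  list(results = results, report = report, out_dir = out_dir,
       results_path = results_path, report_path = report_path)
}
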