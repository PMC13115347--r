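# Model assembly: per-modality projection heads into a shared latent space,
# three staged fusion positions (vis: semantic+pose, audio: +acoustic,
# text: +linguistic), attention-based temporal pooling over utterances, and
# a sigmoid classifier head. Forward and backward passes are explicit; all
# trainable parameters live in one flat named list so the optimiser, the
# gradient checker and the checkpoint writer share a single representation.

MODALITIES <- c("visual_semantic", "pose", "audio", "text")

#' Projection head specification for one modality
#'
#' Describes the small MLP that maps raw modality features (width
#' `input_dim`) into the shared latent space (width `output_dim`), as
#' `n_blocks` repetitions of Linear -> normalisation -> activation ->
#' Dropout. Visual blocks are additionally layer-normalised (non-affine)
#' before projection to remove scale discrepancies between semantic and
#' geometric features.
#'
#' @param modality one of `"visual_semantic"`, `"pose"`, `"audio"`, `"text"`.
#' @param input_dim raw feature width.
#' @param output_dim shared latent width `d`.
#' @param hidden width after the first block when `n_blocks > 1`.
#' @param norm `"none"`, `"batch"` or `"layer"` normalisation inside blocks.
#' @param activation `"relu"` or `"gelu"`.
#' @param dropout dropout rate (train mode only).
#' @param n_blocks number of blocks (1 or 2).
#' @param pre_norm apply non-affine layer normalisation to the raw input.
#' @return a `projection_spec` list.
#' @export
projection_spec <- function(modality, input_dim, output_dim = 256, hidden = NULL,
                            norm = c("none", "batch", "layer"),
                            activation = c("relu", "gelu"),
                            dropout = 0.3, n_blocks = 1, pre_norm = FALSE) {
  modality <- match.arg(modality, MODALITIES)
  norm <- match.arg(norm)
  activation <- match.arg(activation)
  if (input_dim < 1 || output_dim < 1) stopf("projection dims must be >= 1")
  if (n_blocks > 1 && is.null(hidden)) hidden <- output_dim
  structure(list(modality = modality, input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim), hidden = hidden,
                 norm = norm, activation = activation, dropout = dropout,
                 n_blocks = as.integer(n_blocks), pre_norm = pre_norm),
            class = "projection_spec")
}

#' Default projection heads for the four modalities
#'
#' Visual-semantic: Linear(dv -> d) + ReLU + Dropout; pose mirrors it from
#' its 3 angles; audio: 2 blocks of Linear -> BatchNorm -> ReLU -> Dropout
#' through a d/2-wide hidden layer (88 -> 128 -> 256 at the default d = 256);
#' text: 2 blocks of Linear -> LayerNorm -> GELU -> Dropout. Both visual
#' blocks are layer-normalised before projection.
#'
#' @param dims named list of raw feature widths per modality.
#' @param d shared latent width.
#' @param dropout dropout rate used in every head.
#' @return named list of [projection_spec()]s.
#' @export
default_projection_specs <- function(dims = list(visual_semantic = 768, pose = 3,
                                                 audio = 88, text = 1024),
                                     d = 256, dropout = 0.3) {
  list(
    visual_semantic = projection_spec("visual_semantic", dims$visual_semantic, d,
                                      activation = "relu", dropout = dropout,
                                      pre_norm = TRUE),
    pose = projection_spec("pose", dims$pose, d, activation = "relu",
                           dropout = dropout, pre_norm = TRUE),
    audio = projection_spec("audio", dims$audio, d, hidden = max(2L, d %/% 2L),
                            norm = "batch", activation = "relu",
                            dropout = dropout, n_blocks = 2),
    text = projection_spec("text", dims$text, d, hidden = d, norm = "layer",
                           activation = "gelu", dropout = dropout, n_blocks = 2)
  )
}

# Materialise a projection spec into layers + initial parameters/state.
build_projection <- function(prefix, spec) {
  layers <- list(); params <- list(); state <- list()
  add <- function(x) {
    layers[[length(layers) + 1L]] <<- x$layer
    params[names(x$params)] <<- x$params
    if (!is.null(x$state)) state[names(x$state)] <<- x$state
  }
  if (spec$pre_norm) add(make_layernorm(paste0(prefix, ".ln0"), spec$input_dim, affine = FALSE))
  widths <- if (spec$n_blocks == 1L) c(spec$input_dim, spec$output_dim)
            else c(spec$input_dim, spec$hidden, spec$output_dim)
  for (i in seq_len(spec$n_blocks)) {
    p <- paste0(prefix, ".l", i)
    add(make_linear(p, widths[i], widths[i + 1]))
    if (spec$norm == "batch") add(make_batchnorm(paste0(p, ".bn"), widths[i + 1]))
    if (spec$norm == "layer") add(make_layernorm(paste0(p, ".ln"), widths[i + 1]))
    add(make_activation(spec$activation))
    add(make_dropout(spec$dropout))
  }
  list(layers = layers, params = params, state = state)
}

#' Fusion architecture configuration
#'
#' One point of the strategy grid: which fusion operator acts at each of the
#' three integration positions, whether the acoustic/text branches are
#' present at all, the shared latent width and the gate granularity.
#'
#' @param vis_fusion,audio_fusion,text_fusion fusion strategy at each
#'   position (`"concat"`, `"sum"`, `"gated"`, `"attention"`).
#' @param use_audio,use_text include the acoustic / text branch; when FALSE
#'   the corresponding stage is an identity pass-through and its parameters
#'   are not instantiated.
#' @param d shared latent width.
#' @param gate `"vector"` (elementwise) or `"scalar"` gate for gated stages.
#' @param dropout dropout rate for the projection heads.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(vis_fusion = "gated", audio_fusion = "attention",
                          text_fusion = "concat", use_audio = TRUE,
                          use_text = TRUE, d = 256,
                          gate = c("vector", "scalar"), dropout = 0.3) {
  gate <- match.arg(gate)
  for (s in c(vis_fusion, audio_fusion, text_fusion)) {
    if (!s %in% FUSION_STRATEGIES)
      stopf("unknown fusion strategy '%s' (expected one of %s)", s,
            paste(FUSION_STRATEGIES, collapse = ", "))
  }
  structure(list(vis_fusion = vis_fusion, audio_fusion = audio_fusion,
                 text_fusion = text_fusion, use_audio = isTRUE(use_audio),
                 use_text = isTRUE(use_text), d = as.integer(d), gate = gate,
                 dropout = dropout),
            class = "fusion_config")
}

stage_prefix <- function(name) paste0("stage.", name)

# Attach prefixed fusion-stage parameters to the flat list.
init_stage <- function(name, strategy, d, gate) {
  par <- init_fusion_params(strategy, d, gate)
  if (length(par) == 0) return(list(par_names = character(0), params = list()))
  nms <- paste0(stage_prefix(name), ".", names(par))
  list(par_names = stats::setNames(nms, names(par)),
       params = stats::setNames(par, nms))
}

stage_par <- function(model, st) {
  stats::setNames(lapply(st$par_names, function(nm) model$params[[nm]]), names(st$par_names))
}

prefix_grads <- function(grads, par_names) {
  if (length(grads) == 0) return(list())
  stats::setNames(grads, unname(par_names[names(grads)]))
}

#' Build a fusion model
#'
#' Initialises all trainable parameters for the configured architecture.
#' Gate weights, the pooling vector and the classifier start at zero, so an
#' untrained model mixes both visual streams evenly (gate 0.5), pools
#' uniformly and outputs probability 0.5.
#'
#' @param config a [fusion_config()].
#' @param proj_specs named list of [projection_spec()]s; defaults to
#'   [default_projection_specs()] for `dims`.
#' @param dims raw feature widths (used when `proj_specs` is NULL).
#' @param seed integer seed for weight initialisation.
#' @return a `fusion_model` object.
#' @export
fusion_model <- function(config, proj_specs = NULL,
                         dims = list(visual_semantic = 768, pose = 3,
                                     audio = 88, text = 1024),
                         seed = 1L) {
  stopifnot(inherits(config, "fusion_config"))
  if (is.null(proj_specs))
    proj_specs <- default_projection_specs(dims, config$d, config$dropout)
  for (m in names(proj_specs)) {
    if (proj_specs[[m]]$output_dim != config$d)
      stopf("projection for '%s' outputs %d but shared width is %d",
            m, proj_specs[[m]]$output_dim, config$d)
  }
  used <- c("visual_semantic", "pose",
            if (config$use_audio) "audio", if (config$use_text) "text")
  set.seed(child_seed(seed, 11L))
  params <- list(); state <- list(); layers <- list()
  for (m in used) {
    bp <- build_projection(paste0("proj.", m), proj_specs[[m]])
    layers[[m]] <- bp$layers
    params[names(bp$params)] <- bp$params
    state[names(bp$state)] <- bp$state
  }
  stages <- list(vis = c(init_stage("vis", config$vis_fusion, config$d, config$gate),
                         strategy = config$vis_fusion))
  if (config$use_audio)
    stages$audio <- c(init_stage("audio", config$audio_fusion, config$d, config$gate),
                      strategy = config$audio_fusion)
  if (config$use_text)
    stages$text <- c(init_stage("text", config$text_fusion, config$d, config$gate),
                     strategy = config$text_fusion)
  for (st in stages) params[names(st$params)] <- st$params
  params[["pool.w"]] <- numeric(config$d)
  params[["clf.W"]] <- matrix(0, 1, config$d)
  params[["clf.b"]] <- 0
  structure(list(config = config, proj_specs = proj_specs, layers = layers,
                 stages = stages, params = params, state = state,
                 d = config$d, seed = seed),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<fusion_model> d=%d | vis:%s audio:%s text:%s | params: %d\n",
              cfg$d, cfg$vis_fusion,
              if (cfg$use_audio) cfg$audio_fusion else "(absent)",
              if (cfg$use_text) cfg$text_fusion else "(absent)",
              n_model_params(x)))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model a `fusion_model`.
#' @return integer count over all trainable arrays.
#' @export
n_model_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

check_blocks <- function(model, blocks) {
  used <- names(model$layers)
  for (m in used) {
    if (is.null(blocks[[m]])) stopf("session is missing the configured '%s' block", m)
    if (!is.matrix(blocks[[m]])) stopf("block '%s' must be a matrix", m)
    if (ncol(blocks[[m]]) != model$proj_specs[[m]]$input_dim)
      stopf("block '%s' has width %d, projection expects %d",
            m, ncol(blocks[[m]]), model$proj_specs[[m]]$input_dim)
  }
  Ts <- vapply(used, function(m) nrow(blocks[[m]]), integer(1))
  if (length(unique(Ts)) != 1L) stopf("modality blocks disagree on utterance count")
  if (Ts[1] < 1L) stopf("session has no utterances")
  invisible(TRUE)
}

# Temporal attention pooling: alpha = softmax(H w), h = sum_t alpha_t H_t.
pool_forward <- function(H, w) {
  s <- as.vector(H %*% w)
  alpha <- softmax_vec(s)
  list(h = as.vector(crossprod(H, alpha)), alpha = alpha, H = H)
}

pool_backward <- function(cache, w, dh) {
  H <- cache$H; alpha <- cache$alpha
  dalpha <- as.vector(H %*% dh)
  ds <- (dalpha - sum(dalpha * alpha)) * alpha
  list(dH = outer(alpha, dh) + outer(ds, w), dw = as.vector(crossprod(H, ds)))
}

# Full forward pass with caches (internal; the exported forward_session()
# returns only probability and trace).
forward_session_full <- function(model, blocks, training = FALSE) {
  check_blocks(model, blocks)
  params <- model$params
  new_state <- list()
  proj <- list(); caches <- list(proj = list(), stage = list())
  for (m in names(model$layers)) {
    fw <- mlp_forward(model$layers[[m]], params, model$state, blocks[[m]], training)
    proj[[m]] <- fw$out
    caches$proj[[m]] <- fw$caches
    if (length(fw$state)) new_state[names(fw$state)] <- fw$state
  }
  trace <- list(gates = list(), attention = list())
  run_stage <- function(name, ha, hb) {
    st <- model$stages[[name]]
    fw <- fusion_forward(st$strategy, ha, hb, stage_par(model, st))
    caches$stage[[name]] <<- fw$cache
    if (!is.null(fw$trace$gate)) trace$gates[[name]] <<- fw$trace$gate
    if (!is.null(fw$trace$attention)) trace$attention[[name]] <<- fw$trace$attention
    fw$out
  }
  v <- run_stage("vis", proj$visual_semantic, proj$pose)
  if (model$config$use_audio) v <- run_stage("audio", v, proj$audio)
  if (model$config$use_text) v <- run_stage("text", v, proj$text)
  pf <- pool_forward(v, params[["pool.w"]])
  trace$pooling <- pf$alpha
  z <- sum(params[["clf.W"]] * pf$h) + params[["clf.b"]]
  prob <- sigmoid(z)
  list(prob = prob, logit = z, trace = trace, h = pf$h, pool = pf,
       caches = caches, state = new_state)
}

#' Run one session through the model
#'
#' @param model a `fusion_model`.
#' @param blocks named list of T x dim matrices (one per configured
#'   modality), or a one-row sessions tibble.
#' @param training use train-mode stochastic layers (dropout, batch
#'   statistics); evaluation mode is deterministic.
#' @return list with `prob` (depression probability in (0,1)) and `trace`
#'   (gate matrices per gated stage, attention maps per attention stage,
#'   pooling weights `pooling` summing to 1).
#' @export
forward_session <- function(model, blocks, training = FALSE) {
  if (is.data.frame(blocks)) {
    stopifnot(nrow(blocks) == 1L)
    blocks <- blocks$blocks[[1L]]
  }
  fw <- forward_session_full(model, blocks, training)
  list(prob = fw$prob, trace = fw$trace)
}

# Backward pass given d(loss)/d(logit). Returns flat gradient list.
backward_session <- function(model, fw, dlogit) {
  params <- model$params
  grads <- list()
  h <- fw$h
  grads[["clf.W"]] <- matrix(h * dlogit, 1)
  grads[["clf.b"]] <- dlogit
  dh <- as.vector(params[["clf.W"]]) * dlogit
  pb <- pool_backward(fw$pool, params[["pool.w"]], dh)
  grads[["pool.w"]] <- pb$dw
  dv <- pb$dH
  back_stage <- function(name, dout) {
    st <- model$stages[[name]]
    bw <- fusion_backward(st$strategy, stage_par(model, st), fw$caches$stage[[name]], dout)
    grads <<- params_axpy(grads, prefix_grads(bw$grads, st$par_names))
    bw
  }
  dproj <- list()
  if (model$config$use_text) {
    bw <- back_stage("text", dv); dv <- bw$da; dproj$text <- bw$db
  }
  if (model$config$use_audio) {
    bw <- back_stage("audio", dv); dv <- bw$da; dproj$audio <- bw$db
  }
  bw <- back_stage("vis", dv)
  dproj$visual_semantic <- bw$da
  dproj$pose <- bw$db
  for (m in names(dproj)) {
    mb <- mlp_backward(model$layers[[m]], params, fw$caches$proj[[m]], dproj[[m]])
    grads <- params_axpy(grads, mb$grads)
  }
  grads
}

#' Score a set of sessions
#'
#' Evaluation-mode forward pass over every session; deterministic.
#'
#' @param model a `fusion_model` (or `fusion_fit`).
#' @param sessions sessions tibble from [simulate_sessions()] (columns
#'   `subject_id`, `label`, `blocks`).
#' @param with_trace also return per-session trace bundles (list-column).
#' @return tibble with `subject_id`, `label`, `score` (and `trace`).
#' @export
predict_sessions <- function(model, sessions, with_trace = FALSE) {
  if (inherits(model, "fusion_fit")) model <- model$model
  out <- purrr::map(sessions$blocks, function(b) forward_session_full(model, b, training = FALSE))
  res <- tibble::tibble(subject_id = sessions$subject_id, label = sessions$label,
                        score = vapply(out, `[[`, numeric(1), "prob"))
  if (with_trace) res$trace <- purrr::map(out, "trace")
  res
}
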