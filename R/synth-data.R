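# Synthetic multimodal corpus generator. Emulates the statistical structure
# of a PHQ-9-labelled interview corpus: 74 subjects (13 depressed), ragged
# sessions of utterance-level feature vectors in four modality blocks, a
# single affect factor shared across modalities (so modalities are
# complementary and gating has something to redistribute), subject random
# effects, and per-modality auxiliary "affective pretraining" corpora with a
# controllable domain-shift knob.
#
# Generative model: each modality m has a fixed unit loading vector u_m
# (drawn once from the structural seed). A subject with label y has latent
# affect z = mu * y + N(0, subject_sd^2); every utterance row of block m is
#   effect_size_m * z * u_m + noise_sd * N(0, I).

#' Configuration of the synthetic corpus
#'
#' Defaults state the reference world: 74 subjects of whom 13 are positive
#' (prevalence 17.6%, imbalance about 1:4.7), 20-40 utterances per session,
#' feature widths 768 (visual-semantic), 3 (head pose: pitch/yaw/roll),
#' 88 (acoustic functionals), 1024 (text embedding).
#'
#' @param n_subjects,n_positive subject counts (positives < subjects).
#' @param utterances_range inclusive integer range of utterances per session.
#' @param dims named list of feature widths per modality.
#' @param effect_size named numeric: standardised class signal per modality
#'   (0 = that modality carries no label information).
#' @param subject_sd between-subject random-effect scale on the latent.
#' @param noise_sd within-session feature noise scale.
#' @param mu latent class separation (mean latent shift for positives).
#' @param pretrain_shift named numeric: domain-shift magnitude delta for each
#'   modality's pretraining corpus (0 = matched domain).
#' @param seed base seed; all randomness derives from it via child seeds.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_subjects = 74L, n_positive = 13L,
                         utterances_range = c(20L, 40L),
                         dims = list(visual_semantic = 768L, pose = 3L,
                                     audio = 88L, text = 1024L),
                         effect_size = c(visual_semantic = 1.0, pose = 0.35,
                                         audio = 0.6, text = 0.6),
                         subject_sd = 0.6, noise_sd = 1.0, mu = 1.0,
                         pretrain_shift = c(visual_semantic = 0, audio = 0,
                                            text = 0),
                         seed = 1L) {
  if (n_positive >= n_subjects) stopf("n_positive must be < n_subjects")
  if (n_positive < 1) stopf("need at least one positive subject")
  if (any(unlist(dims) < 1)) stopf("all feature dims must be >= 1")
  if (any(effect_size < 0)) stopf("effect sizes must be >= 0")
  if (any(pretrain_shift < 0)) stopf("pretrain shifts must be >= 0")
  if (utterances_range[1] < 1 || utterances_range[2] < utterances_range[1])
    stopf("invalid utterances_range")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_positive = as.integer(n_positive),
                 utterances_range = as.integer(utterances_range),
                 dims = lapply(dims, as.integer),
                 effect_size = effect_size, subject_sd = subject_sd,
                 noise_sd = noise_sd, mu = mu,
                 pretrain_shift = pretrain_shift, seed = as.integer(seed)),
            class = "synth_config")
}

# Fixed structural directions shared by the target corpus and every
# pretraining corpus: the affect loading u_m, an orthogonal nuisance
# direction (domain-shifted corpora rotate their loading toward it) and a
# mean-shift direction.
modality_structure <- function(cfg, modality) {
  dim_m <- cfg$dims[[modality]]
  set.seed(child_seed(cfg$seed, 7L + match(modality, MODALITIES)))
  u <- stats::rnorm(dim_m)
  u <- u / sqrt(sum(u^2))
  if (dim_m > 1) {
    v <- stats::rnorm(dim_m)
    v <- v - sum(v * u) * u
    v <- v / sqrt(sum(v^2))
  } else v <- u
  s <- stats::rnorm(dim_m)
  s <- s / sqrt(sum(s^2))
  list(loading = u, nuisance = v, shift_dir = s)
}

#' Simulate the target session corpus
#'
#' Generates one session per subject: a binary label, a latent affect score
#' with subject random effect, and one T x dim feature block per modality
#' whose rows carry the latent along the modality's loading direction plus
#' isotropic noise. Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return tibble with one row per subject: `subject_id`, `label`, `t_utt`
#'   and a `blocks` list-column of named T x dim matrices.
#' @export
simulate_sessions <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  structure_m <- lapply(stats::setNames(nm = names(cfg$dims)),
                        function(m) modality_structure(cfg, m))
  set.seed(child_seed(cfg$seed, 101L))
  n <- cfg$n_subjects
  labels <- integer(n)
  labels[sample(n, cfg$n_positive)] <- 1L
  t_utt <- sample(seq(cfg$utterances_range[1], cfg$utterances_range[2]),
                  n, replace = TRUE)
  z_subject <- cfg$mu * labels + stats::rnorm(n, sd = cfg$subject_sd)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    Ti <- t_utt[i]
    bl <- list()
    for (m in names(cfg$dims)) {
      dim_m <- cfg$dims[[m]]
      eff <- cfg$effect_size[[m]] %||% 0
      signal <- outer(rep(z_subject[i] * eff, Ti), structure_m[[m]]$loading)
      bl[[m]] <- signal + matrix(stats::rnorm(Ti * dim_m, sd = cfg$noise_sd),
                                 Ti, dim_m)
    }
    blocks[[i]] <- bl
  }
  tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)),
                 label = labels, t_utt = as.integer(t_utt), blocks = blocks)
}

#' Simulate an affective pretraining corpus for one modality
#'
#' Rows carry a discrete affect class whose latent level loads on the same
#' feature direction as the target corpus when `delta = 0`. Increasing the
#' domain-shift `delta` (taken from `cfg$pretrain_shift` unless overridden)
#' moves the corpus away from the target distribution: the feature mean is
#' shifted by `delta * noise_sd`, the noise covariance is scaled by
#' `(1 + delta)`, and the affect loading is rotated toward an orthogonal
#' nuisance direction with weight `delta / (1 + delta)` — emulating a
#' pretraining source whose feature-affect relationship no longer matches
#' the target domain (the mechanism behind negative transfer).
#'
#' @param cfg a [synth_config()].
#' @param modality `"visual_semantic"`, `"audio"` or `"text"`.
#' @param n_samples number of corpus rows.
#' @param n_classes number of affect classes (>= 2).
#' @param delta domain-shift magnitude; defaults to the config's value.
#' @return a `pretrain_corpus`: list with `modality`, `features`
#'   (n x dim matrix), `affect_labels` (integer classes) and `shift`.
#' @export
simulate_pretrain_corpus <- function(cfg, modality, n_samples = 2000L,
                                     n_classes = 3L, delta = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!modality %in% names(cfg$dims)) stopf("unknown modality '%s'", modality)
  if (is.null(delta)) delta <- cfg$pretrain_shift[[modality]] %||% 0
  if (n_classes < 2) stopf("pretraining corpus needs >= 2 affect classes")
  st <- modality_structure(cfg, modality)
  rho <- delta / (1 + delta)
  loading <- (1 - rho) * st$loading + rho * st$nuisance
  loading <- loading / sqrt(sum(loading^2))
  set.seed(child_seed(cfg$seed, 301L + match(modality, MODALITIES)))
  dim_m <- cfg$dims[[modality]]
  eff <- cfg$effect_size[[modality]] %||% 0
  classes <- sample(rep_len(seq_len(n_classes), n_samples))
  level <- cfg$mu * (classes - (n_classes + 1) / 2)
  level <- level + stats::rnorm(n_samples, sd = cfg$subject_sd)
  noise_sd <- cfg$noise_sd * sqrt(1 + delta)
  X <- outer(level * eff, loading) +
    matrix(stats::rnorm(n_samples * dim_m, sd = noise_sd), n_samples, dim_m)
  X <- sweep(X, 2L, delta * cfg$noise_sd * st$shift_dir, "+")
  structure(list(modality = modality, features = X,
                 affect_labels = as.integer(classes), shift = delta),
            class = "pretrain_corpus")
}

#' Subject-independent stratified folds
#'
#' Partitions subjects into `k` folds, stratified by label so that every
#' fold contains at least one positive and one negative subject; no subject
#' appears in more than one fold. Singleton folds are rejected.
#'
#' @param sessions sessions tibble (needs `subject_id` and `label`).
#' @param k number of folds (>= 2).
#' @param seed shuffling seed.
#' @return tibble `subject_id`, `label`, `fold` with attribute `k`.
#' @export
make_subject_folds <- function(sessions, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stopf("k must be >= 2")
  n_pos <- sum(sessions$label == 1)
  n_neg <- sum(sessions$label == 0)
  if (n_pos < k) stopf("fewer positive subjects (%d) than folds (%d)", n_pos, k)
  if (n_neg < k) stopf("fewer negative subjects (%d) than folds (%d)", n_neg, k)
  set.seed(child_seed(seed, 401L))
  fold <- integer(nrow(sessions))
  for (lab in c(1L, 0L)) {
    idx <- sample(which(sessions$label == lab))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  out <- tibble::tibble(subject_id = sessions$subject_id,
                        label = sessions$label, fold = fold)
  attr(out, "k") <- k
  out
}
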