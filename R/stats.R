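# Statistical analysis layer: Kruskal-Wallis with eta-squared effect sizes,
# Mann-Whitney transfer deltas, paired-t gate dominance, and the grouped
# report over grid results.

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Rank-based H (tie-corrected, via [stats::kruskal.test()]) across the
#' groups of `group`, with effect size `eta2 = H / (n_cell - 1)` where
#' `n_cell` is the per-group sample size — the convention used by the
#' analysis this package reproduces. Set `eta2_n = "total"` for the
#' conventional `H / (N_total - 1)`.
#'
#' @param data data frame of observations.
#' @param value column with the metric (tidy-eval).
#' @param group column with the grouping factor (tidy-eval).
#' @param n_cell per-cell sample size for the effect size; defaults to the
#'   common group size (groups must then be balanced).
#' @param eta2_n `"cell"` (default) or `"total"`.
#' @return one-row tibble: `H`, `df`, `p`, `eta2`, `n_cell`.
#' @export
kruskal_wallis_eta2 <- function(data, value, group, n_cell = NULL,
                                eta2_n = c("cell", "total")) {
  eta2_n <- match.arg(eta2_n)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- as.factor(as.character(g[keep]))
  sizes <- table(g)
  if (length(sizes) < 2) stopf("kruskal_wallis_eta2 needs >= 2 groups")
  if (any(sizes < 2)) stopf("every group needs >= 2 values")
  kt <- stats::kruskal.test(v, g)
  H <- unname(kt$statistic)
  denom_n <- if (eta2_n == "total") length(v)
             else if (!is.null(n_cell)) n_cell
             else if (length(unique(sizes)) == 1L) unname(sizes[1])
             else stopf("groups are unbalanced; supply n_cell explicitly")
  tibble::tibble(H = H, df = unname(kt$parameter), p = kt$p.value,
                 eta2 = H / (denom_n - 1), n_cell = as.integer(denom_n))
}

#' Mann-Whitney U test with mean difference
#'
#' Two-sided rank-sum test between samples `a` and `b`. `U` counts pairs
#' with `a > b` (plus half-ties), `delta = mean(a) - mean(b)`, and `effect`
#' labels the direction at alpha = 0.05 (`"Positive"`, `"Negative"`,
#' `"n.s."`).
#'
#' @param a,b numeric samples (nonempty).
#' @return one-row tibble: `U`, `p`, `delta`, `effect`.
#' @export
mann_whitney_delta <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stopf("both samples must be nonempty")
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  if (is.na(p)) p <- 1
  delta <- mean(a) - mean(b)
  effect <- if (p >= 0.05) "n.s." else if (delta > 0) "Positive" else "Negative"
  tibble::tibble(U = U, p = p, delta = delta, effect = effect)
}

#' Gate dominance analysis
#'
#' Per-subject mean gate difference between the semantic and pose streams at
#' the intra-visual gated stage, `delta_i = mean(g_i) - mean(1 - g_i)`
#' (averaged over utterances and gate dimensions), followed by a paired
#' t-test across subjects and a verbal dominance class:
#' `strong_semantic` (delta > 0.5, p < 0.05), `moderate_semantic`
#' (0 < delta <= 0.5, p < 0.05), `reversal` (delta < 0, p < 0.05), else
#' `balanced`. A zero-variance (saturated) gate is reported with `t = Inf`
#' and the p-value floored at 1e-300.
#'
#' @param gate_means numeric vector: per-subject mean gate weight on the
#'   semantic stream (in (0,1)), one value per subject.
#' @return one-row tibble: `delta`, `t`, `p`, `class`, `n`, `saturated`.
#' @export
gate_dominance <- function(gate_means) {
  if (length(gate_means) < 2) stopf("gate dominance needs >= 2 subjects")
  d_i <- 2 * gate_means - 1  # g_siglip - g_pose for a convex gate
  delta <- mean(d_i)
  sd_d <- stats::sd(d_i)
  saturated <- sd_d == 0
  if (saturated) {
    tval <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 1e-300
  } else {
    tt <- stats::t.test(d_i)
    tval <- unname(tt$statistic)
    p <- tt$p.value
  }
  cls <- if (p >= 0.05) "balanced"
         else if (delta > 0.5) "strong_semantic"
         else if (delta > 0) "moderate_semantic"
         else "reversal"
  tibble::tibble(delta = delta, t = tval, p = p, class = cls,
                 n = length(gate_means), saturated = saturated)
}

#' Statistical report over grid results
#'
#' Reproduces the analysis tables from a long results table (one row per
#' condition x fold, as produced by [run_grid()]): per-position
#' Kruskal-Wallis comparisons of the four fusion strategies on AUC and
#' PR-AUC (with `eta2 = H / (n_cell - 1)`, `n_cell` = conditions per
#' strategy cell), Mann-Whitney pretraining transfer deltas per modality,
#' and gate dominance per condition (where the intra-visual stage is gated).
#'
#' @param results long results tibble from [run_grid()] /
#'   [aggregate_results()].
#' @param alpha significance level used for effect labels.
#' @return a `stat_report`: list of tibbles `fusion_auc`, `fusion_pr_auc`,
#'   `pretraining`, `gates`.
#' @export
analyze_results <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  cond <- results |>
    dplyr::group_by(.data$condition_id, .data$vis_fusion, .data$audio_fusion,
                    .data$text_fusion, .data$pt_visual, .data$pt_audio,
                    .data$pt_text) |>
    dplyr::summarise(auc = mean(.data$auc), pr_auc = mean(.data$pr_auc),
                     gate_delta = mean(.data$gate_delta), .groups = "drop")
  positions <- c(vis_fusion = "vis_fusion", audio_fusion = "audio_fusion",
                 text_fusion = "text_fusion")
  fusion_table <- function(metric) {
    purrr::map_dfr(positions, function(pos) {
      g <- cond[[pos]]
      v <- cond[[metric]]
      n_cell <- max(table(g))
      kw <- if (length(unique(g)) >= 2 && all(table(g) >= 2)) {
        kruskal_wallis_eta2(tibble::tibble(v = v, g = g), v, g, n_cell = n_cell)
      } else {
        # restricted grids can leave a position without a contrast
        tibble::tibble(H = NA_real_, p = NA_real_, eta2 = NA_real_,
                       n_cell = as.integer(n_cell))
      }
      means <- tibble::tibble(g = g, v = v) |>
        dplyr::group_by(.data$g) |>
        dplyr::summarise(mean = mean(.data$v), sd = stats::sd(.data$v),
                         .groups = "drop")
      tibble::tibble(position = pos, strategy = means$g, mean = means$mean,
                     sd = means$sd, H = kw$H, p = kw$p, eta2 = kw$eta2,
                     n_cell = kw$n_cell)
    })
  }
  pt_cols <- c(visual = "pt_visual", audio = "pt_audio", text = "pt_text")
  pretraining <- purrr::map_dfr(names(pt_cols), function(m) {
    flag <- cond[[pt_cols[[m]]]]
    mw <- if (any(flag) && any(!flag)) {
      mann_whitney_delta(cond$auc[flag], cond$auc[!flag])
    } else {
      tibble::tibble(U = NA_real_, p = NA_real_, delta = NA_real_,
                     effect = NA_character_)
    }
    tibble::tibble(modality = m,
                   mean_pt = mean(cond$auc[flag]), sd_pt = stats::sd(cond$auc[flag]),
                   mean_sc = mean(cond$auc[!flag]), sd_sc = stats::sd(cond$auc[!flag]),
                   delta = mw$delta, U = mw$U, p = mw$p, effect = mw$effect)
  })
  gates <- results |>
    dplyr::filter(.data$vis_fusion == "gated", !is.na(.data$gate_delta)) |>
    dplyr::group_by(.data$condition_id, .data$pt_visual, .data$pt_audio,
                    .data$pt_text, .data$audio_fusion, .data$text_fusion) |>
    dplyr::summarise(delta = mean(.data$gate_delta), .groups = "drop")
  structure(list(fusion_auc = fusion_table("auc"),
                 fusion_pr_auc = fusion_table("pr_auc"),
                 pretraining = pretraining, gates = gates,
                 alpha = alpha, n_conditions = nrow(cond)),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %d conditions\n", x$n_conditions))
  cat("Fusion effects (AUC):\n")
  print(x$fusion_auc, n = 12)
  cat("Pretraining transfer:\n")
  print(x$pretraining)
  invisible(x)
}

#' Write a statistical report to JSON (plus CSV table renderings)
#'
#' @param report a `stat_report` from [analyze_results()].
#' @param path output JSON path; sibling CSVs (`*_fusion_auc.csv`, ...) are
#'   written next to it.
#' @param csv also write the CSV renderings.
#' @return `path`, invisibly.
#' @export
write_stat_report <- function(report, path, csv = TRUE) {
  stopifnot(inherits(report, "stat_report"))
  jsonlite::write_json(
    list(n_conditions = report$n_conditions, alpha = report$alpha,
         fusion_auc = report$fusion_auc, fusion_pr_auc = report$fusion_pr_auc,
         pretraining = report$pretraining, gates = report$gates),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (csv) {
    stem <- sub("\\.json$", "", path)
    readr::write_csv(report$fusion_auc, paste0(stem, "_fusion_auc.csv"))
    readr::write_csv(report$fusion_pr_auc, paste0(stem, "_fusion_pr_auc.csv"))
    readr::write_csv(report$pretraining, paste0(stem, "_pretraining.csv"))
    readr::write_csv(report$gates, paste0(stem, "_gates.csv"))
  }
  invisible(path)
}
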