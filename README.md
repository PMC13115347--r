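# multifuse

Controlled analysis of **interaction-driven dynamic multimodal fusion**
under class imbalance, for researchers studying automated depression
screening (or any session-level binary screening task) from utterance-level
behavioural features: visual-semantic embeddings, head-pose angles,
acoustic functionals and text embeddings.

The package answers two coupled design questions with a fully controlled
experiment rather than a single architecture benchmark:

1. **Which fusion operator, at which integration position?** Four
   strategies — concatenation, summation, sigmoid-gated mixing,
   cross-attention — are crossed over three positions (intra-visual,
   +acoustic, +text), giving 4³ = 64 architectures.
2. **Does affective pretraining of the projection heads transfer?** Each of
   the three pretrainable heads (visual-semantic, acoustic, text) is
   independently initialised from an auxiliary affect-classification
   checkpoint or from scratch: 2³ = 8 states, for 512 conditions in total.

## The model

Each session is a set of `T × dim` utterance-feature blocks. Per-modality
MLP heads project into a shared latent space of width `d` (default 256).
The staged fusion combines the primary stream `h_a` with the incoming
modality `h_b`:

- concat: `h = W[h_a; h_b] + b` (adds 2d² weights)
- sum: `h = h_a + h_b` (adds nothing)
- gated: `g = σ(W_g[h_a; h_b] + b_g)`, `h = g ⊙ h_a + (1−g) ⊙ h_b`
  (adds 2d² + d; the gate `g` is the interpretability signal)
- cross-attention: `A = softmax(QK'/√d)` with queries from `h_a`, keys from
  `h_b`; `h = W_o[h_a; A·h_b]` (adds exactly 4d²)

Attention-based temporal pooling (`α_t = softmax(w'h_t)`,
`h = Σ α_t h_t`) aggregates utterances into a session vector; a logistic
head scores it. Training uses class-weighted BCE with
`w_pos = n_neg/n_pos` recomputed per training fold (≈ 4.69 at the reference
13/74 prevalence), AdamW (lr 1e-3, weight decay 1e-4), gradient clipping at
norm 1.0 and early stopping on validation AUC. The whole network — including
backprop through BatchNorm/LayerNorm/GELU, the gate, cross-attention and
the pooling — is implemented in base R matrix operations and verified by
finite-difference gradient checks.

Evaluation reports AUC **and** PR-AUC (average precision; random baseline =
prevalence ≈ 0.176), plus F1/balanced accuracy/sensitivity/specificity at
threshold 0.5. The statistics layer mirrors the source analysis:
Kruskal–Wallis per fusion position with `η² = H/(N−1)` at per-cell N,
Mann–Whitney pretraining deltas `Δ = μ_PT − μ_SC`, and paired-t gate
dominance `Δ = ḡ_semantic − ḡ_pose` with verbal dominance classes.

Because the motivating clinical corpus is private, a synthetic-data module
(`simulate_sessions()`, `simulate_pretrain_corpus()`) emulates its
structure: a latent-factor model with one shared affect factor, subject
random effects, 74 subjects / 13 positive by default, and a domain-shift
knob `δ` for the pretraining corpora that reproduces positive, null and
negative transfer regimes.

## Worked example

Cross-validate one condition (gated intra-visual fusion, cross-attention at
the acoustic stage, concatenation at the text stage, no pretraining) on a
synthetic desk-scale corpus with the reference 13/74 class structure:

```r
library(multifuse)
library(dplyr)

cfg <- synth_config(
  dims = list(visual_semantic = 48, pose = 3, audio = 24, text = 48),
  utterances_range = c(10, 20), seed = 42)
sessions <- simulate_sessions(cfg)
folds <- make_subject_folds(sessions, k = 3, seed = 42)

cond <- enumerate_conditions() |>
  filter(vis_fusion == "gated", audio_fusion == "attention",
         text_fusion == "concat", !pt_visual, !pt_audio, !pt_text)

res <- run_condition(cond, sessions, folds,
                     train_spec(max_epochs = 20, patience = 6, seed = 42),
                     d = 16)
select(res, fold, auc, pr_auc, f1, balanced_accuracy, gate_delta)
#> # A tibble: 3 × 6
#>    fold   auc pr_auc    f1 balanced_accuracy gate_delta
#>   <int> <dbl>  <dbl> <dbl>             <dbl>      <dbl>
#> 1     1 0.810  0.521 0.5               0.676   0.00536
#> 2     2 0.775  0.619 0.375             0.65    0.000413
#> 3     3 0.4    0.170 0                 0.5    -0.00230
```

Mean AUC 0.662 and mean PR-AUC 0.437 against the 0.176 prevalence baseline:
the model finds the planted signal in two folds and misses in the third —
honest behaviour for 74 subjects with 13 positives under
subject-independent splits. `gate_delta` is the per-fold mean difference
between the semantic and pose gate weights at the intra-visual stage
(positive = semantic dominance); `analyze_results()` aggregates these into
the fusion/pretraining/gate report tables and `plot_gate_distribution()` /
`autoplot()` draw them.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full desk-scale analysis from scratch: it simulates the
74/13 corpus at reduced feature widths, pretrains the three projection
heads on their synthetic affective corpora, runs a stratified 24-condition
subset of the 512-condition grid under subject-independent 3-fold CV, and
writes the statistical report (fusion-position tables, transfer deltas,
gate dominance) to `<out dir>/acceptance_run/`, with the JSON object named
by `--out` written last. Runtime is a few minutes on one CPU.
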