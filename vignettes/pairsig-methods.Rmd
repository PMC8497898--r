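---
title: "Rank-pair prognostic signatures: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-pair prognostic signatures: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
library(dplyr)
```

## The problem and the model

Prognostic gene signatures built on absolute expression levels inherit
every normalization artifact of the platform they were trained on. The
rank-pair alternative implemented here replaces each predictor with a
within-sample comparison: for an ordered gene pair (A, B) and a patient
s, the indicator G equals 1 when expression of A strictly exceeds that
of B in that patient, and 0 otherwise (ties score 0). Because G depends
only on the within-sample ranking, the resulting risk score

\[ \mathrm{RiskScore}(s) = \sum_i \beta_i \, G_i(s) \]

is invariant to any monotone per-sample rescaling and can be evaluated
on a new cohort without cross-platform normalization.

The full construction chain, applied to an FPKM-style tumor/normal
expression pair plus a curated immune-gene list, is:

1. **Immune-related lncRNAs** — a lncRNA is immune-related when at
   least one immune gene satisfies |Pearson R| > 0.5 with p < 0.001
   (t transform, n − 2 df). Correlations are computed on log2(x + 1) by
   default because FPKM is heavy-tailed and a few extreme values can
   dominate the raw-scale product moment; `log2_transform = FALSE`
   restores the raw scale.
2. **Differential expression** — mean difference of log2(x + 1) between
   tumor and normal (the pseudo-count handles FPKM zeros), Welch t
   p-values, Benjamini–Hochberg FDR, retained when |log2FC| > 2 and
   FDR < 0.05, all thresholds strict. A moderated (empirical-Bayes)
   statistic is deliberately not used: the pipeline's contribution is
   the pair encoding and selection chain, and the plain Welch test
   keeps the operation self-contained and exactly testable against a
   by-hand oracle.
3. **Pair encoding** — all k(k−1)/2 unordered pairs in canonical
   lexicographic orientation; a pair is usable only when its indicator
   prevalence lies strictly inside (0.2, 0.8). Constant or near-constant
   pairs carry no rank information; the symmetric band also makes the
   retained unordered set independent of orientation (up to ties, which
   score 0 by the literal "otherwise" rule).
4. **Selection** — univariate Cox (Wald p < 0.05) → iterated
   cross-validated LASSO-Cox (default 1000 repetitions; a pair counts
   once per repetition in which its coefficient at `lambda.min` is
   nonzero; pairs recorded strictly more than 100 times survive; the
   100/1000 = 10% proportion should be held when fewer repetitions are
   used) → bidirectional stepwise Cox minimizing AIC → among the
   stepwise path's nested models, the one maximizing the 5-year
   time-dependent AUC on the training cohort.
5. **Dichotomization** — the risk-score cut-off minimizing the AIC of a
   single-indicator Cox fit over all admissible splits; high/low groups
   are then compared by Kaplan–Meier/log-rank, chi-square against
   clinical categoricals, Spearman correlation against immune-cell
   fractions, and rank-sum tests against drug IC50 tables.

## Interpretive choices

Several steps of the published recipe are under-specified; the package
resolves them as follows and exposes each resolution as a documented
option rather than a hidden constant.

**"AIC of each point on the ROC curve".** There is no standard AIC
attached to a ROC point. The implemented reading: each candidate
cut-off (midpoints between consecutive distinct scores, with at least
10% of patients on each side to keep the Cox fit well-posed)
dichotomizes the cohort, a one-covariate Cox model is fitted on the
indicator, and its AIC is recorded; the minimizer is the cut-off. This
is well-defined, depends only on score ranks, and reduces to "the best
prognostic split of the score". The Youden point (max TP − FP at the
horizon) is available via `aic_cutoff(..., method = "youden")`.

**"Random stimulation" inside the repeated LASSO.** The per-repetition
randomness is the cross-validation fold assignment, re-drawn from a
seed derived from `base_seed`, so the whole frequency table is
reproducible. Bootstrap resampling of patients is available as
`bootstrap = TRUE` for users who read the recipe as a resampling
procedure.

**Stepwise direction.** Bidirectional search starting from the full
model of frequency-selected pairs, mirroring a reduction of a LASSO
superset (40 → 14 in the motivating analysis). Ties are broken by
candidate order; AIC counts every listed covariate, so an exactly
collinear duplicate is always pruned.

**Signed-rank vs rank-sum.** The group comparisons (risk score across
clinical subgroups, IC50 between risk groups) are unpaired, so the
Mann–Whitney rank-sum test is used even where the source recipe names
the signed-rank test, which requires paired data.

**Tie handling in Cox fits** is Breslow throughout; with 0/1 pair
indicators ties in covariates are ubiquitous but event-time ties are
what matters, and Breslow is the simplest consistent choice.

**Horizons** are converted at 365.25 days per year; survival input is
expected in days (TCGA convention).

## The synthetic-data generator

`simulate_dataset()` produces the cohorts that every end-to-end test
runs on. Log2 expression is a latent-factor Gaussian model,
`mu_g + a_g f_j(s) + shift + noise`, exponentiated to a strictly
positive FPKM-like scale. Its defaults mirror the motivating cohort
shape: 259 tumor and 78 normal samples. The pieces map one-to-one onto
the assumptions the pipeline makes:

* **Immune linkage.** Immune genes and a configurable fraction of
  lncRNAs load on shared latent factors. Loadings are solved from the
  target population correlation (`target_r`, default 0.8) via
  r = a²/(a² + σ²), so the correlation screen has a known ground truth.
* **Differential expression.** A configurable number of lncRNAs gets a
  tumor-only log2 shift (default magnitude 4, comfortably clearing the
  |log2FC| > 2 threshold at the default noise σ = 1).
* **Planted pairs.** The two genes of a planted pair share one
  baseline, one factor loading and one shift direction, so their
  within-sample order is a fair coin per patient: the pair passes the
  prevalence filter by construction and its indicator carries only the
  planted hazard. Planted coefficients are reported in the canonical
  orientation (beta flips sign if lexicographic order swaps the genes).
* **Survival.** Exponential event times with hazard
  h₀·exp(Σ βₖ Gₖ), default baseline 1/1500 events per day (median
  ~2.8 years, a plausible sarcoma scale), and independent uniform
  censoring on [0, T_max] with T_max solved by bisection so the
  realized censoring fraction matches `censor_rate`. Uniform
  independent censoring matches the Cox model's assumption; it does not
  emulate administrative or dropout patterns.

What the generator does **not** emulate: batch effects between the
tumor and normal sources (the motivating data merge two projects with
no published harmonization), isoform structure, count-level noise,
expression-linked clinical covariates, or subtype heterogeneity
(histology labels are attached as unlinked categories so association
tests have inputs). Green end-to-end tests therefore demonstrate that
the chain recovers the structure it assumes, not that it is robust to
the full messiness of merged public cohorts.

## Numerical choices

* Cox fits run Newton iterations to a 1e−9 gradient tolerance (cap
  100); non-convergence is flagged, never silent.
* The shared lambda grid for the repeated LASSO is computed once from
  the full data (60 points), keeping repetitions comparable and warm
  starts effective.
* `td_roc` sweeps thresholds over the distinct marker values plus the
  all-in endpoint; the subgroup Kaplan–Meier estimate is computed
  directly by the product-limit formula. Under heavy censoring the
  KM-based cumulative/dynamic estimator can be locally non-monotone;
  no smoothing is applied, matching the plain estimator's behavior.
* Exact AUC ties in model selection go to the smaller model;
  `aic_cutoff` ties go to the smallest cut-off; stepwise AIC ties go to
  the earlier candidate.
* Degenerate inputs error early and specifically: no events, constant
  scores, empty groups, pairs missing from an indicator table.

## Worked example

Problem sizes here are kept small so the vignette builds quickly; the
same chain at its defaults (1000 LASSO repetitions) is what an analysis
of a real cohort would run.

```{r example, eval = FALSE}
cfg <- sim_config(
  n_tumor = 450, n_normal = 78, n_lnc = 54, n_immune = 20, n_de = 12,
  planted_pairs = data.frame(lncA = c(1, 3), lncB = c(2, 4),
                             beta = c(1, -1)),
  censor_rate = 0.3, seed = 11)
sim <- simulate_dataset(cfg)

cohorts <- split_cohort(sim$clinical$sample_id, ratio = 2 / 3, seed = 11)
lnc <- dplyr::filter(sim$expression, grepl("^lnc", gene_id))
pairs <- build_pairs(lnc, cohorts$training) |> filter_pairs()

clin_tr <- dplyr::filter(sim$clinical, sample_id %in% cohorts$training)
fit <- train_risk_signature(pairs, clin_tr, n_iter = 100, freq_min = 10,
                            seed = 5)
tidy(fit)        # selected pairs with coefficients
glance(fit)      # AUC, cut-off, group sizes

clin_va <- dplyr::filter(sim$clinical, sample_id %in% cohorts$validation)
ev <- evaluate_risk_signature(fit, build_pairs(lnc, sim$clinical$sample_id),
                              clin_va)
ev$auc           # 1/3/5-year validation AUC
ev$logrank$p     # high vs low survival difference
```

On this configuration the training run recovers both planted pairs
with sign-correct coefficients close to (+1, −1); the acceptance script
(`scripts/acceptance.R`) reruns exactly this computation and records
the numbers it produces.

## Known limitations

* The univariate screen uses unadjusted Wald p-values (threshold 0.05);
  with tens of thousands of candidate pairs on a real cohort this
  admits many false positives by design — the LASSO frequency stage is
  the intended filter, as in the source recipe.
* Training-cohort AUC maximization over the stepwise path favors
  larger models; with modest cohorts this is an overfitting risk that
  the validation cohort, not the training AUC, must arbitrate.
* The cumulative/dynamic AUC is estimated without confidence bands;
  comparisons between models at a single horizon inherit its sampling
  noise.
* Pairs sharing a gene are strongly dependent; the LASSO and stepwise
  stages may substitute a proxy pair (one planted gene paired with a
  correlated neighbor) for a planted pair when signals are weak.
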