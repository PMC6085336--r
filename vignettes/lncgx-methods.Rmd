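---
title: "lncgx: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncgx: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery:
what each stage computes, what it assumes, which knobs matter, and where
genuinely open design choices were settled.

## 1. The generative model behind the synthetic panels

All recovery claims in the test suite rest on the synthetic-data module,
so its generative model is worth stating precisely.

**Expression.** Cell-line lncRNA expression is `z`-scale by construction:
each feature is i.i.d. standard normal, plus a mean shift of `type_shift`
z-units on each cancer type's signature features (a random 10% subset per
type). Tumor cohorts reuse the *same* type-signature matrix, which is what
makes tumor/cell-line concordance and tissue-of-origin matching
recoverable. Note one consequence: with nonzero `type_shift` the marginal
mean of a signature feature is no longer exactly zero; the "approximately
standard normal" property holds for non-signature features, or panel-wide
when `type_shift = 0`, and is tested in that regime.

**Drug response.** For agent *j*, `lnIC50 = X βⱼ + lineage offset +
N(0, noise_sd)`, where βⱼ has exactly `k_true_per_agent` nonzero entries
of magnitude `effect_size` with random signs, and the lineage offset is a
per-(cancer type, agent) draw of sd `lineage_effect_sd`. Agents are
assigned to target pathways round-robin, and agents in one pathway share a
common core of `ceil(k/2)` predictive lncRNAs — so pathway structure is
recoverable from selection overlap, which the drug-similarity clustering
test exploits. AUC is a logistic transform of lnIC50 (centered at the
per-agent median, unit scale) plus `N(0, 0.01)` noise. Any monotone link
suffices for the rank-based stages; we use an increasing one, matching
the empirical positive association between the two readouts in real
screens.

**Survival.** Event times are exponential with hazard
`baseline_hazard × exp(log_hr_resistance × z)`, where `z` is the
standardized "true resistance score": the planted linear predictor
`X β` averaged over agents. Censoring is an independent exponential whose
rate is calibrated so that a `censoring_rate` fraction of patients is
censored under the null; with a nonzero planted effect the realized
censoring fraction drifts slightly, which is harmless for the recovery
tests. Stage (I–IV) and age (uniform integers 30–90, so the 65-year
dichotomization is exercised on both sides) are independent of hazard by
design — the multivariate Cox test checks exactly that their confidence
intervals cover 1.

**Multi-omics and gene sets.** Copy-number values and methylation betas
carry scaled copies of the same type signatures (betas through a logistic
squash, so they stay in [0, 1]). Each target pathway gets one planted
co-expressed gene set: 30 protein-coding genes generated as
`loading × partner lncRNA + sqrt(1 − loading²) × noise` with
`loading = 0.8` by default, plus random decoy sets. The defaults (set
size 30, loading 0.8) are typical of a strong co-expression module; a
loading of 0.8 puts members around the top decile of the partner's
correlation ranking without making the GSEA test trivial.

**What the generator does not emulate.** Read-level noise, batch effects,
copy-number breakpoint structure, dose–response curve fitting, correlated
survival covariates, and heavy-tailed expression. Passing recovery tests
therefore certify the *statistical machinery* — they do not promise
equally clean behavior on real panels, where effect sizes are smaller and
confounding is real.

## 2. Predictive scores

Hyperparameters are tuned once per agent on the full panel — exhaustive
search over 10 α values on [0.2, 1] × 200 λ values e^τ, τ ∈ [−5, 5], by
10-fold CV with a seeded fold assignment shared across α — and then
frozen across all 200 bootstrap refits. Re-tuning inside each replicate is
available in principle but is not the default: freezing matches the
procedure the score is defined by, and makes PS a pure function of the
resampling randomness. CV-MSE ties are broken toward larger λ, then larger
α, i.e. toward the sparser model.

Numerical choices worth knowing:

* "Nonzero coefficient" means `|β| > 1e-8`. Coordinate-descent solvers
  return exact zeros for inactive coefficients in theory, but a
  convergence-tolerance guard is safer; the bootstrap convergence
  threshold is tightened to `1e-10` so near-boundary coefficients are
  stable. Even so, PS is only *numerically* invariant to feature order up
  to roughly one replicate's worth (1/B) on features sitting exactly at
  the selection boundary; the tests assert exact invariance for planted
  features and 1/B-bounded invariance overall.
* Features are standardized once globally (the pipeline consumes z-scored
  matrices and fits with `standardize = FALSE`); resamples are not
  re-standardized. Re-standardizing per resample would subtly change what
  "the same λ" means across replicates.
* A bootstrap replicate with constant response cannot be fit; it is
  skipped, and the effective B becomes the PS denominator.
* Missing response values are dropped per agent before tuning.

The PS ≥ 0.25 pair cutoff is inclusive. `calibrate_cutoff()` reproduces
the specificity analysis that motivates it — the two-sample KS distance
between |Spearman ρ| of predictive vs non-predictive pairs measured on an
independent panel, scanned over cutoffs with the knee reported — but it is
advisory; the pipeline default stays 0.25 regardless of the curve.

## 3. LENP models

The top-k features (k = 20 by default) are taken by descending PS, with
rank-k ties broken by larger mean |bootstrap coefficient| and then feature
id, so selection is deterministic. The model is re-tuned and refit on all
training rows; the single full-data refit is what is serialized and
applied downstream, while the 10×10-fold CV report (Pearson r, Kendall τ
per iteration, at the frozen hyperparameters) quantifies its predictive
power. We deliberately keep one refit rather than an ensemble of CV
winners: it makes `predict` a plain affine map with stored normalization
(center/scale from training), serializable to versioned full-precision
JSON with exact round-trip.

Prediction refuses to run when model features are absent from the new
matrix — a silent zero-fill would quietly corrupt transferred predictions.
External validation reports Pearson r plus Spearman ρ with its p-value;
"validated" means Spearman p < 0.05, and agents with fewer than 10 shared
cell lines are skipped.

## 4. Concordance and tissue-of-origin matching

Fold-changes contrast one cancer type against a background resampled
without replacement from all other types, with background size equal to
the target group (the resampling equalizes the variance of the two means).
Types need more than 15 tumors and more than 20 cell lines to enter the
analysis. The tumor-type × cell-line-type matrix averages Pearson
correlations of fold-change vectors over 10 resampling iterations.

Rank-sum integration across genomic features ranks every cell within each
feature's matrix (descending correlation) and sums ranks; the score is
negated so higher remains better, and rank-sum ties are broken by mean
correlation added at `1e-4` scale — far below the minimum rank-sum gap of
0.5, so it can only ever reorder exact ties.

Matching is row-wise: each tumor type queries cell-line types by
descending score; ties at the k boundary break lexicographically. The
random expectation is estimated by 1000 row-wise permutations, and for
exchangeable rows it converges to the analytic k/T, which the tests
verify. The per-feature significance flag ("p-value within the lowest
decile of the matrix's pairwise p-values") is exposed only as a
diagnostic: it is a relative, not calibrated, criterion.

## 5. Patient stratification and survival

* **Sensitivity labeling** uses the nearest-rank 25th percentile of
  predicted response per agent (lowest predicted IC50 quartile =
  sensitive), ties all included; being rank-based it is invariant to any
  monotone transform of the predictions.
* **Consensus rank** R′ is the weighted mean of per-drug ascending ranks
  (1.0 first-line, 0.5 second-line), computed within each cancer type.
  Categories use nearest-rank boundaries at 30 / 50 / 70%.
* **Stage filter**: stage-I patients are excluded except for cancer types
  without meaningful staging (acute myeloid leukemia by default);
  unknown stages are retained with a warning rather than dropped.
* **Multivariate Cox** codes the response category ordinally 0–3
  (resistance high) by default; the continuous R′ is available behind a
  switch. Stage is ordinal I–IV, age binary at 65 with age 65 itself
  classed "old". Whether the category, the raw R′, or a binary split is
  the "right" covariate is genuinely underdetermined; the ordinal coding
  is the default because it uses the declared categories without assuming
  linearity of R′ itself. Degenerate covariates are dropped with a notice.
* **Treated-patient KM** splits at the median predicted response; with
  odd n the median patient joins the resistant group (stated convention,
  tested). Eligibility requires 10 treated patients and 5 events.

Cox fits use the standardized predictor, so hazard ratios are per sd and
invariant to the predictor's scale.

## 6. Entropy-based MDR detection and GSEA

The pathway multiset of a predictive lncRNA keeps duplicates: two drugs
hitting the same pathway contribute two elements, so breadth is measured
against the number of *agents*, not pathways touched. Entropy is base-2
with 0·log 0 = 0; lncRNAs predicting a single agent get H = 0 and simply
dilute the z-score population, which is computed over all predictive
lncRNAs (minimum multiset size 1). The MDR rule is strict: z > 1.

GSEA is the classic weighted running-sum statistic (weight exponent 1 on
|score|). The null is gene-label permutation — the only option for a
correlation-ranked list, where there is no phenotype to permute — which
for a preranked list is equivalent to drawing random member positions;
consequently the null depends only on set size, and equal-size sets share
one null sample (a substantial speedup at no statistical cost). NES
divides ES by the mean |null ES| of matching sign; the nominal p uses the
(b + 1)/(n + 1) estimator so zero p-values cannot occur; FDR q follows the
standard pooled positive/negative NES procedure, and significance is
declared at FDR ≤ 0.25. Sets with fewer than 5 members in the ranked
universe are skipped. 1000 permutations is the default; the calibration
test (100 random sets on a random ranking) checks that nominal p is
uniform at that depth.

## 7. Problem sizes and determinism

The test-suite and acceptance-script problem sizes — 100 cell lines × 500
lncRNAs with 10 planted features per agent for selection recovery, 6 types
× 300 features for matching, 20 cohorts of 1000 patients for hazard
recovery, 100 random sets × 1000 permutations for GSEA calibration — were
chosen as the smallest panels at which the planted effects are
comfortably identifiable, so the checks measure correctness of the
machinery rather than luck. Every stochastic stage takes an explicit seed,
routed through isolated RNG streams (`withr`), and the command-line
stages are byte-identical across repeated runs with the same seed.

## 8. Known limitations

* Elastic-net selection inherits glmnet's convergence behavior; PS values
  of boundary features can move by ~1/B across algebraically equivalent
  inputs.
* The Haldane 0.5 correction makes odds ratios finite for degenerate
  tables but biases them toward 1; corrected values carry a flag.
* The specificity-curve knee (maximum discrete second difference) is a
  coarse estimator on a 0.05-step grid; it locates a transition, not a
  precise threshold.
* Exponential survival is the simplest proportional-hazards world; the
  Cox stages are exercised under correctly specified hazards only.
* The permutation GSEA FDR is the classic pooled procedure, which is
  conservative for small set collections.
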