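# lncgx — lncRNA pharmacogenomics in R

`lncgx` is a tested, reusable implementation of an lncRNA-centric
pharmacogenomic analysis pipeline. It is aimed at computational biologists
who want to ask, on a cell-line drug screen plus a tumor cohort:

* which long non-coding RNAs predict response to which drugs,
* how well a sparse expression-based model predicts ln(IC50) per agent,
* whether cell lines recapitulate tumor biology well enough to transfer
  those models to patients,
* whether predicted resistance stratifies patient survival, and
* which lncRNAs look like general multi-drug-resistance markers.

Because the original large screens (drug panels, tumor cohorts) cannot be
redistributed, the package ships a first-class synthetic-data generator
with planted ground truth — every statistical claim the pipeline makes is
exercised and verified on data whose answers are known by construction.

## The core statistic

For each agent, drug response across *N* cell lines is modeled from the
lncRNA expression matrix *X* (samples × p features, log-transformed and
z-scored) by elastic-net regression:

```
min_{β0, β}  (1/2N) Σᵢ (yᵢ − β0 − xᵢᵀβ)²  +  λ Pα(β),
Pα(β) = (1 − α)/2 ‖β‖²₂ + α ‖β‖₁
```

with α searched over 10 values on [0.2, 1] and λ over 200 values e^τ,
τ ∈ [−5, 5], by 10-fold cross-validation. With (α*, λ*) frozen, 200
bootstrap resamples of the cell lines are refit, and each lncRNA *u* gets
a **predictive score**

```
PS_u = (1/200) Σ_b I(β_ub ≠ 0)
```

— the fraction of resamples selecting it. Pairs with PS ≥ 0.25 form the
lncRNA–drug predictive-pair table. The top-20 lncRNAs per agent are refit
into a compact drug-response model (**LENP**) evaluated by 10×10-fold CV
(Pearson r, Kendall τ) and applied to tumors for sensitivity labeling
(lowest predicted-IC50 quartile), consensus-rank survival stratification
(weights 1.0 first-line / 0.5 second-line agents), Cox regression and
Kaplan–Meier analysis. LncRNAs whose predicted agents spread across many
target pathways are flagged as multi-drug-resistance related by the
Shannon entropy of their pathway multiset (z > 1), and co-expression
profiles against protein-coding genes feed a preranked GSEA
(gene-permutation null, FDR ≤ 0.25).

## Worked example

```r
library(lncgx)

cfg   <- sim_config(n_cell_lines = 100, n_lncRNAs = 300, n_agents = 4,
                    n_cancer_types = 4, k_true_per_agent = 10, seed = 1)
panel <- simulate_cell_line_panel(cfg)
X <- as.matrix(panel$expression)
y <- panel$response$ln_ic50[, "AGENT001"]

tuned <- tune_hyperparams(X, y, seed = 1)
bs    <- bootstrap_ps(X, y, tuned$alpha, tuned$lam, B = 200, seed = 2)
pairs <- define_pairs(bs, X, y, agent_id = "AGENT001")

model <- build_lenp(X, y, bs, agent_id = "AGENT001", seed = 3)
cv    <- evaluate_cv(X[, model$features], y, model$alpha, model$lam, seed = 4)

cohort <- simulate_tumor_cohort(cfg, panel$truth)
pred   <- predict(model, cohort$expression)
cox    <- univariate_cox(pred, cohort$clinical)
```

Output on this run:

```
tuned alpha = 1.00, lambda = 0.0320 (CV MSE 0.386)
51 lncRNA-drug predictive pairs at PS >= 0.25
planted lncRNAs among top-10 PS: 10 / 10
10x10-fold CV: Pearson r = 0.986 +/- 0.001, Kendall tau = 0.902
univariate Cox on predicted response: HR = 1.23 [1.07, 1.42], p = 0.0047
```

Reading: the tuner picked a lasso-like model (α = 1); 51 lncRNA–drug
pairs clear the PS ≥ 0.25 cutoff for this agent and all ten planted
predictive lncRNAs rank in the top ten by PS; the refit top-20 model
explains held-out response almost perfectly at this noise level; and
applying it to the simulated tumor cohort yields a predicted-resistance
score whose hazard ratio is significantly above 1, i.e. predicted-resistant
patients die faster — as planted.

A file-based interface to the main stages is available as a thin script:

```sh
Rscript inst/cli/lncgx.R simulate --config sim.yaml --out data/ --seed 1
Rscript inst/cli/lncgx.R select --expr data/cell_expression.tsv \
    --response data/ln_ic50.tsv --out sel/ --seed 1
```

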