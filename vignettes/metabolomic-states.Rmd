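---
title: "Multitask metabolomic states: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask metabolomic states: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A single blood draw profiled by NMR spectroscopy quantifies on the order of
168 circulating metabolic markers — amino acids, fatty acids, glycolysis
metabolites, ketone bodies and a dense grid of lipoprotein subclass measures.
`metstate` implements an analysis pipeline that asks how much multidisease
risk information such a profile carries: it learns, per disease endpoint, a
single scalar *metabolomic state* that behaves like a relative log-hazard,
integrates that state into Cox proportional-hazards (CPH) models alongside
standardized clinical predictor sets, and quantifies what the state adds in
discrimination, calibration and decision-curve utility.

Real cohorts of this kind are access-restricted, so the package is exercised
end to end on synthetic cohorts whose generating process mirrors the
statistical structure the analysis assumes — and, crucially, retains the
ground truth, so every stage can be tested as a recovery problem with a known
answer.

## The state model

The state model is a multitask residual feed-forward network mapping the
marker panel $x \in \mathbb{R}^{168}$ (z-scored with training-fold statistics)
to one scalar state per endpoint:

* a shared trunk of three fully connected layers (256, 256, 512 nodes), each
  with batch normalization, SiLU activation and dropout 0.3;
* per endpoint, a residual head with two inputs: an MLP (256, 128, 32 nodes,
  dropout 0.6) on the 512-dimensional shared representation, and a skip
  network (128, 128, 32 nodes) on the raw markers; the two 32-dimensional
  outputs are added, passed through a 128/128 post-merge network, and reduced
  by a final single-output linear layer with identity activation.

Within each layer block the order is linear → batch norm → SiLU → dropout.
The heads are stored *feature-fused*: per-endpoint layers are represented as
block-diagonal dense maps over endpoint-concatenated features. This is an
implementation detail — no parameter is shared across endpoints beyond the
trunk, and batch normalization over concatenated features is exactly
per-endpoint batch normalization — but it lets the elementwise work run over
all endpoints at once, which matters for CPU training.

### Loss

Each endpoint contributes an adapted proportional-hazards loss: the negative
log partial likelihood of the endpoint's eligible in-batch rows (Breslow tie
handling, risk sets formed within the batch), averaged over the eligible
in-batch events. Rows that are prevalent for that endpoint, of the wrong sex
for a sex-restricted endpoint, or excluded by medication rules enter neither
as events nor as risk-set members, via a per-endpoint eligibility mask, so a
single forward pass serves all endpoints. The multitask loss is the **sum**
over endpoints of these per-endpoint **averages** — averaging first makes an
endpoint's contribution independent of how many of its events happen to fall
in a batch; summing then weights endpoints equally.

Two properties anchor the loss: on a full dataset it equals the classical
negative log partial likelihood (so minibatch training is a restriction of
the classical objective, verified against an independent brute-force oracle
to 1e-10), and a degenerate configuration with no hidden layers trained to
convergence recovers classical CPH coefficients (verified within 0.05 per
standardized coefficient).

### Training

Adam (default parameters), batch size 1024, learning rate $10^{-3}$ with
multistep decay (factor 0.1 at epochs 20, 30, 40), at most 100 epochs, early
stopping on the validation multitask loss, and stochastic weight averaging:
weights from the first learning-rate step onward are averaged, the averaged
model's batch-norm statistics are refreshed with one full pass over the
training markers, and the averaged model is kept when it validates better
than the best single checkpoint (checkpoint selection on the validation
set either way). Batch-local risk sets are standard for stochastic Cox
training; batch size 1024 keeps them dense. Where the protocol leaves details
open we chose: early-stopping patience 10 epochs; Breslow tie handling (ties
are measure-zero in the synthetic data); identical eligibility masking in the
training and validation losses.

At desk scale the package uses a reduced profile of the same architecture
(`desk_state_model_config()`: trunk 64/64, head MLP 32/16, skip 24/16,
post-merge 32, dropout 0.3 everywhere, batch 512, at most 30 epochs with
steps at 15 and 22). The width/epoch reduction is sized to the synthetic
cohorts (tens of thousands of rows, hundreds of events per endpoint), where
the full architecture would be heavily over-parameterized.

### Export

Trained models are exported as a self-describing JSON bundle holding the
graph description, all weights and batch-norm running statistics, the
training-fold marker normalization, and the config. A reloaded bundle
reproduces states to numerical precision; loading data with the wrong marker
count raises a shape error.

## The synthetic cohort generator

`generate_cohort()` draws, per participant: a recruitment center (22 by
default), sex, mildly correlated clinical covariates (one latent factor with
loading 0.5 on the continuous columns, giving pairwise correlations near
0.25), and 168 markers from a block-correlated standard normal — 12 blocks of
12 markers at within-block correlation 0.5 emulating lipoprotein subclass
panels, plus 24 independent singletons for the small molecules. Center
membership shifts marker and clinical *means* (s.d. 0.1 per center) but never
the outcome model, so cross-validation folds differ in covariate distribution
while sharing the truth — the situation spatial validation is meant to probe.

Event times follow proportional hazards exactly, by inverse-transform
sampling with an exponential baseline: $T = -\log U / (h_0 e^{\eta})$, with
$\eta$ the endpoint's true log-hazard mixing clinical and marker terms
(optionally with quadratic/interaction terms). Censoring is the minimum of an
independent exponential (default 0.02/year) and administrative censoring at
the 10-year horizon plus up to half a year of uniform slack. When an
endpoint specifies a target 10-year cumulative rate the generator calibrates
$h_0$ by root finding on the analytic cumulative incidence.

The default endpoint set spans the spectrum seen across common diseases:
three strong-metabolomic endpoints (marker log-hazard s.d. ≈ 1.1–1.15 plus
modest clinical terms; total s.d. ≈ 1.22, chosen once so the *oracle*
concordance — the true log-hazard scored on held-out data — sits near 0.80
under the default censoring), three mixed endpoints, and two null endpoints
with zero marker signal, one restricted to women. Ten-year rates range from
2% to 8.7%. Missingness is injected MCAR (default 5%) into continuous
clinical columns only; a missing-at-random-on-age flag exists to exercise the
imputer; markers stay complete.

What the generator does **not** emulate: unit-faithful NMR concentrations,
assay noise and technical batch structure, non-proportional hazards,
competing risks, informative censoring, or real lipoprotein correlation
geometry (the assay's 81 derived percentage ratios are likewise out of
scope). Passing recovery tests therefore demonstrates that the
machinery is correct under its own assumptions — not that those assumptions
hold in any particular real cohort.

## Partitioning, preprocessing and leakage control

Cross-validation is spatial: one fold per center, the whole center as the
test set, a uniform random 10% (floor-rounded) of the pooled remaining
centers as validation, the rest as training. The draw is unstratified, as the
simplest reading of "randomly selecting 10%". An audit asserting pairwise
disjointness and exact test-set coverage runs on every plan construction and
every pipeline run.

Preprocessing is fitted strictly on training rows: chained-equation
imputation over the continuous columns with missingness (round-robin
conditional models — linear by default, random-forest optional — iterated to
relative change $<10^{-3}$ or 10 sweeps), then standardization, then one-hot
encoding with training-time level maps (reference level dropped; unseen
levels map to all zeros with a warning). Imputation runs on the raw scale
with standardization after — the alternative order is defensible but this one
keeps the imputation models interpretable in measurement units. A single
completed imputation is used per fold; the pipeline pools predictions, not
parameter estimates, so multiple imputations would only smooth the
predictions, and the single-imputation default keeps the pipeline simple.
The metabolomic state enters predictor matrices as a passthrough column
without re-standardization: it is already on a relative log-hazard scale.

## Cox integration and evaluation

Per endpoint, seven covariate sets are fitted: the state alone (MET), Age+Sex,
ASCVD (adds smoking, systolic blood pressure, total and HDL cholesterol,
diabetes and antihypertensive flags), PANEL (adds lifestyle, physical
measurements and laboratory values), and the three clinical sets each
combined with the state. `PANELnoLaboratory` exists additionally for
decision-curve comparisons. Fits use maximum partial likelihood with Breslow
ties through the survival package behind a deterministic retry ladder
(default control → raised iteration cap → small ridge) standing in for the
step-size-halving fallbacks of other implementations. Ten-year risks come
from the Breslow baseline cumulative hazard:
$\mathrm{risk} = 1 - S_0(10)^{\exp(\mathrm{lp})}$.

Evaluation pools the per-fold test predictions (a duplicate participant
across folds is treated as evidence of leakage and raises an error) and
computes: Harrell's C with percentile-bootstrap CIs (≥1000 iterations);
paired bootstrap C deltas, significant when the 95% CI excludes zero; event
rates over 100 equal-count state percentiles and the top-vs-bottom-decile
rate ratio (both the risk ratio and the odds ratio are emitted, explicitly
labeled, since the two diverge at high rates); calibration against
Kaplan–Meier observed risk in equal-count bins with Greenwood CIs; decision
curves — net benefit $TP/n - (FP/n)\,p_t/(1-p_t)$ and its
prevalence-standardized version, with treat-all/treat-none references — and
sensitivity/PPV/LR+ at target false-positive rates. Horizon classifications
exclude participants censored before the horizon without an event (the count
is reported); with zero censoring the results equal the naive binary
computation exactly. An inverse-probability-of-censoring weighting variant
was considered and left out of scope as the synthetic censoring is
independent by construction.

## Attributions

Per-sample marker attributions use expected gradients: integrated gradients
along straight paths from each background sample (default 256 training rows)
to the explained sample, midpoint rule with 32 steps, averaged over the
background. The contract is local additivity — attributions sum to the
prediction's deviation from the mean background prediction — which the
midpoint rule satisfies at $O(\text{steps}^{-2})$ for the smooth SiLU network
and exactly for linear models ($\phi_i = w_i(x_i - \bar b_i)$, the frozen
closed-form oracle in the tests). Global importance is the sum of absolute
attributions per marker; high-impact attributions are flagged outside the
empirical 1%/99% percentiles (the interval is data-derived; a fixed-interval
variant is available); percentile profiles aggregate attributions in 100
equal-count bins with the mean raw marker value carried along for coloring;
and the per-endpoint attribution space can be embedded in 2-D with UMAP
(fixed seed, single-threaded, hence deterministic).

## Pipeline, seeds and problem sizes

`run_pipeline()` chains simulate → partition → train → integrate → evaluate →
attribute, writing the partition plan, per-fold model bundles, pooled
predictions, a JSON evaluation report and a line-delimited JSON log. Every
stage and fold derives its seed from the master seed by a stable arithmetic
fan-out (`derive_seed()`), so two runs with the same configuration produce
byte-identical reports.

The shipped problem sizes are chosen for single-CPU reproducibility: the
smoke profile runs 2 folds of a 5000-participant, 4-endpoint cohort; the
recovery experiments train all 22 folds at 20,000 participants with the desk
architecture; bootstrap CIs use 1000 iterations. At these sizes the strong
endpoints carry roughly 500–900 training events per fold — enough for the
learned state to come within a few hundredths of the oracle concordance, with
the residual gap dominated by estimation noise in 168 dimensions rather than
by optimization.

## Known limitations

* The generator's signal is linear (plus optional low-order terms), so these
  tests cannot show an advantage of the network over a linear state — they
  show faithful recovery, not superiority.
* Single-CPU training at full architecture scale (24 endpoints, 100 epochs,
  trunk width 512) is supported but slow; the desk profile is the intended
  default for experimentation.
* The null-endpoint concordance band is checked on state predictions pooled
  across all folds; per-center estimates at desk scale carry binomial noise
  wider than any meaningful band.
* Decision-curve thresholds default to a 0.01–0.5 grid in steps of 0.005 and
  are configurable; no claim is made about clinically adequate thresholds for
  any real disease.
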