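---
title: "Immune-cell composition and epigenetic age acceleration: models and methods"
author: "immunoEAA"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Immune-cell composition and epigenetic age acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoEAA)
```

# The problem

DNA methylation clocks are linear predictors over CpG beta values that
estimate an age-like quantity — chronological age, an aging pace, or
cumulative stem-cell divisions. Epigenetic age acceleration (EAA), the
residual of methylation age on chronological age, is widely used as a
biomarker of health outcomes. In whole blood, however, a clock sees a
mixture of leukocyte subtypes whose proportions themselves change with
age — naive lymphocytes decline, memory lymphocytes accumulate — so part
of every blood clock's signal is *extrinsic* (composition-driven) rather
than *intrinsic* (shared cell-level aging). Cell composition can then
confound EAA–outcome associations: a disease that shifts neutrophil and
lymphocyte proportions will move EAA even when cell-level aging is
untouched.

`immunoEAA` implements this analysis end to end: reference-based
deconvolution of 12 immune cell types (Bas, Eos, Neu, Mono, Bnv, Bmem,
CD4nv, CD4mem, Treg, CD8nv, CD8mem, NK) by constrained least squares;
clock evaluation with library-level QC masking; residual and difference
EAA; intrinsic EAA adjusted for the traditional six cell types or the
granular eleven (NK excluded); per-cell and mutually adjusted
association models with age-group z-scoring and BH-FDR; partial and
additional R² variance decomposition; composition PCA; and a matched
case/control confounding study. Because public cohorts cannot be
redistributed, every analysis is exercised against a synthetic-data
module whose ground truth is known exactly, making the whole pipeline
testable as a set of parameter-recovery experiments.

# The generative model

## Composition

Cell proportions follow a logistic-normal model: for sample $i$ and cell
$k$,

$$\mathrm{logit}_k(i) = b_k + s_k \min(\mathrm{age}_i, \kappa_k)
  + d_k\,\mathrm{diseased}_i + \varepsilon_{ik} + \lambda_k L_i,
\qquad w_i = \mathrm{softmax}(\mathrm{logit}(i)),$$

with $\varepsilon_{ik} \sim N(0, \sigma^2)$ independent per cell and
$L_i \sim N(0, \tau^2)$ a *shared antigen-experience factor* with
loadings $\lambda = +1$ on the memory subsets and $-1$ on the naive
subsets. Additive logit effects are used (rather than a Dirichlet)
because they give independent control of per-cell age slopes and disease
shifts — exactly the structure the association models must recover.

Default study conditions (`bloodCompositionModel()`,
`defaultScenario()`), chosen once up front:

* Baseline logits calibrated so the age-50 expectation matches typical
  adult whole blood (Neu ≈ 54%, Mono ≈ 8%, CD8mem ≈ 8%, CD4mem ≈ 7%,
  CD4nv ≈ 5%, NK ≈ 5%, Bnv ≈ 4.5%, minor populations 1–1.5%).
* Age slopes: naive $-0.02$/yr, memory $+0.02$/yr, Neu $+0.03$/yr up to
  a knot at 18 years (the neutrophil share rises through childhood then
  plateaus).
* Independent dispersion $\sigma = 0.7$: for a rare cell the SD of its
  proportion is then comparable to its mean, matching the large relative
  spreads observed for rare subsets in adult blood.
* Shared axis $\tau = 0.8$: between-subject immune history co-moves the
  memory compartments and is the dominant source of correlated
  composition variation. Without it, the naive and memory members of
  one lineage would co-vary only through the simplex, which is far
  weaker than observed biology.
* Disease shifts (rheumatoid-arthritis-like): Neu $+0.45$ and Treg
  $+0.50$ logits, the other lymphocyte subsets, Mono and NK down by
  0.15–0.50 — composition-mediated confounding by design.
* An optional newborn override (elevated naive lymphocytes plus a
  basophil-like excess standing in for nucleated-RBC contamination of
  cord blood) is off by default: it is a scenario, not a core
  assumption.

## Methylation

On marker CpGs the mixture mean is $\mu = w^\top R$, where $R$ is the
reference library (12 cell types × marker CpGs). Synthetic libraries
give each cell type `nCpgsPerType` hypermethylated markers with a margin
of at least `delta` over every other type, guaranteeing identifiability;
the default library uses 12 markers per type, a deliberately small but
information-rich stand-in for the hundreds of markers in real extended
blood references.

Intrinsic aging is carried by a disjoint panel of drift CpGs with
$\mu = \mathrm{base} + \beta\,s_i$ (clipped to $[0,1]$), where the
intrinsic signal $s_i = \mathrm{age}_i + N(0, 7^2)$ (+ a planted disease
offset in intrinsic-disease scenarios). The defaults — 20 CpGs at
$3\times10^{-4}$ beta/yr — mimic the small per-CpG effect sizes of real
age-associated CpGs (a few percent per decade). The 7-year
between-subject SD matches the spread of observed EAA values in blood
(5–7 years). These choices make the intrinsic signal individually weak
and noisy, which is what produces the real-world phenomenon that
composition-dominated clocks lose most of their accuracy inside
purified cell populations.

Every CpG is observed through Beta noise,
$\beta \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with precision
$\phi = 100$, so $\mathrm{var} = \mu(1-\mu)/(1+\phi)$: values stay in
$[0,1]$ with realistic heteroscedasticity.

## Planted clocks

`generateClock()` builds a clock whose variance splits in a known
proportion between the drift panel (intrinsic) and the marker CpGs
(extrinsic). Drift weights are $a_d = 1/(n_D \beta_d)$, so the intrinsic
score equals $s_i$ up to a constant. Marker weights $v$ solve
$R v = \gamma$ exactly (full row rank), so the extrinsic score is
$\gamma^\top w$ for a chosen per-cell loading vector $\gamma$. Both
components are standardised on a noiseless probe cohort so that the
drift share of the score variance equals `intrinsicFraction`;
`decomposeClockVariance()` recovers the share empirically within 0.05.

The default $\gamma$ (`defaultCellLoadings()`) is the naive-to-memory
axis dominated by the CD8 compartment (CD8mem $+1$, CD8nv $-1$, B/CD4
subsets $\pm 0.4$, granulocytes $+0.1$): clocks trained on
age-correlated blood composition load on the axis that tracks age, and
memory CD8 T cells — the fastest-dividing, most clonally expanding
compartment — are its strongest driver. `targetNoiseSd` jitters
$\gamma$ so a panel of clocks differs in its loadings; the default
panel spans four age-scale clocks (intrinsic fractions 0.75–0.35), a
pace-scale clock (0.25) and a mitotic-scale clock (0.15). Calibration is
an identity transform onto family units (years; a unitless pace around
1.0; division counts around 3300); a monotone log-linear adult-age calibration is
supported for user-supplied clocks.

# The estimators

**Deconvolution.** Per sample, minimise $\lVert b - R^\top w \rVert^2$
over $w \ge 0$ with $\sum w \le 1$ (default; the unexplained remainder
is allowed) or $\sum w = 1$. The solver is an exact active-set method on
the 12-dimensional normal equations, with ties broken by lowest cell
index for determinism; the sum constraint is handled by a bordered KKT
system that activates only when the unconstrained-sum solution exceeds
one. Samples missing more than 10% of the library CpGs are masked; the
boundary is strict (exactly 10% is kept). The same rule masks samples
per clock.

**EAA variants.** `eaaResidual()` is the OLS residual of mage on
(intercept, age) within the supplied population — mean zero and exactly
age-uncorrelated by construction; constant-age populations fall back to
centred mage with a warning. `eaaDifference()` (mage − age) exists for
age-scale clocks only. IEAA is a *single* regression of mage on age plus
the cell block (not a residual-of-residuals; the two differ and the
single regression is the standard intrinsic-EAA construction; a
`twoStage` flag provides the alternative). The six-cell block aggregates
the 12-cell estimates (Bcell = Bnv+Bmem, CD4T = CD4nv+CD4mem+Treg, Gran
= Neu+Eos+Bas, plus CD8nv, CD8mem, Mono) for internal consistency; the
eleven-cell block drops NK, which has the smallest proportions among the
cell types that are almost never zero, to avoid compositional
collinearity. Age² is *not* included in the residualisations — the
quadratic age term belongs to the association models only.

**Association models.** Within each age group (newborn = exactly 0;
pediatric = 0–18 including newborns; adult = 18–99) EAA and cell
proportions are z-scored (sample SD, $n-1$). The per-cell model regresses
the EAA z-score on one cell z-score plus sex, ancestry, disease (a
single any-disease indicator by default), age and age²; constant or
collinear columns are dropped deterministically (age² before age, then
ancestry levels by frequency) — in the newborn group the age terms are
always dropped as constants. The mutually adjusted model enters all
eleven cell z-scores at once. BH-FDR is applied per clock × age group ×
variant across the cells by default (matching per-panel starring;
a global family is available). Standardisation makes the coefficients
scale-free: proportions and percentages give identical results.

**Variance decomposition.** Partial R² of a covariate block is
$1 - \mathrm{SSE}_{\text{full}}/\mathrm{SSE}_{\text{reduced}}$ with the
full design (11 cells + sex + ancestry + disease + age + age²); the age
block is {age, age²}, the cells block all eleven. Additional R² adds one
cell at a time to the baseline (no cells) model — here NK is included,
since one-at-a-time models have no compositional collinearity. The
outcome is raw residual EAA: R² is scale-invariant so z-scoring is
unnecessary. Composition PCA (centred, unscaled by default — the
compositional scale is shared) provides the batch QC: batch labels are
assigned independently of composition in the generator, so PC–batch
F-tests are null by construction.

**Matching.** Cases are matched 1:1 to controls exactly on sex and
ancestry and greedily nearest-neighbour on age, hardest cases first
(smallest eligible pool), without replacement, followed by a
deterministic 2-opt swap pass within each exact stratum; the result
stays within a few percent of the exact optimal assignment (computed by
a sorted non-crossing dynamic program, `optimalMatchDistance1d()`). The
group-effect models are covariate-free OLS on the case indicator
(equivalent to a pooled-variance t-test) — matching handles the
confounders; a covariate-adjusted variant is available.

# The planted studies

The `experiment*()` functions re-run the package's headline analyses
from scratch (sizes chosen to keep the full suite in minutes on one
core; the vignette states them as the package's study sizes):

* `experimentDeconvolution` — exact recovery on noiseless mixtures
  (error at solver precision) and per-cell MAE under precision-100 noise
  at n = 200, cross-checked against a penalty-formulation NNLS oracle.
* `experimentAssociationStudy` — 20 cohorts of n = 2000: in adults the
  per-cell model recovers the planted signs (naive negative, memory
  positive, FDR-q < 0.05) for all six naive/memory subsets; across a
  panel of canonical-loading plus jittered clocks, the mean absolute
  standardized association obeys IEAA-11 < IEAA-6 < EAA for at least
  10 of 12 cell types. The two exceptions, when they occur, are Bmem
  and CD4mem: conditioning on the Bcell/CD4T aggregates *sharpens* the
  within-lineage naive/memory contrast that the clock loads on, a real
  property of aggregation-based six-cell adjustment worth knowing about.
* `experimentTypeIError` — under the null (intrinsic clock, composition
  independent of age and disease, independent-noise cell regressors so
  the 500 fits are mutually independent), the per-cell test rejects at
  the nominal rate.
* `experimentVarianceRecovery` — the planted dominant block (cells for a
  composition-dominated clock; disease for a planted intrinsic disease
  effect with an intrinsic clock) attains the largest partial R², and
  the additional-R² ranking of cells matches the ranking computed on
  true proportions at n = 12000 (Spearman).
* `experimentConfounding` — pools of 2600 with 15% disease prevalence
  (≈ 350–430 matched pairs, the scale of a real RA case set):
  composition-mediated disease moves raw EAA of an
  inflammation-sensitive pace clock (neutrophils as a strong positive
  driver) but not its IEAA-11; a direct intrinsic effect (+12 years on
  the intrinsic signal) survives full cell adjustment of an
  intrinsic-dominated clock.
* `experimentPurifiedDegradation` — a mitotic-scale clock with intrinsic
  fraction 0.15 loses over 0.3 of age-tracking R² inside purified cell
  panels (40 adult donors per cell type), and pooled purified EAA is
  lower in CD8nv than CD8mem in every replicate.

# What the synthetic data do and do not show

The generator reproduces the *statistical structure* the analysis needs:
simplex-valued composition with age trends, disease shifts and correlated
between-subject variation; mixture methylation with Beta noise; weak,
noisy intrinsic drift; clocks with known intrinsic fractions. It does
not emulate array chemistry (probe types, dye bias), probe-level QC,
genomic correlation among CpGs, sex-chromosome methylation, ancestry- or
sex-linked composition differences, or nonlinear clock training. Passing
tests therefore demonstrate that the estimators recover planted truth
under the stated noise model — not that any particular real-data effect
size will be reproduced.

# Numerical choices and degenerate inputs

* Active-set tolerances: 1e-9 for constraint activity; noiseless
  recovery is exact to ~1e-12.
* Missing clock CpGs contribute zero to the linear score once a sample
  passes masking (deterministic; reference-mean imputation is available
  via `imputeWith`).
* Constant age ⇒ centred-mage fallback with a warning; constant or
  collinear covariates are dropped in a fixed order and logged in the
  fit output.
* Degenerate references (rank-deficient, or fewer than two shared
  markers for a cell type) and empty groups raise informative errors;
  association-grid rows for unfittable groups are emitted with NA
  estimates so runs complete.
* All randomness flows from explicit integer seeds through
  `deriveSeed()`; regenerating any object with the same arguments is
  bit-identical.

# Known limitations

* The six-cell IEAA uses aggregated 12-cell estimates rather than an
  independent coarse deconvolution; as noted above this can sharpen
  within-aggregate contrasts instead of attenuating them.
* NK sits outside both adjustment blocks, so both IEAA variants remove
  its signal almost completely and comparisons for NK are mostly noise.
* The greedy matcher is near-optimal, not optimal; `optimalMatchDistance1d`
  quantifies the gap.
* Mitotic-scale clocks are kept positive by their calibration range, not
  by a hard constraint.
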