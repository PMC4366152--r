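---
title: "Genomic selection and locus mapping in DH populations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection and locus mapping in DH populations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dhgs` implements a complete analysis chain for quantitative traits in
biparental doubled-haploid (DH) populations, organised around flowering
time (FT) in oilseed rape (*Brassica napus*): whole-genome prediction
with eight models, repeated cross-validation with shared folds,
breeding-value estimation, random-forest screening of trait-associated
SNPs, allelic-direction tests, MARS-based epistasis mapping, and
window-based functional enrichment. Because chip data of this kind are
rarely redistributable, the package ships a first-class simulator that
generates DH panels with the statistical structure the analysis assumes
and with planted ground truth for recovery testing.

This vignette records the models, their assumptions, the tunable
parameters, and the design decisions taken where more than one
reasonable choice existed.

## The data model

A DH line is produced by doubling a single gamete from the F1 of a
biparental cross, so every marker is homozygous for one of the two
parental alleles — coded `A` (first parent) or `B` (second parent) on
disk and $x_{ij} \in \{-1, +1\}$ numerically. Phenotypes are
flowering-time records in days, one per line and environment, where an
environment is a site–year combination in one of three geographic
regions (north, south, east; the default design has 4 + 4 + 2 years).

For a single environment, the linear families model

$$y_i = \mu + \sum_{j=1}^p \beta_j x_{ij} + \varepsilon_i,$$

with far more markers than lines ($p \gg n$), so all of them differ
only in how the $\beta_j$ are shrunk.

## Quality control

The QC cascade runs in a fixed order, each rule computed on the set
surviving the previous one:

1. samples with $\ge$ 20% missing calls are removed,
2. markers missing in more than 10% of the remaining samples are
   removed,
3. markers with minor allele frequency strictly below 0.05 are removed.

The boundary conventions (≥, then strict >, then strict <) are
deliberate and tested; a marker at MAF exactly 0.05 survives. After the
cascade, `A`/`B` calls are coded −1/+1 and the few remaining missing
cells are imputed by the per-marker mean, which preserves column means
(equal to $1 - 2\,\mathrm{freq}(A)$) and keeps every entry in
$[-1, 1]$. Major-allele imputation would be an alternative; mean
imputation was chosen because it keeps the coded columns' first two
moments interpretable for ridge-type models.

Linkage disequilibrium is the squared Pearson correlation of coded
columns. For a fully homozygous DH design this *is* the classical
haplotype $r^2$ (each line carries one gamete), an identity rather than
an approximation. Pruning is a greedy scan in map order: a marker joins
the cluster of the first accepted tag it reaches $r^2 \ge 0.7$ with,
otherwise it becomes a new tag. This is deterministic, order-stable,
and guarantees pairwise $r^2 < 0.7$ among tags. Constant columns are
assigned $r^2 = 0$ against everything so they can never cluster.

## The eight prediction models

All families share one fit/predict contract. Environment covariates are
handled in two ways, by design: linear and kernel families (RR-BLUP,
the Bayesian alphabet, RKHS) estimate reference-coded site–year dummies
jointly as unpenalised fixed effects; SVR and random forest, which have
no native fixed-effect notion, are fitted on phenotypes residualised
against environment means, with the mean added back at prediction.
Inputs to SVR/RF stay on the raw −1/+1 coding (a flagged assumption:
whether standardisation was applied upstream in comparable analyses is
usually unstated).

* **RR-BLUP** minimises $\mathrm{RSS} + \lambda \sum_j \beta_j^2$ with
  the intercept and covariates unpenalised, solved exactly — through
  the primal normal equations when $p < n$ and the $n \times n$ dual
  otherwise. By default $\lambda$ is the REML-estimated variance ratio
  $\sigma_e^2 / \sigma_\beta^2$ of the equivalent random-effect model,
  found by spectral decomposition after projecting out the fixed
  effects; a fixed $\lambda$ can be supplied.
* **Bayesian LASSO, BayesA, BayesB** are Gibbs samplers (implemented in
  C++ against R's RNG, so runs are exactly reproducible from a seed)
  with the classical conditional updates: per-marker
  exponential-mixture variances giving the double-exponential marginal
  (BL), per-marker scaled inverse-chi-square variances giving the
  scaled-t marginal (BayesA), and a point mass at zero with probability
  $\pi$ plus the BayesA slab, with the indicator sampled each sweep
  after integrating the effect out (BayesB). Defaults: 12,000
  iterations, 2,000 burn-in, thinning 5 — desk-scale settings that give
  stable posterior means at $p \approx 1{,}250$ (cross-validation runs
  use 1,500/500/2, which changes accuracies by well under the
  fold-to-fold noise); $\pi = 0.95$ fixed but configurable; prior
  scales set from the phenotypic variance at a nominal $R^2 = 0.5$, as
  reference implementations do. Convergence is monitored by split-chain
  R-hat on the residual-variance and intercept traces; values above 1.1
  are recorded in the fit's diagnostics rather than raised as errors.
* **RKHS regression** is kernel BLUP with
  $K_{ij} = \exp[-(D_{ij}/\theta)^2]$ on the Euclidean marker distance,
  fixed effects profiled out by GLS and the ridge level set by REML.
  $\theta$ defaults to selection from $\{0.25, 0.5, 1, 2, 4\} \times
  \mathrm{median}(D)$ by inner cross-validation; with a linear kernel
  ($K = XX'$) the fit is the exact dual of RR-BLUP, which the tests
  exploit as an identity check.
* **$\varepsilon$-insensitive SVR** (linear and Gaussian kernels) via
  `e1071`, tuned by grid search over inner cross-validation with
  defaults $C \in \{0.1, 1, 10, 100\}$,
  $\varepsilon \in \{0.01, 0.1, 0.5\}$ and the Gaussian width centred
  on the median-distance heuristic ($\times\{0.5, 1, 2\}$).
* **Random forest** regression via `ranger`: 1,000 trees, $mtry =
  \mathrm{round}(p/3)$ candidate markers per split, minimum node size
  5, bootstrap per tree. Permutation importance (mean out-of-bag error
  increase under marker permutation) is the canonical importance for
  selection, being less distorted by correlated markers than impurity
  importance.

## Cross-validation and breeding values

`make_folds()` draws folds on **lines**, never on line-by-environment
records, so a line cannot leak between train and test, and the same
plan (content-hashed) is served to every model. Accuracy is the Pearson
correlation of observed and out-of-fold predicted phenotype. "Mean
correlation" is ambiguous between pooling predictions per repeat and
averaging fold-wise correlations; the package pools per repeat (lower
variance with 18-line folds) and offers `pooling = "per_fold"`.
Per-environment evaluation fits each model within one environment
(intercept only); folds with fewer than three test phenotypes are
skipped with a warning. A single fold plan per run is used across
environments and logged.

GEBVs are estimated in two stages: line values adjusted for covariates
(site–year dummies for the overall GEBV; year within site for
per-region EBVs) by fixed-effect regression, then shrunk by
Gaussian-kernel RKHS at the REML variance ratio, and centred. The
two-stage form is exact for balanced designs and unbiased otherwise.

## SNP selection, directions, epistasis

Selection runs against **region EBVs**, not raw site–year values, to
suppress associations driven by single-season accidents (a raw-value
mode exists for diagnostics). Tag SNPs are ranked by permutation
importance averaged over 20 independently seeded forests; then a
recursive inclusion walks fractions 5%, 10%, …, 100% of the ranking,
records each forest's out-of-bag MSE averaged over 20 repetitions, and
selects the minimal-MSE fraction (ties to the smaller). OOB MSE is used
as the curve's error because it is the forest-native generalisation
estimate and needs no extra split. Selected tags expand to their full
LD clusters for reporting and annotation.

Allelic direction uses Welch's t-test per SNP and environment (DH
genotype classes can be unbalanced, so equal variances are not
assumed). A SNP is direction-consistent when the early-flowering
genotype class is the same in every environment where the test is
significant; SNPs significant nowhere are reported as a separate
category rather than folded into the consistent count, since
consistency conditioned on an empty set is vacuous.

Epistasis mapping fits MARS — greedy forward selection of reflected
hinge pairs $h(\pm(x - t))$ with products capped at two distinct
markers, then backward pruning by
$\mathrm{GCV} = \mathrm{RSS} / (n(1 - C(M)/n)^2)$ with $C(M)$ counting
coefficients plus `penalty` (default 3) per knot. Knots sit at observed
predictor values only; for −1/+1 markers each variable contributes at
most one informative hinge, every hinge is affine in its marker, and a
surviving degree-2 product term is therefore exactly a marker-by-marker
interaction (an identity the tests assert). One knot is counted per
forward selection event, so a reflected pair shares its knot — for
binary markers, where only one member of each pair is non-degenerate,
this keeps the complexity charge per term at its intended level. The
forward pass is capped at $\min(2p + 1, n/2, 41)$ terms and stops if
the complexity charge approaches $n$.

A refinement guards the reported pairs' meaning: on −1/+1 markers the
product $(x_1+1)(x_2+1)$ spans $x_2$'s main effect, so a surviving
degree-2 term can be a pure proxy for a main effect the model lacks.
After pruning, each surviving product is therefore tentatively swapped
for the marginal hinge(s) of its markers, and the swap is kept whenever
it does not worsen the GCV — a genuine interaction loses fit under
every swap and survives, while main-effect proxies are decomposed. With
this step the stability-selection procedure's false-positive rate under
an additive-only trait is measured at about 7% per dataset.

"Cross-validation determines the interactions" is made precise as
stability selection: 10 rounds of 10-fold CV, a pair credited per round
when a degree-2 term on it appears in the majority of that round's
fold models, and pairs credited in at least half the rounds reported.
Both thresholds are configurable; the rule is deliberately
conservative and reproducible. A caveat the tests encode: a pure
interaction with no marginal effect is structurally hard for the MARS
forward pass (the first hinge must be marginal), but in this pipeline
MARS only ever sees forest-screened tags already associated with the
EBVs — loci with marginal effects — so the power checks plant pairs
with modest additive effects alongside the interaction.

## Enrichment

SNPs map to genes when the closed window $\pm 1$ kb around the SNP
overlaps the half-open gene interval $[start, end)$ — conventions
stated exactly to avoid off-by-one drift. Term over-representation is
the one-sided hypergeometric (Fisher) test with fold enrichment
$(k/n)/(K/N)$; the conservative EASE-style adjustment (one candidate
hit removed) is available by flag but off by default. Groups of terms
score $-\log_{10}$ of the geometric mean of member p-values, with the
classical strict threshold 1.3 ($\equiv p = 0.05$). Term groupings are
user-supplied: similarity-based clustering of terms (as annotation web
services do) is out of scope, and the package makes no attempt to
reproduce database-dependent fold-enrichment values.

## The simulator

`simulate_dh_genotypes()` draws each line as an independent doubled
gamete: the first allele per chromosome is fair, and the allele
switches between adjacent markers with the Haldane recombination
fraction $r = (1 - e^{-2d/100})/2$. Haldane (no interference) was
chosen over Kosambi as the simplest process consistent with a cM map
that still produces realistic LD decay; there are no heterozygotes, no
segregation distortion, and no genotyping-error model beyond
missingness. The default map spreads 1,674 markers uniformly at random
over 19 linkage groups (A1–A10, C1–C9) of 90 cM, with physical
positions at a nominal 500 kb/cM.

Phenotypes follow
$y = \mu + \mathrm{env} + \textstyle\sum_j a_j x_j +
\sum_l w_l x_{l_1} x_{l_2} + \mathrm{gxe} + \varepsilon$.
Effect sizes are supplied in trait units (days); the residual SD is
derived so the genetic share of the within-environment variance equals
the target $h^2$, and G×E is modelled as independent normal deviates
per line and environment — the simplest form consistent with "large
G×E" when no parametric structure is known — defaulting to one third of
the non-genetic variance. The default truth plants 30 additive QTLs
with exponentially distributed magnitudes and random signs (a few
large, many small) plus two epistatic pairs, scaled to a ~10-day
within-environment SD at $h^2 = 0.6$; the default missingness pattern
removes 8 of 190 lines and thins 1,674 markers to roughly 1,250 under
the QC cascade, mirroring the scale of the reference design. Marker
density per linkage group is uniform because true chip densities per
group are generally not published.

What the simulator does **not** emulate: segregation distortion,
genotyping error beyond missingness, interference, structured (e.g.
correlated-across-years) G×E, or population structure beyond the
biparental cross. Passing recovery tests on simulated panels therefore
demonstrates the machinery is correct under the stated generative
model, not that real chip data meet those assumptions.

## Numerical choices and degenerate inputs

* REML for the variance ratio optimises the profiled restricted
  likelihood on a 33-point log grid refined by `optimize()`; eigenvalues
  are floored at zero.
* `rr_blup` with $\lambda = 0$ uses the primal equations and fails
  loudly when the design is rank-deficient; the kernel solve reports a
  singular system rather than regularising silently.
* Constant marker columns: $r^2$ defined as 0; forests and MARS simply
  never split on them.
* MARS candidate columns are accepted only if their orthogonalised norm
  exceeds $10^{-10}$ of the raw norm, which silently drops the
  degenerate reflected twin on binary markers.
* Welch's test with two zero-variance groups returns $t = 0, p = 1$
  when means agree and $p = 0$ otherwise.
* Ties: inclusion-curve minima go to the smaller fraction; importance
  ranks break by marker id; "best model per environment" breaks
  lexicographically.

## Problem sizes used by tests and the acceptance script

The shipped checks run on one CPU at the reference scale: the standard
panel (190 → 182 lines, 1,674 → ~1,250 markers, 10 environments,
$h^2 = 0.6$). Cross-validation checks use one repeat (the acceptance
script covers all ten environments; the test suite one environment per
region), MCMC at 1,500/500/2, SVR with a single tuned configuration,
and forests of 100–500 trees for the selection protocol (20 ranking
runs, 20 inclusion repetitions); Monte-Carlo calibration checks use 20
seeds. These sizes are the package's reproducibility defaults; the
full-length defaults above remain available through each function's
arguments.

## Known limitations

* Bayesian samplers return posterior means only; no credible intervals
  are exposed (diagnostics carry the chains' R-hat instead).
* The stability-selection reading of "CV determines the interactions"
  is one defensible formalisation; per-fold crediting rules differ
  across the literature, so counts are comparable only within a rule.
* Forest OOB error at very small marker counts (2–4 features) is
  noisier than its bagged-tree idealisation; the inclusion curve's 5%
  step is only meaningful when 5% of the tag panel is more than a
  handful of markers.
* Enrichment results depend entirely on the user-supplied gene and
  term tables; no ontology traversal or propagation is performed.
* Epistasis is mapped on EBVs that were themselves estimated with a
  Gaussian kernel, a nonlinear function of the markers; MARS pairs on
  such EBVs can reflect that smoothing rather than physiological
  epistasis. This is inherent to the two-stage design (EBVs first,
  interactions second), so reported pairs should be read as candidate
  interactions for validation, not confirmed epistatic loci.
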