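---
title: "Methods: linking brain network change to cognitive recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking brain network change to cognitive recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrecov)
```

# The analysis in one paragraph

`netrecov` implements a longitudinal analysis of traumatic brain injury
(TBI): patients are scanned early (days) and late (about a year) after
injury, controls once. Each scan yields a symmetric 90-region
connectivity matrix whose entries are mean fractional anisotropy (FA)
along white-matter tracts. From each matrix the package derives
node-level graph metrics; from the neuropsychological battery it derives
a one-number cognitive function component (CFC); it then selects the
metrics that discriminate the early from the late phase (univariate
filter, then a genetic-algorithm random-forest wrapper, "GARF"), and fits

$$\Delta Y = \beta_0 + \beta_1 \Delta X_1 + \dots + \beta_N \Delta X_N$$

where $\Delta$ is the late-minus-early change of the standardized
selected metrics ($X$) and of the CFC ($Y$). The model is pruned by
backward elimination, checked with variance inflation factors (VIF) and
residual diagnostics, and validated with repeated train/test splits and
a random-metric-subset null distribution. Binary lesion masks are
combined into a voxelwise probability map whose overlap with atlas
regions is quantified with the Sørensen–Dice coefficient.

# Graph metrics

All metrics operate on a validated matrix: symmetric within $10^{-10}$,
zero diagonal, non-negative, no missing entries. Path-based metrics use
the distance $d = 1/w$, the standard convention for FA-weighted
connectomes (stronger tracts are shorter). The metric families are:

* **strength** $s(v)=\sum_u w_{vu}$;
* **weighted clustering** (Onnela geometric-mean form with
  $\hat w = w/\max w$) — the network's segregation around each node;
* **local efficiency** — the Latora–Marchiori efficiency of each node's
  neighbour subgraph. The common verbal gloss of this metric can be read
  as closeness; the package implements the established neighbour-subgraph
  definition, and closeness is available separately;
* **betweenness** with fractional counting over equal-length shortest
  paths, and **closeness** $(n-1)/\sum_u d(v,u)$; on disconnected graphs
  closeness switches to the harmonic form $\sum_u d(v,u)^{-1}/(n-1)$ so
  unreachable pairs contribute zero;
* **eigenvector centrality** (non-negative principal eigenvector, unit
  2-norm; assumes a connected graph) and **PageRank** (damping 0.85,
  power iteration, L1 tolerance $10^{-9}$, cap 1000 iterations — a
  failure to converge is an error carrying the residual);
* **local disassortativity**
  $\delta(v)=\sum_{u\in N(v)} w_{vu}\,|s(v)-s(u)| \big/ \sum_{u\in N(v)} w_{vu}$,
  the edge-weighted mean absolute strength gap between a node and its
  neighbourhood. It decreases when a region's strength approaches its
  neighbours' (by strengthening or weakening on either side) and grows as
  the gap widens. "Local assortativity" is reported as the negated,
  across-region standardized value. No closed-form reference
  decomposition of global assortativity into node contributions is
  universal; this definition was chosen because it reproduces the
  qualitative mechanics usually described (central/peripheral
  strengthening and weakening) and is exactly testable
  ($\delta \equiv 3$ on a unit star $K_{1,4}$, $\delta \equiv 0$ on
  strength-regular graphs);
* **global assortativity** — Pearson correlation of endpoint strengths
  over the edge list, both orientations; strength-regular graphs (zero
  endpoint variance) raise an undefined-statistic error.

Binary-graph metrics and matrix thresholding are deliberately out of
scope: matrices are analysed fully weighted.

# Cognitive function component

Tests with lower-is-better polarity (timed CWIT trials) are negated via
an explicit polarity map before any analysis. Tests whose |z-skewness|
(sample skewness over its standard error
$\sqrt{6n(n-1)/((n-2)(n+1)(n+3))}$) exceeds 1.96 are Box-Cox transformed
with a maximum-likelihood $\lambda$ (one-sample profile likelihood,
non-positive samples shifted by $-\min + 1$ with the shift recorded).
All tests are then z-scored, so the PCA is a correlation PCA; the
package fits it on the pooled sample (controls + both patient phases) so
a single loading vector scores every timepoint. The CFC is the first
component score, sign-oriented so the control mean is at least the
early-patient mean — "higher CFC = better cognition" by construction.
Group comparisons (early vs control, late vs control independent; early
vs late paired by subject) use a t-test when Shapiro–Wilk accepts
normality at the 5% level and the rank-based alternative otherwise, with
Benjamini–Hochberg correction across the three comparisons.

# Feature selection

The selection is cross-sectional over the $2 \times n_\text{patients}$
patient rows (46 at the study size). Features are z-scored per column
with parameters recorded. Step 1 ranks every (region, metric) feature by
a paired early-vs-late test (normality-gated, as above) and keeps
uncorrected $p < 0.05$ — deliberately uncorrected, because the step
screens candidates rather than drawing inference; a `top_k` cap is also
available since the boundary between "cut" and "rank" readings of this
step is ambiguous. Step 2 runs a generational GA over binary inclusion
masks: tournament selection, uniform crossover ($p = 0.8$), per-bit
mutation $1/L$, elitism 2, fitness = mean 5-fold cross-validated
accuracy of a 500-tree random forest on the masked columns, with exact
fitness ties broken toward fewer features. Folds and per-fold forest
seeds are fixed across masks, so fitness is a deterministic function of
the mask and the whole search is reproducible from one seed.

Two fold modes exist: `grouped` (default) keeps a patient's two rows in
one fold, so no patient contributes to both training and testing;
`paper` treats the 46 rows as independent samples. The grouped default
is the defensible one for paired data; the alternative is provided for
comparability and the mode used is recorded in the report provenance.

Because the GA maximizes a cross-validated accuracy, the accuracy of the
winning mask is an optimistically biased estimate on null data —
nested cross-validation would be needed for an unbiased figure and is a
deliberate non-goal. Tests therefore check calibration of the mean
accuracy across seeds, not of single runs.

# Change-score regression

Ordinary least squares of $\Delta$CFC on the selected $\Delta$ metrics,
with adjusted $R^2$, nRMSE (RMSE divided by the observed range of
$\Delta$CFC — "normalized" is not otherwise pinned down), an F-test
against the intercept-only model, and standardized coefficients
$\beta_j\,\mathrm{sd}(\Delta X_j)/\mathrm{sd}(\Delta Y)$ as the
importance ranking. Backward elimination drops the highest-p predictor
per round until every coefficient and the model F-test are significant
at $\alpha = 0.05$ (two-sided; the threshold is a package choice).
VIFs ($1/(1-R_j^2)$) are reported at every step as a multicollinearity
check but never trigger automatic removal; values $\ge 10$ are flagged.
Saturated starts (more predictors than rows minus two) are trimmed to
the leading-ranked feasible subset with a warning. Residual diagnostics
return the data for residual-vs-fitted, lag-1 and normal-quantile plots
plus a Shapiro–Wilk p; no plotting is mandated.

A property worth knowing: with $k$ pure-noise predictors in the starting
set, the last surviving null predictor behaves like the minimum of $k$
uniform p-values, so the probability that elimination returns *exactly*
a planted pair with 5 nulls present is about $0.95^5 \approx 0.77$, even
though the planted predictors themselves are essentially never lost.
Simulations in the test suite reflect this.

# Validation

The "bootstrap" split analysis is subsampling without replacement (the
traditional name is kept): for each split size (20–3, 19–4, 18–5 by
default) the patients are repeatedly partitioned, the fixed
retained-feature model is refit on the training part and predicts the
held-out patients; per-patient prediction means/sds are pooled over runs
and an adjusted $R^2$ of observed vs mean-predicted values summarizes
each split size, with the whole procedure repeated (default 10 times) to
attach a dispersion. The mean-prediction summary is the default reading;
per-repeat values are also emitted.

The random-subset null draws $k$ features per run from the step-1
candidate pool, fits the model *without* elimination (a flag enables
elimination for sensitivity analysis), and records adjusted $R^2$ and
nRMSE. Empirical p-values use the add-one correction
$p = (1 + \#\{\text{null at least as good}\})/(\text{runs}+1)$, so they
are never zero.

# Lesion maps

The probability map is $100\cdot\text{count}/n_\text{masks}$ per voxel,
where the denominator counts subjects *with* masks (patients without a
visible lesion contribute nothing). Thresholding keeps voxels lesioned
in at least 3 patients by default. Dice overlap
$2|A\cap B|/(|A|+|B|)$ is computed against an integer-labeled atlas
volume; the package ships no real atlas — a synthetic octant labeling
(`octant_labels()`) stands in for parcellations in tests and the
synthetic pipeline, and the thresholded map is the default Dice input
(the raw support is also computable).

# The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not the physics of diffusion MRI. Defaults state the study conditions:
28 controls (one timepoint), 23 patients (early and late), 90 regions.
Per subject, a modular weighted random graph (6 contiguous modules,
overall density 0.3, within-module weights Beta with mean 0.45 and sd
0.10, between-module mean 0.30, clipped to (0, 1], plus a weak ring
backbone guaranteeing connectedness) plays the role of the pre-injury
network; the real matrices' weight distribution and density are not
reported anywhere, so these are documented stand-ins exposed in the
configuration. Injury multiplies edges incident to a configurable set of
"frontal" regions by `early_attenuation` (default 0.7) — attenuation
rather than deletion keeps all path metrics finite — and the late matrix
interpolates back toward the base network by a latent per-patient
recovery factor $r \sim U(0.1, 1)$. Cognitive scores are linear in a
latent ability; the late-phase ability gain is
`recovery_gain`$\cdot r$ (default slope 1.5, on the scale of a planted
early deficit of mean 1.5), test noise sd defaults to 0.5 on the
unit-loading scale, one test (List Learning by default) is exponentiated
so its raw scores are significantly right-skewed, and timed tests carry
negative polarity. About 19 of 23 patients receive a spherical lesion
mask (radius 2.5–6 voxels) inside a designated frontal octant of a
45×54×45 grid. Mild/moderate labels come from thresholding a severity
latent at a 18:5 ratio and do not alter generation, matching the working
assumption that the moderate injuries here behave like mild ones.

Passing tests on this cohort demonstrate that the pipeline recovers
planted structure of the assumed form; they cannot show robustness to
registration error, tractography bias, non-spherical lesions, practice
effects on repeated testing, or non-linear metric–cognition coupling,
none of which the generator emulates.

# Problem sizes and seeds

One master seed drives everything; per-stage streams are spawned from it
so changing, say, the bootstrap effort does not perturb the GA. GA
defaults are population 50, 40 generations, 500 trees. The bundled
example configuration and the test suite run the same algorithms at
desk scale — GA population 30, 12 generations, 200 trees, 200 bootstrap
and null runs, 20-seed simulation batches — sizes chosen so a complete
run takes tens of seconds on one core while leaving the planted-recovery
and calibration properties comfortably detectable. Fitness values are
memoized per mask, so masks revisited by the GA (increasingly common as
the population converges) cost nothing to re-score.

# Known limitations

* The GARF accuracy is an in-search cross-validation estimate, not a
  nested-CV generalization estimate.
* The local (dis)assortativity definition is one defensible reading of a
  node-level assortativity contribution; a strength-based
  Piraveenan-style decomposition would be an alternative and could be
  added behind a configuration switch, never silently.
* With 16-ish predictors and 23 patients the initial regression is
  near-saturated; inference before elimination should be read with that
  in mind (the package warns, fits, and reports residual degrees of
  freedom through the standard lm machinery).
* Empirical p-values from the subset null are granular at
  $1/(\text{runs}+1)$.
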