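---
title: "Projecting range change under obligate biotic interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting range change under obligate biotic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostsdm)
```

## The modelling problem

Bioclimatic envelope models relate a species' presence–absence record to
climate and project the fitted response onto a future climate surface.
For a species that can only occur where a second species is present — a
dragonfly that lays its eggs exclusively on one water plant, a butterfly
tied to a single larval host — a climate-only projection answers the wrong
question: the climatically suitable area matters only where the host can
also live. `hostsdm` implements a climate-only baseline and three schemes
for coupling the dependent species' projection to its host, together with
the evaluation, novel-climate screening and uncertainty-attribution
machinery needed to compare them.

All four schemes operate on the same ingredients: occurrence maps for the
dependent species $A$ and the host $S$ on a common grid, climate layers
for a calibration ("current") and a projection ("future") period, and an
ensemble of envelope models combined by the *probability mean* (the
arithmetic mean of member probabilities).

**No interaction.** An ensemble is fitted to $A$'s occurrences on climate
alone and projected onto both periods. The occurrence threshold is the
prevalence of the model-building (training) data, so the modelled current
range reproduces the training prevalence by construction.

**Overlap.** $A$ and $S$ are modelled separately on climate, each
thresholded at its own prevalence, and the projected range of $A$ is the
cellwise intersection of the two binary maps. By construction the result
is a subset of the climate-only range — the containment law
`gain%(overlap) <= gain%(none)` is exact and is asserted in the test
suite on randomized grids.

**Explanatory variable.** The host's *modelled* current occurrence
probability $\hat P(S)$ enters the dependent model as one additional
predictor next to climate; the future projection substitutes the host's
future probability. The host layer is the modelled probability, never the
observed presence — at projection time only a modelled host is available.

**Reference area.** The dependent model is calibrated only on cells where
the host is observed present, so it estimates the conditional probability
$\hat P(A \mid S)$. That conditional surface is projected over the full
grid and multiplied by the host's modelled probability,
$\hat P(A) = \hat P(A \mid S)\,\hat P(S)$, for both periods; the
threshold is $A$'s prevalence within the calibration training data. The
product bound $\hat P(A) \le \min(\hat P(A \mid S), \hat P(S))$ holds
cellwise and is asserted on every synthetic run.

The current period in the reference-area scheme is treated symmetrically
(the current conditional map is also multiplied by the current host
probability); only the future product is strictly required by the
scheme's definition, and reports flag the symmetric choice.

### Assumptions shared by all schemes

* *Unlimited dispersal*: any cell projected suitable is counted as
  attainable.
* Cells are equal-weight; range sizes are cell counts, not areas.
* The grid is static; reprojection and resampling are out of scope.
* The host model is always the climate-only ensemble (no recursion).

## Learners and the plug-in contract

Fitting is delegated to registered learners. Four ship with the package,
spanning the qualitative behaviours of the classical ensemble-SDM
algorithm families:

| name | model | extrapolation behaviour |
|------|-------|-------------------------|
| `glm_poly2` | ridge-stabilised logistic regression, linear + quadratic terms | smooth, unimodal responses continue beyond the data |
| `glm_lin`   | the same with linear terms only | monotone; projects open-ended trends |
| `cta`       | classification tree (rpart) | piecewise constant; never extrapolates |
| `sre`       | surface range envelope on presence-only $[q, 1-q]$ quantiles (default $q = 0.025$) | binary box; predictions are 0 outside the envelope |

`register_learner()` accepts any pair of `fit(spec, X, y)` /
`predict(artifacts, X)` functions, so further algorithms plug in without
touching the pipeline. The default ensemble pairs the two core learners
(`glm_poly2`, `sre`); the variance-partition analysis deliberately uses
all four, because attributing projection variance to "algorithm" is only
meaningful when the algorithm family is heterogeneous.

### Numerical choices

* `glm_poly2`/`glm_lin` carry a small ridge penalty (default `1e-6` on
  standardised non-intercept terms) so perfectly separable training data
  yield finite coefficients; standard errors come from the penalised
  Fisher information, back-transformed to the raw predictor scale.
* Zero-variance predictors are dropped with a warning, which makes the
  explanatory scheme degrade exactly to the baseline when the host layer
  is constant.
* Ties at the occurrence threshold count as presence
  (`probability >= threshold`), fixed so binary maps are bit-reproducible.
* In permutation importance, the Pearson correlation with a constant
  prediction vector is defined as 0 (a permutation that flattens the
  predictions has destroyed all signal); variables not used by a model
  score exactly 0. Importance of an ensemble is computed on the combined
  predictions, not averaged over members. Variable ties in the ranking
  break lexicographically.
* The mean-probability threshold is found by exhaustive scan over the
  observed probability values, minimising
  `|fraction(p >= t) - mean(p)|` with ties resolved toward the smaller
  cutoff — exact, no interpolation.
* The train/test split is a seeded uniform 70/30 partition without
  stratification.
* Missing climate propagates: a cell missing any variable is excluded
  from fitting and projected as `NA`; in range intersections
  `NA AND FALSE` is a definite absence while `NA AND TRUE` stays `NA`.

## Evaluation and thresholds

Discrimination is summarised by the rank-based (Mann–Whitney) AUC on the
held-out 30 % test cells; omission (presences predicted absent) and
commission (absences predicted present) rates are reported at the chosen
threshold. Thresholds are computed on the 70 % model-building cells —
prevalence by default, with the mean-predicted-probability rule available
as an alternative (`threshold_method = "mean_probability"`).

## Screening for non-analogue climate

The reference-area scheme deliberately restricts the calibration climate
space to the host's range, which makes extrapolation into novel climate
likely. Each projection cell is screened with the multivariate
environmental similarity surface: per variable, a piecewise similarity
against the calibration sample (with `f` the percentage of reference
values strictly below the projection value; ties count as not-below),
and per cell the minimum over variables. Negative similarity flags
non-analogue climate — at least one variable outside the calibration
range, an equivalence asserted by construction in the tests. Flagged
cells are carried through reports as a caution mask; projections are
never truncated by it.

## Attributing projection variance

Re-running every coupling scheme with each learner as a single-member
ensemble yields a complete factorial of relative range changes
$(G - L)/C$ (gained minus lost cells over currently occupied cells). A
Gaussian linear model with categorical encodings is fitted for every
subset of the factors `{algorithm, approach}`, and each factor's
independent contribution is its average $R^2$ increase over all entry
orders (hierarchical partitioning by all-subsets enumeration — exact at
this scale). Shares are normalised over independent contributions; raw
independent and joint values are reported alongside, and small negative
values, which the averaging scheme can produce, are reported as-is. For
two factors the independent contributions sum to the full $R^2$ exactly,
a property the tests assert to `1e-10`.

## The virtual scenario generator

Real atlas-and-climate inputs are deliberately out of scope; instead the
generator builds *virtual species* with known ground truth, so every
claim the package makes can be checked against the generating process.

Climate variables are linear gradients along a grid axis, rescaled to a
target range, plus spatially smooth noise (white noise convolved with a
Gaussian kernel, rescaled to a target standard deviation; the length
scale is in cells). The future layer adds a per-variable shift and
redraws the noise field. Species respond through quadratic-logistic
suitability — the minimal structure that produces unimodal niches and
hence simultaneous gain, loss and shift — and occupancy is Bernoulli in
the suitability, masked to host presences for the obligate dependent.
Detection and survey fraction default to 1 (census), matching the
treatment of atlas data as presence–absence truth.

### The default scenario

The packaged default emulates the study situation in which a host cannot
track climate change: on a 60 × 60 grid,

* `temp` runs from 14 at the equatorward edge to 0 at the poleward edge
  (rows), warms by +2 in the future, noise sd 1.0;
* `soil` is a stationary habitat-quality gradient along the same axis
  (0–10, noise sd 0.8) — it does not shift;
* `prec` runs 300–900 across columns, stationary, noise sd 30.

The host responds to `soil` and `prec` only: a widespread species with a
steep poleward habitat edge near row 43 that warming cannot move. The
dependent species tracks a steep thermal optimum (`temp` = 5) with a weak
moisture preference, and occurs only where the host does; it is roughly
an order of magnitude rarer than its host (prevalence about 0.03 versus
0.3), mirroring the rarity contrast typical of a specialised insect on a
widespread plant. Under the +2 shift the dependent species' thermal
envelope moves about 8 rows poleward — well past the host's stationary
edge — so the host's future range genuinely limits the dependent
species' climatically suitable area, and the comparison between coupling
schemes is non-trivial. The steepness of the host's edge matters: a
near-step habitat boundary is poorly captured by additive quadratic
climate terms, while the host-probability predictor and the range
intersection capture it directly, which is what gives the coupling
schemes their systematic effect.

The generator emulates gradient structure, spatial autocorrelation,
niche-driven occupancy and obligate masking. It does **not** emulate
dispersal limitation, sampling bias, observation error beyond Bernoulli
detection, temporal dynamics, or interactions among more than two
species — so passing tests support the correctness of the machinery, not
the realism of any particular ecological forecast.

## Problem sizes and reproducibility

The packaged analyses run on 60 × 60 grids (3 600 cells, the scale at
which the quadratic-logistic coefficients are comfortably recoverable
from a census realisation), with 20-replicate designs for the stochastic
properties; module tests use 40 × 40 grids. Every stochastic operation
takes an explicit seed, sub-seeds are derived by fixed offsets, and a
fixed configuration reproduces byte-identical artifacts (checksummed in
the run manifest).

## Known limitations

* Gains and losses are computed against the *observed* current
  occurrence (the definition of gained/lost sites used throughout); a
  modelled-current variant is available by substituting the modelled
  binary map, but is not the default reporting path.
* The overlap scheme's current-period map intersects the two *modelled*
  current binaries; both single-species maps are retained in the result
  for inspection.
* Hierarchical partitioning is implemented for a small number of factors
  (all-subsets enumeration); climate model or emission-scenario factors
  would require extending the factorial, not the partitioning code.
* The TIFF raster format stores 32-bit floats min–max scaled per layer
  (metadata in a JSON sidecar); round-trips are exact to about `1e-9` of
  the variable range, while CSV round-trips are lossless.
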