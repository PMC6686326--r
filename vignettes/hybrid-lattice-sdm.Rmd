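---
title: "Habitat suitability on a density-adaptive hybrid lattice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat suitability on a density-adaptive hybrid lattice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modeling problem

Forest inventories sample trees on a sparse network of plots; habitat
suitability models interpolate from those plots to a complete map. The
response modeled here is the **importance value** (IV), a 0--100 index of a
species' local abundance on a plot that combines its relative stem density
and relative basal-area dominance in equal parts:

$$\mathrm{IV}_{s} \;=\; 50\,\frac{n_s}{\sum_k n_k} \;+\;
   50\,\frac{BA_s}{\sum_k BA_k},$$

where $n_s$ and $BA_s$ are the focal species' stem count and basal area on
the plot. By construction the IVs of all species on a forested plot sum to
100; a plot with no stems at all is *non-forested* and carries no IV (that
is a different statement than "the species is absent"). The equal weighting
of density and dominance follows the classical importance-value convention
of community ecology.

Cell-level responses are the arithmetic mean IV over the forested plots
assigned to a cell, with forested plots lacking the species contributing 0.
Non-forested plots are excluded from the mean entirely: they carry no
information about the tree community. This zero-versus-missing distinction
is a deliberate design choice; an inventory plot in a parking lot says
nothing about a species' suitability, while a forested plot without the
species is an observed absence.

## The hybrid lattice

A uniform grid faces a resolution trade-off: coarse cells blur
environmental gradients, fine cells leave many cells with too few plots to
estimate a mean. The hybrid lattice resolves it adaptively. A coarse
(default 20 km) grid is laid over the study extent, anchored at the
extent's lower-left origin; each coarse cell is inspected through its four
fine (10 km) quadrants, and if at least 50% of the quadrants contain two or
more plots, the coarse cell is replaced by its four children. Otherwise it
is retained whole. With exactly two levels one pass over the coarse cells
is sufficient; the `depth` argument of `refine_lattice()` is reserved for
deeper nesting.

Conventions the refinement rule itself leaves open, fixed here and tested:

* **Membership** is half-open, $[x_{\min}, x_{\max}) \times
  [y_{\min}, y_{\max})$, so a plot on a shared edge is counted exactly
  once.
* **Edge cells** that intersect the extent polygon are retained whole, not
  clipped; their nominal areas (100/400 km²) are used throughout.
* **Grid registration** is at the extent origin; cell ids
  (`L<level>_<row>_<col>`) are deterministic functions of the row/column
  indices. Clipping edge cells to a boundary mask would change edge-cell
  counts but not the method, so whole-cell retention is the simplest
  defensible rule.

Rectangle-polygon intersection is computed by Sutherland--Hodgman clipping
with a shoelace-area test, so arbitrary (non-rectangular, non-convex)
study polygons are supported without a GIS dependency.

## Training data filters

Per species, cells are excluded from training in a fixed order, each cell
recorded under the first rule that removes it:

1. fewer than two inventory plots (`min_plots = 2`);
2. forest-cover fraction below 5% (`min_forest = 0.05`) --- such cells are
   dominated by non-forest land use and their covariates say little about
   tree habitat;
3. outlier cell means: among occupied (mean IV > 0) survivors of (1)--(2),
   cells whose mean IV exceeds `iqr_mult * IQR` (default 1.5) are dropped.

Rule (3) is implemented literally as stated --- the cutoff is a *multiple of
the IQR itself*, not the conventional upper fence. That reading is
unusually aggressive for distributions whose IQR is small relative to
their median (it can remove the entire upper half of occupied cells), so
the conventional Tukey fence $Q_3 + 1.5\,\mathrm{IQR}$ is available via
`outlier_rule = "tukey"`. The literal rule stays the default; neither
reading is asserted to be uniquely correct. Quartiles use linear
interpolation between order
statistics (`stats::quantile` type 7), a stated, testable convention. With
fewer than four occupied survivors the IQR is ill-determined and rule (3)
is skipped with a warning.

A species is modeled at all only if it occupies at least 60 cells
(`min_cells = 60`). Predictions, however, are made for *every* lattice
cell, including those excluded from training.

## The random-forest model and the mean--median rule

The per-species model is a regression random forest
(`randomForest`) with the method's standard parameterization: 1,001 trees, `mtry = 8`
candidate predictors per split, minimum terminal node of 10 observations.
The forest learner is deliberately *called, not re-implemented*; the
package's contribution is everything around it, and the contract it needs
is per-tree prediction access, the out-of-bag error, and permutation
importances. The out-of-bag pseudo-$R^2$ is $1 - \mathrm{MSE}_{oob} /
\widehat{\mathrm{Var}}(y)$ and may be negative, which later forces
withdrawal of the species.

Each cell's 1,001 per-tree predictions feed the **mean--median
combination**: the reported IV is the ensemble mean unless the ensemble
median is 0 *and* the coefficient of variation (sample SD divided by mean)
of the per-tree values is at least 2.75, in which case the prediction is 0.
The rule gives more weight to half the forest voting "absent" than to a
few trees voting high when the spread is large relative to the mean. Two
degenerate cases the rule itself does not define are fixed as: a zero
mean with any positive tree value has CV $+\infty$ (the zero rule fires);
an all-zero vector has CV 0 and yields 0 through the mean path anyway.
With `cv_threshold = Inf` the combiner reduces to the plain ensemble mean
(a tested identity).

**Confidence values** summarize ensemble agreement per cell: the fraction
of the 1,001 values within one sample standard deviation of the mean, or
--- for cells where the zero rule fired --- within one *unscaled* median
absolute deviation of the median. Bounds are inclusive, so a degenerate
ensemble (SD or MAD exactly 0) credits the values sitting exactly at the
center; with a MAD of 0 and 60% of values at 0, the confidence is 0.6.
The inclusive bound is a package convention for these
degenerate cases.

## Reliability scoring

Five components are computed per species:

* **RF $R^2$** --- the out-of-bag pseudo-$R^2$ above;
* **FK** --- fuzzy kappa between the observed and predicted IV maps on the
  training cells. IVs are rounded and binned into eight ordinal classes
  ({0}, 1--3, 4--6, 7--10, 11--20, 21--30, 31--50, 51--100); agreement
  between classes at index distance $d$ is scored $s(d) = 2^{-d}$, and the
  chance-corrected statistic is $(P_o - P_e)/(1 - P_e)$ with marginal-
  frequency expectation. The exact bin partition and the geometric
  similarity constant are package conventions, both configurable. With the identity similarity FK reduces exactly to Cohen's
  kappa (a tested equivalence).
* **TSS** --- sensitivity + specificity $-$ 1 with IV > 0 read as
  presence, computed on training-eligible cells using post-combiner
  predictions (so cells zeroed by the mean--median rule contribute
  predicted absences). If the observations are all one class the statistic
  is undefined and recorded as missing.
* **CVdev** and **Top5** --- stability metrics from a 30-tree bagging
  ensemble of single CART trees (`rpart`), each fitted on a bootstrap
  resample with all predictors available at every split. Per tree, the
  deviance explained (impurity decrease) is attributed to the split
  variables; Top5 awards $6 - r$ points when a tree's rank-$r$ predictor
  equals the forest's rank-$r$ predictor ($r \le 5$), normalized by the
  perfect-match sum of 15; CVdev is one minus the (0--1 clipped)
  coefficient of variation, across trees, of the inverse-rank-weighted
  deviance shares of the forest's top five predictors. Same-rank matching
  is the only reading consistent with both endpoint conditions (exact
  order $\to$ 1, no matches $\to$ 0); a present-anywhere variant is
  available via `match = "anywhere"`. The inverse-rank weights of CVdev mirror
  Top5's point scheme, a deliberate symmetry between the two stability
  metrics. References shorter than five variables keep the /15
  denominator.

The composite is
$$\mathrm{ModRel} = 0.33\,nR^2 + 0.33\,n\mathrm{FK} + 0.11\,n\mathrm{TSS}
 + 0.11\,n\mathrm{CVdev} + 0.11\,n\mathrm{Top5},$$
where each $n\cdot$ is the component min--max normalized across the
modeled species set (a constant column normalizes to 1, a missing value to
the worst observed). Cross-species min--max normalization puts the five
components, whose native scales differ, on a common footing and maps the
best species to the maximum attainable score of 0.99. Classes use half-open intervals --- high $\ge 0.70$, medium
$[0.55, 0.70)$, low $[0.14, 0.55)$, unreliable $< 0.14$ --- so every score
falls in exactly one class. A species with negative raw RF
$R^2$, or ModRel below 0.14, is withdrawn.

**Range codes** classify each species from the inventory side: narrow (N)
if occupied cells cover < 10% of the study area (true cell areas), else
wide (W); dense (D) if $\ge$ 40% of plots in occupied cells report the
species, else sparse (S); high (H) if mean IV where present is $\ge$ 6.0,
else low (L); an X marks withdrawal. "Mean IV where present" is averaged
over plots; a cell-level variant would be a one-line change and the
plot-level reading is used because detection is a plot-level event.

**Predictor importance across species** (`variable_importance_index()`)
averages three 0--100 min--max normalized scores per predictor: summed
importance scores, summed reciprocal ranks, and the frequency of top-ten
appearances. Within-species rank ties share their average rank so that
identically important predictors receive identical indices.

## The synthetic study system

So that every stage is testable without access to a real inventory
database, the package ships a generator that emulates the *structure* of
the problem with known ground truth:

* **Covariates** are stationary Gaussian random fields (squared-
  exponential covariance, random-Fourier-feature approximation with 256
  features) plus a weak low-order polynomial trend, standardized to mean 0
  and SD 1 over the extent. Defaults: a 300 x 300 km extent, 12 surfaces,
  50 km correlation length --- large enough for several hundred cells,
  small enough that every test regenerates its data in seconds.
* **Plots** follow homogeneous Poisson processes with region-specific
  intensities; the default scenario uses a densely inventoried half
  (4 plots per fine cell) and a sparse half (0.3), which makes the hybrid
  lattice genuinely mixed: the dense half refines, the sparse half stays
  coarse.
* **Species** have Gaussian niche responses: expected IV is `max_iv` times
  a product of Gaussian kernels in the driving covariates, zeroed below an
  occupancy threshold (default 1 IV unit, producing the zero inflation
  typical of range boundaries), with Gaussian noise (default SD 3 IV
  units) added at occupied plots and clipped to [0, 100].
* **Tallies** are constructed so the arithmetic is exact: each plot holds
  1,000 stems and 10 m² of basal area in total, the focal species gets
  `round(10 * IV)` stems and `IV/10` m², and a single background species
  pool takes the remainder --- so `plot_importance_value()` recovers the
  intended IV to within 0.05 and per-plot closure holds identically. With
  several species, intended IVs are rescaled proportionally on the rare
  plots where they would sum above 100.

What the generator does *not* emulate --- and what passing tests therefore
do not establish about real inventories --- includes coordinate fuzzing and
plot swapping, uneven inventory cycles, subplot geometry and
expansion factors, covariate collinearity structure of real climate/soil
stacks, and non-Gaussian (skewed, bimodal, interaction-driven) niche
responses. The generator validates the machinery and the recoverability of
known signal, not the ecology of any real species.

## Problem sizes and numerical choices

The test suite fits forests of 101--1,001 trees on landscapes of roughly
160--400 km sides (a few hundred to ~1,500 cells, ~1,000--3,500 plots),
sizes chosen so the full suite completes in a few minutes while leaving
the parameter-recovery experiments enough cells (>= 400 training cells)
to be meaningful. Other numerical conventions:

* importance ranks break ties by predictor name, so rankings are
  deterministic permutations;
* per-tree predictions are clipped at 0 to remove $-10^{-16}$
  floating-point residue from averaging zeros;
* every stochastic step takes an explicit seed and derives any internal
  seeds from it; there is no hidden global state, and regenerating any
  synthetic object with the same seed is bit-identical;
* the pipeline writes outputs through a staging directory that is
  promoted only on success, and its manifest records a hash of the
  scientific parameters (not file paths), so reruns with the same
  configuration and seed are byte-identical.

## Known limitations

* The evaluation of FK and TSS on training-eligible cells only (the cells
  with observed data) means reliability statements do not cover the
  imputed portion of the map; confidence values are the per-cell
  diagnostic there.
* The literal outlier rule can remove a large fraction of occupied cells
  for species with compact IV distributions; users modeling such species
  should consider the Tukey variant consciously.
* Min--max normalization ties every species' ModRel to the best and worst
  species in the *same run*, so scores are comparable within a run, not
  across runs with different species sets.
* The lattice supports exactly two levels; deeper nesting would require
  extending the refinement pass.
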