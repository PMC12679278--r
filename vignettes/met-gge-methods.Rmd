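---
title: "Methods: multi-environment trial analysis with metgge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment trial analysis with metgge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgge)
```

## The problem

Plant breeders evaluate candidate genotypes in several locations before
recommending them, because genotype-by-environment interaction (G×E) can
reorder genotypes between sites. A multi-environment trial (MET) asks
three questions at once: which genotypes combine high mean performance
with stability; which test locations discriminate genotypes while
representing the target region; and whether the region splits into
mega-environments, each with its own winning genotype. `metgge`
implements this workflow for balanced trials, with a simulator that makes
every stage testable against known truth.

## Data model

The canonical object is a long table of plot records — one row per
(genotype, environment, replicate) with numeric trait columns
(`met_dataset`, `read_met_csv`). Balance (equal replicate count in every
cell) is checked by `validate_balance` and is a hard requirement for
ANOVA and the GGE engine: the methods below are derived for the balanced
layout, and imputing missing cells would silently change the estimand, so
unbalanced data is an error rather than a warning. Labels are compared
case-sensitively after whitespace trimming; trait values must be finite.
`to_two_way` collapses replicates into the genotype × environment table
of cell means that the GGE model decomposes.

## ANOVA, percent contribution and variance components

`met_anova` computes the definitional balanced-layout sums of squares
for Environment, Genotype, G×E and Error, and verifies their additivity
against the total at 10⁻⁸ relative (an internal invariant, also
cross-checked against `stats::aov` in the tests). With one replicate the
error stratum has zero degrees of freedom and is omitted.

`percent_contribution` reports each non-error source as a share of the
summed *mean squares*, 100·MSₛ/(MS_E + MS_G + MS_GE). The more common
convention is a share of the sums of squares; both are available
(`method = "ss"`), but the mean-square share is the default because it is
the convention under which the bundled grasspea trial's published
percentages reproduce exactly. The two differ because the three sources
have very different degrees of freedom.

`variance_components` inverts the expected mean squares of the balanced
random model (σ²_err = MS_err, σ²_ge = (MS_GE − MS_err)/r,
σ²_g = (MS_G − MS_GE)/(e·r)). Method-of-moments estimates can be
negative in small trials; they are truncated at zero and flagged, the
standard practice.

Two heritability routes are offered and deliberately kept distinct. The
genetic-parameter table (`genetic_parameters`) takes σ²_g, h² and the
mean as *inputs* and derives the phenotypic variance as σ²_p = σ²_g/h²,
which keeps GCV = 100·σ_g/ȳ, PCV = 100·σ_p/ȳ, GA = k·h²·σ_p and GA%
self-consistent with whatever heritability the analyst trusts. The
ANOVA-based estimator h² = σ²_g/(σ²_g + σ²_ge/e + σ²_err/(e·r)) is
available separately (`heritability_anova`) and clearly labeled: for the
bundled trial the two routes do not agree for every trait (the published
maturity σ²_g is not recoverable from the published mean squares at all,
whose method-of-moments estimate is negative), so the package reports
rather than reconciles. The selection intensity defaults to k = 2.06,
the standard value at a 5% selected fraction, and is a plain argument.

## The selection index

The base linear phenotypic selection index scores genotype i as
Iᵢ = Σₜ wₜ·yᵢₜ. Default weights are 1 per trait on raw scales — the
classical base index — because any other weighting is an economic
judgement the caller must make explicitly (traits where smaller is
better, such as days to maturity, belong with negative weight; an
optional z-scoring puts traits on comparable scales first). The bundled
trial publishes a per-genotype index column whose weighting cannot be
reconstructed from its printed trait means; that column is therefore
shipped as *data* in the fixture, not claimed as a reproduction target.
Because the index is linear, `add_selection_index` computes it per plot
record and lets replicate averaging commute, so the index flows through
`to_two_way` and the GGE engine like any trait.

## The GGE engine

Environment-centering subtracts each location's column mean from the
two-way table, removing the grand mean and environment main effects and
leaving genotype main effect plus interaction — the only two sources
relevant to genotype evaluation. No column scaling is applied (the
engine operates on the trait's own units). The SVD of the centered table
gives Yᵢⱼ − μ − eⱼ = Σₙ λₙ γᵢₙ δⱼₙ; biplot-derived summaries use the
first two axes (the rank at which the planted-crossover simulations are
exact by construction), while all axes are retained for diagnostics and
the full-rank reconstruction test.

**Singular value partitioning.** Genotype-focused SVP (scores U·Λ, V)
preserves Euclidean geometry among genotypes and is used for the
mean-vs-stability and which-won-where views; environment-focused SVP
(U, V·Λ) preserves it among environments and is used for environment
evaluation. Variance explained per axis, λₙ²/Σλ², is SVP-invariant.

**Sign convention.** The SVD determines each axis only up to sign. Each
axis is oriented so the sum of its environment loadings is nonnegative
(ties broken by the first nonzero loading), so repeated runs and
permuted inputs produce the same plot rather than a mirror image.

**AEC views.** The average-environment axis (abscissa) is the normalized
mean of the 2-D environment scores; the ordinate is its 90° rotation.
Genotype projections on the abscissa proxy mean performance, signed
perpendicular projections proxy instability, and the ideal genotype sits
at (max projection, 0); genotypes are ranked by Euclidean distance to
it. An average environment at the origin (e.g. a perfectly balanced
crossover pattern, or an all-constant table) makes the frame undefined
and is a flagged degenerate case, skipped by the pipeline rather than
fudged.

**Environment evaluation.** An environment's vector length is its
discriminating power; the cosine of its angle with the abscissa is its
representativeness. The default desirability combines them as their
product — the projection onto the average-environment axis — which is
the standard combination in the GGE literature; a rank-sum alternative
is selectable. The bundled trial's published desirability column is not
exactly reproducible from its own printed length/cosine columns, so no
fixture assertion is made on it.

**Which-won-where.** The convex hull of the 2-D genotype scores is
traversed counter-clockwise; the outward normal of each hull edge,
drawn as a ray from the origin, separates the normal cones of the two
adjacent vertices. A vertex's sector is therefore the set of directions
in which it maximizes the inner product with any environment vector, so
sector membership *is* the winning-genotype relation — this equivalence
with brute-force argmax over all genotypes is the engine's central
correctness property and is tested on batches of random instances. An
environment direction exactly on a boundary ray is assigned to the
counter-clockwise sector and flagged; an environment at the origin is
unassignable and flagged. Environments sharing a sector form a
mega-environment. Because the centered matrix has zero column sums, the
genotype scores always average to the origin, which keeps the origin
inside the hull.

**Ward clustering.** Genotype (or location) grouping uses Ward's
minimum-variance criterion on Euclidean distances of z-scored features,
via `stats::hclust(method = "ward.D2")`; the tests verify from scratch
that its merge heights satisfy height² = 2·ΔESS, the Ward criterion.

## Validation harness

`compute_metrics` implements the six regression metrics exactly as
defined above each test: R², RMSE (square root of the mean squared
error — the dimensionally consistent reading), MAE, MAPE (percent),
MSLE (natural logarithm of value + 1) and MedAE. Inputs that make a
metric undefined (a zero observation for MAPE, values ≤ −1 for MSLE,
constant observations for R²) yield `NA` plus a flag for that metric
only. `loo_cv` is plain leave-one-out: deterministic folds, model seed
re-applied before each fit so stochastic learners reproduce.
`grid_search` exhaustively evaluates a hyperparameter grid under LOO-CV
and picks the best cell by one declared metric (maximize R², minimize
the rest), ties to the earlier grid row.

Learner families are consumed through a minimal fit/predict contract:
the grand-mean baseline and an OLS fit (both useful as analytic
oracles), a random forest (`randomForest`) and a single-hidden-layer
perceptron (`nnet`, with internal feature/target standardization and
linear output). The harness is the authored, tested surface; the
learners' internals are the established implementations. The default
feature encoding for trial data is one-hot genotype + environment
indicators — an explicit design choice of this package, since no
canonical feature construction exists for trait prediction from trial
structure alone.

## The simulator

`simulate_met` draws Y = μ + G + E + GE + ε with independent normal
effects at configurable variances. Defaults describe a 64-genotype ×
4-location × 2-replicate seed-yield trial on the kg/ha scale
(μ = 1233.74, σ²_g = 16536.58, σ²_ge = 95370.46, σ²_e = 271165 from the
spread of the four location means, σ²_err = 27988 from a 13.56% plot
CV) — the scale of the bundled grasspea trial, chosen once so that
recovery tests run under realistic signal-to-noise. Effects are *not*
sum-to-zero constrained by default (estimators must absorb sampling
deviation, as with real data); a `sum_to_zero` flag enables the
constrained version for exact small-sample checks.

With a crossover specification, the interaction is replaced by a rank-1
product of standard-normal genotype loadings and group-signed
environment loadings, rescaled so the mean squared interaction equals
the requested σ²_ge exactly. Rank-1 structure means the 2-axis GGE
representation is exact by construction and the winning-genotype
partition equals the planted grouping (`plant_crossover_truth`) whenever
noise is negligible — the ground truth the engine's recovery tests use.

What the simulator does *not* emulate: incomplete-block (alpha-lattice)
field structure, spatial trend, non-normal errors, multi-trait genetic
correlation, or year effects. Tests passing on simulated data therefore
validate the estimators and geometry under the stated model, not
robustness to field artifacts.

## Numerical choices and problem sizes

- ANOVA additivity is enforced at 10⁻⁸ relative; reconstruction and
  geometry tests assert at 10⁻¹⁰; boundary detection in sector
  assignment uses a 10⁻⁹ angular tolerance.
- Monte-Carlo recovery checks use 200 replicates of the 64 × 4 × 2
  layout and a 3-standard-error band around the truth — wide enough to
  make false alarms rare, tight enough to catch estimator bias.
- Property batches use 100 random 10 × 4 instances for sector-winner
  equivalence and 300 random vector pairs for metric equivalence; these
  sizes give broad coverage while keeping the default test run fast.
- Negative variance components truncate to zero with a warning; ties in
  grid search resolve to the earlier cell; hull traversal order and axis
  signs are fixed as described so all outputs are bit-reproducible under
  a fixed seed.

## Known limitations

Only balanced trials are supported; there is no REML route for
unbalanced or incomplete-block data. The GGE engine is strictly 2-D for
its derived views (higher axes are diagnostic only). The published
trait-by-location table behind the bundled trial's biplot was never
released, so the fixture checks cover the ANOVA/genetics stage, while
the GGE stage is validated by construction against simulations. The
published selection-index weighting and desirability rule are likewise
unrecoverable and are treated as data, not targets.
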