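---
title: "Methods: bias-aware comparison of sparse methylation signals"
author: "methagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias-aware comparison of sparse methylation signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methagg)
```

## The problem

Metaplot comparisons of DNA methylation across functional boundaries
(intron-exon junctions, 5'UTR-coding starts, CpG-island edges) average
per-CpG bisulfite rates at each distance from the boundary and compare the
resulting profiles. Because a position can only carry signal where a CpG
dinucleotide survives, and because deamination preferentially removes CpGs
from constitutively methylated, weakly selected regions, the missing-data
pattern is coupled to the very quantity being averaged. Aggregate (column)
averages and regional (row) averages can then disagree arbitrarily — a
Yule-Simpson effect — and a "step" in the metaplot across a boundary can be
a pure artifact of differential CpG depletion.

`methagg` represents each side of a boundary as an *aggregation matrix*
(regions x relative positions, `NA` where no CpG exists) and provides:

1. the three averaging statistics `C` (mean of column averages, the
   standard %mCG metaplot value), `R` (mean of row averages) and `M`
   (grand mean), plus the row-level count-mean correlation `r`;
2. a randomization diagnostic for the presence of the effect;
3. Paired Region Averaging, a non-parametric correction;
4. COMPARE, a per-column logistic-regression matrix completion that infers
   a methylation *tendency* at every cell;
5. simulators with known ground truth, including a deamination-coupled
   generator and a deterministic 12-region worked example
   (`fig1_pair()`, left side `C = 1/3, R = 2/3, M = 1/3`, right side
   `C = R = M = 2/3`, with zero true cross-boundary difference).

```{r}
pair <- fig1_pair()
summary_stats(pair$left)
summary_stats(pair$right)
paired_region_averages(pair)$mean_difference
```

## Averaging statistics and their conventions

Rows (columns) with no observed cell carry no mean and are excluded from
`R` (`C`) and from `r`; this changes the effective `n` and is therefore
stated explicitly here. On a complete matrix `C = R = M` to machine
precision. The correlation `r` uses the observed-site *count* per row, not
the observed fraction. `column_profile()` reports the per-column average
and its backing count, with an optional minimum-observation gate
(`min_obs`, default 1 for description; inference uses 10, see below) and
optional fixed-width binning (default: site-specific).

### Witness construction

That `C`, `R` and `M` are mutually unconstrained is demonstrated
constructively: `witness_matrix(r, c, m)` returns a matrix realising any
rational triple in (0, 1). Two closed-form families are searched over
integer shape parameters:

* *singles + mixed row* — `k` single-cell rows in column 1 plus one fully
  observed row `(y, z, ..., z)`. For fixed shape `(k, m)` the three cell
  values solve a linear system exactly; the balancing cell `y` has an O(1)
  feasibility window in `k`, located by root finding and scanned over
  nearby integers. This family covers targets with `m` between `r` and
  `c`.
* *diagonal + stack + block* — a diagonal of single cells (each lifts one
  row *and* one column mean at the cost of one observed cell), a
  one-column stack (breaking row/column symmetry) and a dense constant
  block (dominating the cell count, hence `M`). The three values solve a
  3x3 linear system per shape; shapes come from a first-order sizing
  heuristic plus a coarse log-grid. This family covers `m` outside
  `[min(r, c), max(r, c)]`.

Transposition (swap `r`, `c`) and value complementation (`1 -` targets)
reduce every regime to the two families. Because values are solved
algebraically once the integer shape is fixed, achieved statistics are
exact to floating-point rounding (~1e-16), far inside the 1e-9 acceptance
band. Extreme targets (both `r` and `c` near one bound with `m` near the
other) genuinely require large witnesses (up to roughly 7000 x 7000 inside
the default `max_dim = 10000` cap); the construction errs with a
suggestion to raise the cap if no feasible shape fits.

## The randomization diagnostic

`shuffle_pair()` permutes the observed values of each concatenated
left||right row uniformly over that row's observed positions, leaving the
mask untouched, so both sides of every boundary share one methylation
tendency by construction. `randomization_test()` repeats this and examines
the null distribution of the %mCG step `C_right - C_left`. A null-step
distribution displaced from zero is the signature of methylation-coupled
missingness; an observed step compatible with the null carries no evidence
of a true difference. The two-sided empirical p-value uses the add-one
estimator `(1 + #{|null| >= |obs|}) / (n_reps + 1)` (the source analyses
assessed the shuffled profiles visually; the numeric step statistic and
its p-value are this package's formalisation). Per-replicate seeds derive
from one master seed by a counter scheme, so an entire run is reproducible
from a single integer.

One statistical subtlety: for a single finite dataset the null-step mean
conditions on the realised mask and fluctuates around zero at the mask
sampling scale, which is much larger than the within-dataset shuffle
standard error. Calibration statements about uncoupled missingness are
therefore Monte-Carlo statements over independently generated datasets,
and that is how the test suite and acceptance script phrase them (250
simulated pairs x 4 shuffles).

## Paired Region Averaging

`paired_region_averages()` computes per-region means on each side within a
window of boundary-adjacent columns (100 bp is the conventional window for
UTR-coding analyses and 200 bp for intron-exon ones; both are arguments)
and discards regions lacking data on either side. The exclusion step is
the correction: retained regions contribute one mean per side regardless
of CpG counts. The result deliberately carries a notice that absolute
tendencies are not estimable this way — exclusion biases the retained set
toward CpG-rich (less methylated) regions — only the relative comparison
is. `compare_paired()` applies a two-sided rank test to the retained mean
vectors: the two-sample rank-sum (Mann-Whitney-Wilcoxon) test by default,
with the paired signed-rank variant offered because the design is
intrinsically paired and either choice is defensible. Small samples
(`choose(2n, n) <= 1e5`) use an exact, tie-robust permutation enumeration
written for this package (the standard exact algorithm is unavailable
under ties); larger samples use the normal approximation with continuity
and tie correction. An all-zero-difference signed-rank comparison returns
`p = 1` with a degeneracy flag.

## COMPARE

For every cell `(i, j)`, three leave-one-out features summarise the rest
of row `i` (or its restriction to a user-chosen block of columns centred
on `j`, for long or heterogeneous regions): `B` (rest-of-row empty), `X`
(rest-of-row mean rate, 0 when `B = 1`), `Y` (rest-of-row missing
fraction). Each column `j` with at least `min_obs = 10` observed cells
gets its own logistic model

    M_ij = 1 / (1 + exp(-(b_j B_ij + x_j X_ij + y_j Y_ij + z_j)))

fitted on the column's observed cells. Numerical choices:

* **Fractional-response likelihood.** Bisulfite rates in `[0, 1]` enter a
  cross-entropy (quasi-binomial) objective directly, unweighted by read
  coverage; coverage weighting is exposed as an option in `fit_column()`.
* **Ridge.** An L2 penalty (default 1e-6) on `(b, x, y)` — never the
  intercept — guarantees finite coefficients on separable or collinear
  columns (`B` is often constant within a column).
* **Optimizer.** Penalized IRLS with step halving, convergence at 1e-8
  relative change in the objective, at most 100 iterations, and a BFGS
  fallback; non-convergence is an error naming the column.
* **Predictions** are evaluated at *every* cell of fitted columns,
  observed ones included, and clamped to the open interval (0, 1); a
  `keep_observed` flag substitutes measured values at observed cells for
  users who prefer completion-only output.

`cross_validate()` splits each fittable column's observed cells into ten
folds (assignment seeded per column from one master seed), predicts each
fold from the others, and pools all (observed, inferred) pairs. Both
coordinates carry error, so accuracy is summarised by the first principal
component of the centred, *unstandardised* pairs (total least squares):
its slope, and the variance explained defined as one minus the
perpendicular sum of squares over the total — the eigenvalue ratio
`lambda_1 / (lambda_1 + lambda_2)`. That definition of "variance explained
relative to a random line" is this package's formalisation and is labelled
as such in output. Folds that would leave fewer than `min_obs` training
points skip their column with a warning.

## Simulators as study conditions

The generators define the conditions under which the package's claims are
tested; their defaults are fixed once and documented here.

* `fig1_pair()` — the deterministic worked example above.
* `equal_tendency_null()` — the row-shuffle null (delegating to
  `shuffle_pair()`), plus a `joint` flag that permutes mask and values
  together (equal selection *and* equal methylation), a variant described
  only informally in the source material.
* `differential_simulation()` — binarizes each coupled row by its joined
  mean (ties at 0.5 go to methylated), turns a fraction (default 5%) of
  methylated rows differential by zeroing their left side, and optionally
  substitutes the three boundary-adjacent columns by their neighbours.
  Selection counts round to the nearest integer with a minimum of one
  whenever the fraction is positive. With 64% of regions methylated the
  5% selection yields 3.2% differential regions overall.
* `deamination_pair()` — the ground-truth generator: `n = 500` regions,
  `m = 20` columns per side, `p_methylated = 0.64` (the methylated share
  consistent with the 3.2% figure above), per-cell observation densities
  0.8 (0.1 on the methylated left side in the coupled regime, a 8:1
  depletion of the kind deamination produces), truncated Gaussian rate
  jitter with sd 0.05 (small enough never to flip a binarized class), and
  an optional true tendency step on the right side. These values are the
  package's standing study conditions, not tuning knobs.

The recovery fixture for the logistic fitter draws responses as binomial
read fractions at coverage 25 — typical whole-genome bisulfite depth and
consistent with the fractional-response likelihood.

## What the tests show, and what they cannot

Simulated regions are exchangeable, tendencies are near-binary, and
missingness is independent across cells given the region class. Real
methylomes have autocorrelated methylation along the genome, coverage
heterogeneity, partially methylated domains and annotation error; none of
these are emulated. Passing tests therefore demonstrate correctness of
the algorithms and their calibration under the stated conditions — they do
not certify effect-size estimates on any particular genome. The
quantities published for real human data (junction-table statistics,
discarded-junction counts, corrected differences) require the original
bisulfite calls and annotations; the pipeline emits exactly those
statistic types when pointed at such inputs, which the end-to-end test
exercises on synthetic files.

Problem sizes used by the test suite and acceptance script: 100 witness
triples; 250 x 4 randomization replicates at `n = 200` plus one
1000-replicate coupled test at `n = 500`; recovery at 5000 observed cells;
100 de-biasing seeds at `n = 300`; 1000 rank-test calibration replicates
at `n = 500`.

## Known limitations

* The witness search is heuristic beyond its two families' proven
  coverage; a failure errs rather than returning an approximate witness.
* COMPARE's features are row summaries only; covariates such as local CpG
  density or sequence context are out of scope.
* The CLI writes site-resolution TSV profiles; plotting is left to the
  caller.
* Significance for COMPARE-corrected comparisons is offered as rank tests
  on completed row means — a post-hoc choice, labelled as such, since the
  original analyses do not specify one.
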