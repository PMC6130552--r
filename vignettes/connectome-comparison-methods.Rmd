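---
title: "Methods: two-group connectome comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-group connectome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fadconn` implements a complete two-group comparison of brain connectomes —
functional networks from region-level BOLD-like time series and structural
networks from tractography streamline counts — of the kind used to contrast
a transgenic disease model against nontransgenic controls with very small
samples (four animals per group). This vignette documents the models, the
tunable parameters, the numerical choices, and what the bundled synthetic
cohorts can and cannot establish.

## Connectome construction

**Functional.** Edges are Fisher r-to-z transformed Pearson correlations
between region time series, `z = atanh(r)`. Negative edges are set to zero:
networks of negative correlations have qualitatively different topology
from positive-correlation networks and mixing the two corrupts every
metric downstream. Correlations are clipped to `|r| <= 1 - 1e-7` before the
transform so that duplicated or near-duplicated signals yield a large
finite weight instead of infinity.

**Structural.** A region pair counts as connected when at least 3
streamlines join it — an inclusive threshold ("at least") that suppresses
false-positive streamlines — and each surviving edge is weighted by the
pair's mean fractional anisotropy (FA). Weights are then scaled to (0, 1]
by dividing by the subject's maximum surviving weight. We deliberately use
max-scaling rather than min–max affine scaling: affine scaling would map
the weakest present edge to exactly 0, conflating "weak connection" with
"no connection". Scaling is per subject by default (`scale = "subject"`);
whether a cohort-level scaling is preferable is genuinely open, so the raw
option (`scale = "none"`) is kept for callers that want to scale across
subjects.

## Density thresholding and the AUC

Proportional thresholding at density `d` keeps the `floor(d * N(N-1)/2)`
strongest edges. Ties are broken by a stable sort on weight (descending)
then (row, column) order, making thresholded networks identical across
runs and platforms; edge sets are nested across densities by construction.

Because a single threshold is arbitrary, metrics are computed across a
density grid (step 0.01, which makes the conventionally reported densities
0.24, 0.34, 0.40, 0.50 exact grid points) and summarized by the
trapezoidal area under the metric–density curve (AUC). The analysis range
runs from the **minimum connection density** — the smallest grid density at
which *every* subject's network is a single connected component, the
standard usage in the AUC literature (the term is used loosely elsewhere) —
to the last density with small-world organization, capped at 0.5, beyond
which networks are dominated by weak, likely spurious edges. The
small-world boundary uses the group-mean sigma by default (`sw_rule =
"mean"`); a stricter every-subject rule (`"all"`) is available, since
published analyses are often ambiguous about which was used. When the two
group-mean sigma curves cross, the crossing density splits the range into
two windows that are tested separately in addition to the full range.

## Graph metrics and normalization

Weighted path lengths use the standard `length = 1/weight` mapping;
weighted clustering uses Onnela's geometric-mean triangle intensity on
max-normalized weights (the connectomics toolbox default — note that
igraph's built-in weighted transitivity is Barrat's formula, which is why
the Onnela form is implemented here). Modularity uses seeded Louvain with
100 restarts, reporting the maximum-Q partition; restarts tame the
algorithm's stochasticity enough that a single reported partition is
meaningful. Normalized metrics divide by the mean over 20 Maslov–Sneppen
degree-preserving rewired nulls (10 attempted swaps per edge); for
weighted networks the topology is rewired first and the original weight
multiset reassigned in random order, preserving both the degree sequence
and the weight distribution exactly. Small-worldness is `sigma =
gamma/lambda`, with `sigma > 1` the small-world criterion, applied
strictly (a subject at exactly 1 is excluded).

Disconnected thresholded networks (below minimum connection density) have
path length averaged over finite pairs only, with a warning; the pipeline
avoids the case by construction.

## Group inference

- **Windowed-AUC permutation test**: the statistic is the difference of
  group-mean AUCs; subject labels are shuffled (never individual
  densities, preserving within-subject dependence across the grid). With
  4 + 4 subjects all 70 assignments are enumerated and the p is exact;
  otherwise 2,000 Monte-Carlo draws with the `+1/(n+1)` correction so p is
  never zero. The group difference of means (not medians) is used, as in
  the AUC methodology this follows.
- **Weighted networks**: each subject's unthresholded network has its own
  density, so metrics are compared with the linear model
  `y ~ group + density` and the two-model F test for the group term
  (`df = n - 3`). Density here is the fraction of nonzero edges of the
  weighted connectome.
- **t tests** are pooled-variance by default (Welch by flag); coupling
  correlations are Fisher-z transformed first.

## Hub profile: power-law fitting

Heavy-tailed degree distributions indicate hub organization. Fitting
follows the standard MLE recipe: the exponent by maximum likelihood (exact
zeta-normalized discrete MLE via a Hurwitz-zeta evaluation, or the
closed-form continuous MLE), the lower cutoff `x_min` by KS minimization,
and goodness of fit by semi-parametric bootstrap (resamples drawn from the
empirical body below `x_min` and the fitted law above it, refit under the
same cutoff protocol). For weighted, unthresholded networks the fits use
node *strength* with the continuous MLE — the binary degree of a
near-complete weighted graph is degenerate at `N - 1`. An exponentially
truncated variant (`x^-alpha * exp(-rate x)`) is fitted by direct MLE with
numerical normalization. The between-group comparison is a label
permutation test on subject-level KS statistics; the original analysis
names only the fitting library, so this surrogate is documented as this
package's procedure, not asserted as the study's.

With a free cutoff, the bootstrap GOF has limited power against
exponential data — the fit can retreat into the far tail where any smooth
law fits a few hundred points. Misspecification checks therefore hold the
cutoff at the support edge (`xmins = 1`).

## Network-based statistic

Edge-wise pooled t statistics are thresholded at a primary `|t|` value and
the connected components of the suprathreshold graph scored by extent
(edge count) or intensity (summed suprathreshold `|t|`, more sensitive to
focal effects). Family-wise error control comes from the permutation
distribution of the maximal component score, with one label shuffle per
iteration reused across all edges so edge dependence is preserved. There
is no canonical primary threshold; `threshold = 3` is the default and is
always reported. Edge-wise FDR (Benjamini–Hochberg) is the focal-effect
alternative.

The FDR contrast is the one parametric procedure in the package: it
converts t to p through the t distribution, which requires approximately
normal edge weights. On bounded FA-like weights with 4 subjects per group
the far tail of that approximation fails badly enough that the
any-discovery rate can triple (the permutation procedures on identical
data remain exact). The calibration study therefore evaluates FDR on
functional (Fisher-z, near-normal) connectomes with 8 subjects per group —
the same size as the component-level power simulations — and at n = 4 the
edge-wise FDR output should be treated as descriptive.

## Structure–function coupling

Communication measures computed on the structural network serve as
regressors for functional connectivity, pair by pair, per subject:
weighted shortest path length and search information (the default set),
plus path transitivity, column-z-scored mean first passage time,
neighborhood overlap, and matching index (the full set). Search
information is the bits a memoryless random walker needs to follow the
shortest path (`-log2` of the product of step probabilities
`w_step / strength`); path transitivity averages the matching index over
all node pairs along the path; MFPT comes from the fundamental matrix of
the walk and is z-scored within target columns; neighborhood overlap is
formalized as the Jaccard index of binarized neighbor sets (the name is
used without definition in the literature this follows). Asymmetric
measures (SI, MFPT) are symmetrized by averaging the two directions before
entering the regression. Pairs with no structural path are excluded rather
than imputed; observed zero-FC pairs are kept by default (flag to drop).
The per-subject coupling statistic is the Pearson r between fitted and
observed FC over upper-triangle pairs; in-sample r of a 2-predictor
regression over 496 pairs has a null expectation near `sqrt(2/496) ≈ 0.06`,
which is why weak coupling settings are indistinguishable from zero at
small T. The all-measures model's in-sample r can never fall below the
default model's (nested least squares).

## Synthetic cohorts

The generator emulates the study design: 32 regions, 4 subjects per group,
450 functional volumes. Structural networks are Watts–Strogatz graphs
(ring lattice degree `k = 10`, rewiring `beta`) with Beta(9, 11) FA-like
weights (mean 0.45, spanning the realistic white-matter range) and
Poisson-distributed streamline counts (present edges at `3 + Pois(20)`,
plus ~5% of absent pairs given 1–2 spurious streamlines that the count
threshold must remove). `k = 10` puts the structural density at 0.32 so
that proportional thresholding across the analysis densities actually
selects edges; a sparser lattice would make every threshold above ~0.2 a
no-op. Functional series follow a stable first-order diffusion,
`x_t = c * W_rn x_{t-1} + noise`, with `W_rn` the row-normalized structural
weights — the simplest process with a tunable structure–function coupling
`c`, and explicitly a statistical stand-in, not a hemodynamic model.

The disease-like group differs in three ways, all density-matched so that
the density-covaried weighted analysis isolates organization effects:

1. **Higher rewiring** (`beta` 0.15 vs 0.05): degrades clustering,
   small-worldness, and modularity of the thresholded networks.
2. **Hub-incident weight deficit** (75% reduction on edges touching the 8
   highest-degree nodes): concentrates weak edges around former traffic
   hubs, which raises the *null-normalized* weighted path length — the
   rewired-and-weight-shuffled nulls can route around weak edges that the
   real network cannot. A within-module weight deficit, the other natural
   candidate (and available via `deficit_scope = "within"`), empirically
   *fails* to raise normalized lambda at any tested setting because
   normalization absorbs it; hub-targeting is also the mechanism actually
   proposed for AD-like degeneration, which is why it is the preset.
3. **Stronger coupling** (`c` 0.9 vs 0.2): the disease group shows
   structure–function hyper-correlation. The pair was calibrated so that
   the 4 vs 4 Fisher-z t test detects the difference with power above 0.8
   — the defining property of the "large" preset; at a milder (0.3, 0.8)
   pair the per-subject coupling r is too variable across random
   topologies for reliable detection at this sample size.

What the synthetic cohorts do **not** emulate: hemodynamics and scanner
noise, physiological artifacts, spatial embedding of regions, realistic
module composition (modules are contiguous lattice blocks), or
between-subject anatomical variability beyond generator randomness. A
passing recovery study shows the pipeline detects effects of this kind at
this size — not that the in-vivo effects are of this kind.

## Validation studies and problem sizes

Two simulation studies ship with the test suite, both with 200 replicates
and per-test permutation counts reduced to 200:

- **Calibration**: on exchangeable null cohorts, the AUC permutation test
  (run on raw clustering curves — the permutation machinery is agnostic to
  which metric feeds it), NBS extent/intensity, and the power-law
  comparison keep type-I error within the binomial 95% interval of 0.05.
  Calibration cohorts use 8 subjects per group: a 4 vs 4 design admits only
  35 two-sided label assignments, capping the achievable type-I error of
  *any* permutation test at 2/70 ≈ 0.029 (measured rates at 4 vs 4 are
  0.015–0.035 — conservative by construction, not by defect). The NBS
  calibration uses a primary threshold of `|t| = 2` so the null
  suprathreshold graph is dense enough for component sizes to vary; at
  `|t| = 3` the extent score ties at 1–2 edges and the test is again
  structurally conservative. The parametric FDR contrast is calibrated on
  the functional connectomes of the same 8-per-group cohorts, as discussed
  above.
- **Recovery**: under the large-effect preset, power above 0.8 for every
  planted deficit — gamma, sigma, and Q via upper-window AUC tests
  (densities 0.34–0.5 on a 3-point grid; thresholded networks are
  identical across this window for the default generator because the
  parent density is 0.32, so the coarse grid changes nothing), lambda via
  the density-covaried model on weighted networks, and coupling via the
  Fisher-z t test. Louvain uses 5 restarts inside the simulations (100 in
  the reported analyses).

Numerical details fixed here: asymmetry tolerance 1e-8 on input matrices
(averaged; anything larger is an error, catching transposed or truncated
files); matrices written at 17 significant digits so round-trips agree to
1e-12; permutation ties counted with a 1e-12 relative epsilon; the
single-entry z-score column (N = 2 only) defined as 0; region order is
never sorted — node identity is positional and must match across subjects.

## Reproducing the in-vivo numbers

The original study's per-animal weighted network matrices are distributed
as supplementary material with the article, not with this package.
`reproduce_study_results(data_dir)` recomputes the published quantities
(minimum connection densities, the functional path-length t statistic at
minimum density after small-world exclusion, weighted-structural F
statistics, coupling t statistics, and the count of subjects with
significant default-model coupling) from a directory holding those
matrices and a YAML manifest; see its help page for the expected layout.
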