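---
title: "Quantifying claw shape, function, and phylogeny with clawmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying claw shape, function, and phylogeny with clawmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

clawmorph implements, as one reusable pipeline, the quantitative toolkit
used to study the function and evolution of theropod manual unguals
(claws): sliding-semi-landmark geometric morphometrics, a class-3 lever
model of claw biomechanics, shape–function regression and group
comparison, and morphological maximum parsimony with consensus trees and
ensemble fit indices. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
conventions genuinely differ between toolchains.

```{r setup, message = FALSE}
library(clawmorph)
library(dplyr)
```

## Geometric morphometrics of ungual outlines

Each ungual is digitized in lateral view (proximal end left, dorsal up)
as an ordered set of 2-D landmarks. The scheme used throughout the
package and its synthetic generator has K = 16 points: 4 fixed anatomical
landmarks (claw tip, proximodorsal lip, proximoventral process, flexor
tubercle apex) and 12 semi-landmarks spaced along the dorsal and ventral
margins. Semi-landmarks carry no anatomical identity along the outline,
so their spacing is arbitrary; a slider table (`before`, `slide`,
`after`, 1-based, as in the morphometrics file conventions) declares
which points may slide and which outline neighbors define each point's
tangent chord. The readers accept any declared slider set rather than
hard-coding one, because fixed-landmark definitions are a property of the
digitization protocol, not of the method.

`gpa()` performs generalized Procrustes analysis in two phases:

1. **Superimposition.** Every configuration is centered and scaled to
   unit centroid size, rotated to the running consensus by the
   closed-form 2-D rotation (complex cross-product; reflections are never
   fitted, so left and right claws must be mirrored at I/O time, e.g.
   with `flip_y`), and the consensus is re-estimated until it moves by
   less than `tol` (default 1e-8, at most `max_iter = 100` outer
   iterations). The objective — the summed squared distance of all
   configurations to the mean shape — is non-increasing across these
   iterations (block coordinate descent), and is recorded in the result.
2. **Sliding.** Semi-landmarks then slide along their tangent chords,
   under either the minimum bending-energy criterion (default, the
   convention of the standard morphometrics toolchains) or the minimum
   Procrustes-distance criterion. Tangent directions are the chords
   through each semi-landmark's neighbors, re-estimated every iteration.
   Two numerical points deserve note. First, the slid positions are
   always re-derived from the *unslid* aligned configurations: sliding
   already-slid coordinates lets points creep along the outline — a
   near-null direction of the objective — and the consensus never
   settles. Second, the sliding loop terminates on stationarity of the
   Procrustes objective rather than on consensus displacement, because
   the outline parameterization leaves the consensus only weakly
   identified along the curve; a step that worsens the objective is
   reverted. Bending-energy sliding minimizes bending energy, not the
   Procrustes objective, so only the no-sliding and Procrustes-mode paths
   promise monotone objectives.

After convergence the aligned shapes are orthogonally projected onto the
tangent space at the consensus (standard before PCA), and the whole
solution is rotated into a canonical frame (consensus principal axes,
with a deterministic sign rule), which makes results invariant — to
machine precision — under arbitrary rotations, translations, and
rescalings of the input configurations.

`shape_pca()` eigen-decomposes the covariance matrix (divisor n − 1) of
the flattened Procrustes coordinates. Scores are in dimensionless
tangent-space units; at most min(n − 1, 2K − 4) components carry
variance. Because eigenvector signs are arbitrary, `orient_axes()` flips
each component so its scores correlate non-negatively with an orienting
statistic. The default statistic is each specimen's aspect ratio (square
root of the ratio of its two principal-axis variances), a scale-free
elongation proxy: an earlier candidate — the length of the longest
landmark chord — turned out to be confounded with centroid-size
normalization and could orient the elongation axis backwards. With this
convention, high PC1 reads as ungual elongation, making score signs
comparable across datasets. `tps_warp()` renders any position in the
score space as a thin-plate-spline deformation grid (kernel
r² log r) anchored on the consensus; affine displacements have exactly
zero bending energy.

## The lever model of claw function

The claw is modeled as a class-3 lever about the phalangeal joint
(fulcrum). With `a` the out-lever (fulcrum to claw tip), `d` the
in-lever (fulcrum to flexor tubercle), `theta` the angle of the flexor
tendon's pull to the out-lever line, and `delta` the angle between the
in-lever and the out-lever (angles in degrees in all files and
interfaces, radians internally):

* mechanical advantage `MA = sin(theta + delta) · d / a`, the fraction
  of input force delivered at the tip, maximal when `theta + delta = 90`
  and bounded by `d/a`;
* development of the flexor tubercle `DFT = h / b`, the perpendicular
  height of the tubercle apex over its base segment divided by the base
  length — a dimensionless proxy for flexor muscle cross-section, hence
  input force. The normalizer is the base-segment length; the published
  description of this ratio is ambiguous about the denominator, and this
  reading produces values in the printed 0.1–0.3 range;
* hypothesized output `= MA · DFT`, a dimensionless proxy for tip force.

Measurements can be supplied as a CSV table (validated:
`a, d, b > 0`, `h ≥ 0`, `0 < theta + delta < 180`) or derived from
designated landmarks with `measure_levers_from_landmarks()`, whose
`role_map` keeps the fulcrum and force-direction conventions explicit
because they belong to the measurement protocol. `theta` is measured
against the out-lever *line* (≤ 90°), so the sense of the force vector
does not matter. Lengths may be in any unit within a file — the three
scores are dimensionless — but shape data of mixed units are fine while
lever tables must be internally consistent.

## Shape–function statistics

`sma_fit()` fits the standardized major axis, the symmetric line-fitting
convention for structural relations: `slope = sign(r)·sd(y)/sd(x)`
through the centroid, with significance reported as the Pearson
correlation test (the convention of the standard SMA toolchain).
Residuals default to signed vertical deviations — matching how "residual
from the regression line" is read off such plots — with perpendicular
residuals behind a flag. `welch_test()` wraps the unequal-variance t
test; `group_summary()` gives boxplot five-number summaries using
linearly interpolated quartiles (type 7), documented because hinge
conventions differ. Tests are two-sided and uncorrected, mirroring how
such single comparisons are reported in this literature.

## Morphological parsimony

`read_character_matrix()` parses TNT `xread` and NEXUS CHARACTERS
matrices, with `?` missing, `-` inapplicable (scored as missing — the
standard non-hierarchical treatment), and bracketed polymorphic cells
with any-of semantics. Character indices are 1-based everywhere a user
sees them; TNT `ccode` blocks are 0-based on disk (translated at parse
time, `tnt_zero_based = TRUE` by default) and a sidecar `ordered =` /
`exclude =` argument can override the file.

Tree length uses Fitch set operations (bitmasks, vectorized across
characters) for unordered characters and Farris minimal-cost intervals
for additive ones. The interval pass is exact only when every cell's
state set is contiguous, so additive characters containing gapped
polymorphic cells (say `{0,2}`) are routed through an exact Sankoff
dynamic program, which also scores trees with polytomies (consensus
trees, collapse tests). Ensemble indices follow the classical
definitions: `CI = M/S` and `RI = (G − S)/(G − M)`, where `M` sums
per-character minima (for unordered characters with polymorphism this is
an exact minimal state cover; for additive ones the observed range) and
`G` sums star-tree maxima. Uninformative characters are included, as in
the conventional program defaults; `S = 0` reports `CI = 1` with an
explicit flag.

The search is the classical heuristic: random-addition Wagner builds
(each taxon inserted on the length-minimizing branch, ties broken by the
seeded RNG) refined by hill-climbing branch swapping over NNI, SPR, or
TBR neighborhoods, holding up to `hold` distinct equally parsimonious
trees per replicate and pooling across replicates. All randomness runs
through one seeded generator, so a seed fully determines the result. The
default desk-scale search is 100 replicates with hold 10 under TBR;
published analyses of this kind use 1000 replicates, which is a config
value, not a different algorithm. `strict_consensus()` and
`majority_rule_consensus()` (strictly-greater-than threshold, so a clade
in exactly half of an even tree set is dropped) are built from
bipartition counts. `collapse_zero_branches()` contracts branches whose
removal leaves tree length unchanged — the usual convention before
counting distinct most-parsimonious trees; because that count depends on
the collapsing rule, no tree count is treated as a checkable result
anywhere in the package.

## The synthetic-claw generator

The tests and the acceptance script run entirely on synthetic data with
known ground truth. `generate_claw()` builds an outline from two
circular arcs sharing the tip — dorsal margin from the proximodorsal lip
to the tip, ventral margin from the proximoventral corner — both
subtending `curvature` degrees, with proximal height equal to the
tip chord over `elongation`. Circular arcs were chosen over logarithmic
spirals because the lever geometry must be analytic: the tests need
exact expectations, not anatomical realism. A triangular flexor-tubercle
bump of height `tubercle_prominence × b` sits on the ventral margin at
an arc distance from the proximal end that scales with claw *depth*, not
claw length — as in real unguals, where the tubercle sits just distal to
the articular surface; this is what makes elongate claws have
proportionally short in-levers and hence lower MA. Lever measurements
come from the noiseless geometry, so `DFT` equals the prominence
parameter exactly and `MA` responds to elongation and curvature through
the geometry alone. Landmark noise is isotropic Gaussian, expressed in
Procrustes units (scaled by centroid size); along-curve noise is
expected to be absorbed by sliding, which is itself tested. Parameter
combinations whose margins meet are rejected as self-intersecting.

The group presets — basal (curvature 140°, elongation 1.6, prominence
0.30) and derived (curvature 100°, elongation 2.6, prominence 0.12) —
straddle the published DFT range for derived therizinosaurids
(0.11–0.13) and reproduce the direction of every published contrast:
derived claws score higher on the elongation axis and lower on MA, DFT,
and hypothesized output. Between-specimen variation is log-normal on
elongation and prominence with coefficient of variation `param_cv`
(default 0.15, a realistic within-group spread for linear proportions);
setting `param_cv = 0` and `landmark_noise_sd = 0` makes generation
fully deterministic given the seed.

`generate_character_matrix()` evolves unordered (uniform jump) and
additive (±1 step, reflected) characters along a known binary tree with
a per-branch change probability, masks cells to missing at a given rate
(fossil matrices are typically 20–60% missing), and records the true
number of changes per character. The optional `max_changes` cap
resamples characters exceeding it; with `max_changes = 1` matrices are
strictly homoplasy-free, so parsimony length on the true tree equals the
true change count exactly. The cap exists because an uncapped
low-rate process still produces occasional parallel changes whose
pattern admits a shorter explanation than the realized history, which
makes "search length equals true change count" false in a substantial
minority of replicates even at well under one expected change per
character; the capped process is the low-homoplasy condition the
recovery simulations are meant to probe.

What passing these simulations shows — and what it does not: the
generator produces smooth, complete outlines with isotropic noise and
character data evolved under the assumed models. Real fossil data add
taphonomic deformation, digitization bias, correlated characters, and
non-random missingness; the parameter-recovery results demonstrate the
pipeline's correctness, not robustness to those factors.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
ds <- generate_claw_dataset(
  claw_preset("basal", n_per_group = 6, seed = 1),
  claw_preset("derived", n_per_group = 6, seed = 2),
  seed = 42)

fit <- gpa(ds$landmarks, ds$sliders)            # bending-energy sliding
space <- orient_axes(shape_pca(fit))
glance(space)

scores <- claw_scores(ds$levers)
welch_test(scores, MA, clade_group)
group_summary(scores, DFT, clade_group)

joined <- inner_join(space$scores, scores, by = "specimen")
glance(sma_fit(joined, PC2, MA))
```

```{r phylo}
tr <- random_topology(8, seed = 3)
sim <- generate_character_matrix(tr, nchar = 60, change_prob = 0.1,
                                 max_changes = 1, seed = 5)
res <- branch_swap_search(sim$matrix, replicates = 5, hold = 10, seed = 9)
res
ape::dist.topo(ape::unroot(strict_consensus(res)), ape::unroot(tr))
```

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use deliberately small problem
sizes — 10–25 landmark configurations, 8–12 taxon matrices with 60–80
characters, 2–10 search replicates, 50–200 simulation replicates —
chosen so that the full battery of property checks, exhaustive-oracle
comparisons (all 105 six-taxon topologies; brute-force optimization over
all internal state assignments), and recovery simulations completes in
minutes on a laptop while still exercising every code path. Every
stochastic step flows through an explicit seed, and the pipeline runners
(`run_morphometrics()`, `run_phylogeny()`) write a manifest with the
seed and content hashes so a rerun with the same config reproduces
byte-identical tables and trees.

## Known limitations

* 2-D lateral-view landmarks only; no missing-landmark estimation, no
  weighted or robust Procrustes.
* The lever model is quasi-static and dimensionless; it ranks claws, it
  does not estimate forces in newtons.
* Comparative statistics are non-phylogenetic by design, reproducing how
  such contrasts are reported in the source literature; no PGLS.
* Parsimony only — no implied weighting, support resampling, or
  model-based inference — and most-parsimonious-tree counts are
  collapse-rule-dependent, so only lengths, indices, and consensus
  topologies are treated as results.
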