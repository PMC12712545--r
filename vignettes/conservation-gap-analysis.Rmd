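---
title: "Methods: multi-perspective conservation-gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-perspective conservation-gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapscape)
```

`gapscape` chains five analyses — habitat quality, carbon accounting,
species distribution ensembles, fragmentation, and simulated-annealing
reserve selection — into one seeded pipeline that flags persistent
conservation gaps: planning units repeatedly selected as irreplaceable
across modelled time periods yet lying outside existing reserves. This
vignette is the package's methodological account: the models, their
assumptions, the tunable parameters and why their defaults are what they
are, and what the synthetic test landscape can and cannot demonstrate.

## The spatial data model

Every layer is a `grid`: a numeric matrix (NA = nodata) with a square
cell size in metres and a top-left origin, north-up. The default cell is
1000 m, so one cell is 1 km² (100 ha) and magnitudes are commensurate
with provincial-scale studies. There is deliberately no reprojection or
resampling: all layers of an analysis must share one geometry, as they
would after a GIS pre-alignment step. The interchange format is the
plain-text ESRI ASCII grid, which round-trips bit-exactly for integer
layers and to full double precision for continuous ones; class-break
definitions travel as YAML.

Two classification primitives serve three downstream modules.
Equal-interval breaks grade habitat quality into five fixed levels on
[0, 1] (high 0.8–1 down to low 0–0.2). Natural-breaks (Jenks)
classification — used for carbon zones and suitability levels — is the
exact Fisher dynamic programme over the sorted values, not a k-means
heuristic, so breaks are deterministic and provably minimise
within-class sum of squares. Classification is half-open and
lower-inclusive (`[e_i, e_{i+1})`), with the global maximum closed into
the top class; the convention matters at the 0.8 boundary of the
high-value habitat mask and is stated once and tested.

## Habitat quality

Quality combines a per-class habitat score H_j in [0, 1] with
threat-driven degradation D through the half-saturation transform
Q = H_j (1 − D^z / (D^z + k^z)), z = 2.5. With `k = "auto"` the
half-saturation constant is half the maximum observed degradation, so
the most degraded cell sits at D = 2k and retains about 15% of its
score, and a cell at D = k exactly half. Degradation is the
weight-normalised sum over threats of the threat's distance-decayed
impact field times the land-use class's sensitivity S_jr, optionally
modulated by a per-cell accessibility grid. The impact of one threat at
a cell sums decayed source intensities within the threat's maximum
distance and divides by the number of contributing source cells, keeping
impact in [0, 1] regardless of how extensive the source is. Decay is
linear (1 − d/d_max) or exponential (exp(−2.99 d/d_max), ≈ 0.05 at
d_max); distances are Euclidean centre-to-centre in km.

The packaged threat parameterisation (cropland: weight 0.6, 1 km,
linear; construction: weight 1.0, 8 km, exponential; roads: weight 0.7,
2 km, linear) and the habitat/sensitivity table are literature-typical
stand-ins for an agricultural–forest mosaic; both are plain config
surfaces (`threats.yaml`, `sensitivity.csv`) and nothing downstream
depends on their particular values. Degradation is computed on every
cell, including zero-habitat classes — the habitat score, not a
degradation mask, is what zeroes quality on built-up land. Temporal
change compares per-cell quality between periods with a stable band of
±0.01 so floating-point churn is not counted as change.

## Carbon accounting

Each land-use class carries four pool densities (above-ground,
below-ground, soil, dead; t/ha) whose sum is the class density; the
landscape total is exact bookkeeping, Σ c_i × R_i over class areas in
ha. Cells are zoned into a dedicated zero-density class plus up to five
Jenks classes over the *distinct* positive densities — with six land-use
classes there are at most six distinct values, and when fewer than five
positive densities exist the zone count collapses gracefully rather
than fabricating empty classes. Zoning is on per-cell density, not
windowed totals: with one density per class the two differ only by a
relabelling, and per-cell zoning keeps zones interpretable as land-use
statements. The packaged density table uses literature-typical
magnitudes per class (woodland ≈ 212 t/ha total, cropland ≈ 115,
construction ≈ 41); it is a default, not a claim, and is overridable
via `carbon_density.csv`.

## Species distribution ensemble

Occurrences are cleaned by exact-duplicate removal and random spatial
thinning to a 1 km minimum separation (seed-reproducible). Predictors
are filtered by greedy elimination: while any pair of layers correlates
above |r| = 0.8, the member of the worst pair with the lower
point-biserial correlation against presence labels is dropped, so
collinearity resolves toward the ecologically more informative layer.

Two learners are built in. The surface-range envelope scores a cell by
the fraction of layers whose value falls inside the central 95%
presence interval. The ridge logistic regresses presence against 500
uniform background points on standardized layer values *and their
squares*: a linear-link learner cannot represent a unimodal niche at
all, and for a Gaussian niche the log-odds are exactly quadratic, so
the quadratic design is the statistically correct minimal form (it is
also what ecology's standard GLM-based SDM practice uses). The ridge
path is fitted with warm starts down to the target penalty
(λ = 0.01), which is numerically robust where a cold single-λ fit can
fail on near-separable data. Externally produced suitability rasters
can join the ensemble after range and alignment validation, so learners
not implemented here (boosting, random forests, MaxEnt) are first-class
members rather than special cases.

Evaluation follows the presence/background convention: AUC by midrank
statistic, TSS maximised over the sorted unique scores (suitable means
score ≥ threshold), Kappa at the max-TSS threshold. Ties in the TSS
sweep break toward the lower threshold — the larger predicted suitable
area — which is the precautionary choice for conservation screening.
Members are refitted over ten 75/25 splits; a member's skill is its
mean TSS, members above 0.8 enter the ensemble, and weights are
TSS-proportional with Σω = 1. Averaging member skill over splits
(rather than pooling predictions) keeps each member's inclusion
decision interpretable. The ensemble surface — the weighted mean of
final full-data member predictions — is binarised at its own max-TSS
threshold, the above-threshold cells graded low/medium/high by Jenks,
and the per-species high classes stacked into a richness surface with
fixed bins (none / 1–2 / 3–4 / 5–6 / ≥7 species). Ensembling
probabilities first and binarising once avoids the vote-threshold
artefacts of binarising members individually.

## Fragmentation

Four metrics are computed per non-overlapping square window (default
20 × 20 cells) of a binary mask: patch count NP under queen
connectivity (the Fragstats patch rule), patch density PD per km²,
mean patch area, and the aggregation index AI = 100 g / g_max, where g
counts rook like-adjacencies and g_max follows the
largest-integer-square rule. The composite index is the equal-weight
mean of min-max normalised NP and PD and *inverted* normalised AREA_MN
and AI — the latter two fall as fragmentation rises, so inversion is
required for the composite to increase with fragmentation; this is the
one under-specified point of the formulation and is isolated in a
single function. Normalisation pools all windows of all periods
jointly, so period means are comparable on one scale; a metric constant
across every window carries no ordering information and its component
is pinned at the neutral 0.5 with a warning. Windowed evaluation (not
one landscape value) is what gives the index a geographic distribution;
window size is a config knob with the usual trade-off between spatial
resolution and patch-statistic stability. The same per-window metrics,
painted back to cell resolution for the woodland + grassland mask, are
the patch-structure covariates offered to the SDMs.

## Cost surface and reserve selection

GDP and a per-class land-use disturbance score combine through the
entropy-weight method: indicators are min-max standardised over cells,
converted to share distributions, scored by Shannon entropy, and
weighted by 1 − entropy (normalised). An indicator that is nearly
uniform over space carries little discriminating information and gets
little weight; a constant indicator gets exactly zero with a warning.
Min-max standardisation before the share step is the canonical recipe.
One consequence worth knowing: an exact duplicate of an indicator earns
its own full weight share (the method has no notion of redundancy), so
the duplicated signal's combined influence doubles — deduplicate inputs
rather than expecting the weights to do it.

Planning units are square grid blocks (default 10 × 10 cells; polygon
units would slot into the same structure). Unit cost is mean HDI;
feature amounts are exact cell counts of each feature mask; boundary
lengths come from shared cell edges, with edges facing nodata or the
grid exterior counted as outer boundary. Units more than half covered
by existing reserves are locked in. The objective is the classic
reserve-selection form: selected cost, plus BLM times the exposed
boundary of the selected set, plus per-feature shortfall penalties
SPF_f · base_f · max(0, (T_f − held_f)/T_f). The penalty scale base_f
is a greedy cost-to-meet-target estimate (cheapest units per unit of
feature until the target is met) computed once — the standard way to
put shortfalls on the cost scale. Targets default to 30% of each
feature's extent ("30 by 30"); SPF defaults to 5 and should be raised
for features whose targets must bind.

The annealer proposes single-unit flips, accepts improvements always
and deteriorations with probability exp(−Δ/T), cools geometrically
(0.999 per iteration, 10,000 iterations), auto-sets the initial
temperature to the 90th percentile of |Δ| over 100 random probes, and
finishes with greedy descent to a local optimum; everything is driven
by R's RNG so a seed fixes the run. Selection frequency (`ssoln`) over
100 independent runs measures irreplaceability; available units with
ssoln > 0.65 (strict) are gaps, and the intersection of gap sets across
periods gives the persistent gaps. BLM calibration runs a short
frequency analysis per candidate value and reports the cost-vs-boundary
trade-off; the suggested value is the knee (maximum perpendicular
distance to the chord) of the *best-run* curve — under a stochastic
solver the run means include local-optimum scatter that can mask the
trade-off, so the means are reported but the best-run columns carry
the signal.

## The synthetic landscape

The generator supplies every input the pipeline needs, with the
statistical structure the methods assume: low-pass-filtered Gaussian
surfaces with broad trends (lag-1 autocorrelation > 0.5, standardized),
a first land-use period carved from elevation and moisture with urban
kernels, later periods drawn cell-wise from a row-stochastic Markov
transition matrix, GDP as smoothed construction density times positive
noise (r ≥ 0.6), blob-shaped reserves covering 10% of cells, and a
one-cell-wide road polyline. Occurrences are drawn without replacement
with probability proportional to a product of Gaussian niche responses,
then jittered within cells so thinning has sub-cell structure to act
on; 40 records per species matches the "at least ~30" working rule for
presence-only modelling.

Species are parameterised as narrow-range specialists: niche breadth
0.35 sd per standardized layer, optima drawn with magnitudes in
[0.8, 1.4] away from the landscape-modal environment. That is the
ecological profile of the rare, protection-listed plants this kind of
analysis targets, and it is also what makes the TSS > 0.8 inclusion
bar meaningful at desk scale — a generalist whose suitable area covers
half the landscape cannot exceed TSS ≈ 0.6 under any model, not
because the model fails but because background points are then drawn
from suitable habitat. The defaults were validated once across many
seeds (every species recovers its niche with held-out AUC > 0.8 and
Spearman > 0.7 against the true probability surface) and then frozen.

What passing tests on this landscape do *not* show: real occurrence
data carry sampling bias, positional error and niche-model
misspecification that the generator does not emulate; real land-use
change is spatially contagious rather than cell-independent (a
neighbourhood-majority option exists but is off by default); and real
threat tables, carbon densities and SPF schedules are study-specific.
The pipeline's correctness claims are structural — formulas, contracts,
determinism — not claims about any particular region.

## Numerical choices and degenerate inputs

Problem sizes were chosen so the full demo (three periods, three
species, 120 × 120 cells, 100 annealing runs per period) completes in
well under a minute: the annealer and the Jenks dynamic programme are
the two compiled kernels, and everything else is vectorised R. Other
fixed choices: impact kernels truncate exactly at d_max; equal-interval
degenerate ranges (max = min) collapse to a single class with a
warning; Jenks requires at least k distinct values and errors
otherwise; empty threat sources yield zero impact with a warning;
quality with no degradation anywhere sets k = 0.5 (Q = H exactly)
rather than dividing by zero; the evaluation threshold sweep uses exact
unique scores, not a grid. One global pipeline seed fans out to
per-stage seeds by stable hashing of stage names, so adding a stage
never perturbs the randomness of earlier ones, and rerunning a config
reproduces every output hash bit-for-bit.
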