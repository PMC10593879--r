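---
title: "Multiscale analysis of polygenic score effects on cortical morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale analysis of polygenic score effects on cortical morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`polycort` implements a multiscale analysis relating a per-subject polygenic
score to surface-based cortical morphometry in a developing cohort, together
with a synthetic-data module that generates every input the analysis needs.
The statistical core is the vertexwise linear model

\[
T_i = \beta_0 + \beta_1\,\mathrm{score} + \beta_2\,\mathrm{age}_c +
\beta_3\,\mathrm{age}_c^2 + \beta_4\,(\mathrm{score}\times\mathrm{age}_c) +
\beta_5\,(\mathrm{score}\times\mathrm{age}_c^2) + \beta_6\,\mathrm{sex} +
\boldsymbol\beta_7\,\mathrm{PC}_{1..10} + \beta_8\,\mathrm{scanner} +
\beta_9\,\mathrm{brainvolume} + \varepsilon_i
\]

fitted independently at every vertex \(i\) of a triangulated cortical
surface, where \(\mathrm{age}_c = \mathrm{age} - c\) for a centering age
\(c\). The \(\beta_1\) (score) t-map is the object every downstream stage
consumes: random-field-theory (RFT) cluster correction, class enrichment
against cytoarchitectural-type and functional-network atlases,
cell-type-specific expression correlation across cortical areas, and
similarity with case-control disorder effect-size maps.

Centering matters because the model includes score-by-age interactions:
\(\beta_1\) is the score effect *at age \(c\)*. The whole-cohort default is
the sample mean age; without centering \(\beta_1\) would be the extrapolated
effect at age zero, which has no developmental interpretation. The
age-centering sweep (`age_center_sweep()`) refits the model at \(c = 3..21\)
years; algebraically the score map at center \(c\) equals
\(\hat\beta_1 + \hat\beta_4 (c - c_0) + \hat\beta_5 (c - c_0)^2\)
from any single fit centered at \(c_0\), an identity the tests verify to
1e-6. Age-group analyses (3-9, 10-15, 16-21 years) subset the cohort, with
membership by completed years so that consecutive whole-year bands partition
a continuous age range, and center age to the group mean.

Sex and scanner are treatment-coded with the first level as reference (any
full-rank coding gives the same contrast t); the score, genetic principal
components and brain volume are standardized by default (configurable and
recorded in the fit object); a single-level factor contributes no columns.
With 2 scanners and interactions enabled the design has 19 columns.
Perfect-fit vertices (zero residual variance) would give infinite t values
and are returned as `NaN` with a warning, because RFT requires finite
fields.

## Surfaces, smoothing and smoothness estimation

Synthetic cortices are icospheres (`10 * 4^s + 2` vertices) with the
registration sphere equal to the surface, a contiguous polar cap of ~5% of
vertices flagged as medial wall (`NaN` everywhere, exercising the missing
data paths of every stage), and spherical-Voronoi atlases grown from
farthest-point-sampled seeds: 64 coarse parcels, a 200-parcel fine
decomposition, 6 cytoarchitectural classes and 7 functional networks
(classes cycle across patches so they are spatially distributed, as in real
type/network atlases).

Smoothing is iterated symmetric neighbour averaging,
\(S = I - (w/\mathrm{deg}_{max}) L\) on the valid-vertex subgraph, with the
per-step spatial variance calibrated from the mesh edge lengths so the
accumulated kernel has the requested FWHM
(\(\sigma^2 = \mathrm{FWHM}^2 / 8\ln 2\)). The operator is doubly
stochastic: constants, positivity and the map total are preserved exactly,
and two passes compose like a single pass at \(\sqrt{f^2+g^2}\) (checked to
5%). The per-step neighbour weight is capped at 0.5 so the kernel spans
several rings and is close to Gaussian; this matters for the RFT
calibration below. Closed-form heat kernels are unavailable on irregular
meshes, which is why iterated averaging (oracle-checkable through the
smoothness estimator) was chosen over spectral methods.

Residual smoothness is estimated by the standard roughness estimator:
residuals are normalized per vertex, the gradient variance
\(\lambda\) is accumulated along edges, and
\(\mathrm{FWHM} = \sqrt{4 \ln 2 / \lambda}\). White noise sampled on a mesh
with mean edge length \(h\) has intrinsic smoothness
\(\sqrt{2\ln 2}\,h \approx 1.18 h\); the thickness generator deconvolves its
target FWHM against this intrinsic term so that the generated *field* (not
the kernel) has the requested autocorrelation scale — the
generator/estimator round trip agrees within a few percent at icosphere
resolution 4.

## RFT cluster inference

Cluster correction follows the expected-Euler-characteristic formulation
for t fields on a 2D search region: EC densities give the expected number
of clusters at the primary threshold, the t tail probability times the
resel count gives the expected suprathreshold area, and the Poisson
clumping heuristic with exponential cluster extents gives
\(p = 1 - \exp(-E[m]\,e^{-k/E[n]})\) for a cluster of \(k\) resels. Cluster
extent is the sum of member-vertex areas, which is unbiased for the
continuous excursion-set area (each vertex is suprathreshold with exactly
the marginal tail probability); piecewise-linear interpolation was
evaluated and rejected because it systematically under-measures excursion
sets when the FWHM is only a few edge lengths.

The primary cluster-forming threshold defaults to vertexwise p < .001 at
the model df (the convention of surface-statistics toolboxes; the reference
analysis style leaves it unstated), one-sided positive by default (the
analysis of interest is a directional thickness increase) with two-sided
available, and cluster-level alpha .01. Smoothness is global (stationary);
non-stationary resel-per-vertex correction is a known limitation. On 1000
simulated null smooth t fields (icosphere 4, field FWHM three edge lengths,
df 300) the family-wise rate of any cluster p <= .05 is ~0.04 — within the
95% binomial band of the nominal rate, on the mildly conservative side,
which is the expected behaviour of the clumping approximation at moderate
thresholds.

## Spatial null models

Spin permutations draw Haar-uniform rotations (normalized Gaussian
quaternions), rotate the registration sphere, and reassign each vertex (or
parcel centroid) the value of its nearest original neighbour, with lowest
index breaking ties deterministically. A mesh carrying both hemispheres
uses the x-mirrored rotation on the right hemisphere, the standard
bilateral-symmetry convention. Medial-wall `NaN` values travel with the
rotation and are excluded pairwise from statistics. All permutation
p-values use the add-one rule \((1 + \#\{|r_{null}| \ge |r_{obs}|\}) /
(n_{perm} + 1)\), so p is never exactly zero.

Class enrichment reports the within-class median (the reporting convention
of the analyses this emulates; mean available) with its within-class SD,
and a two-tailed p as the doubled one-sided add-one p — the null medians of
a spun map are not centred at zero, so the symmetric |null| >= |obs| rule
would be wrong there. No cross-class multiplicity correction is applied at
this stage, matching the reference reporting. For the handful of expression
sampling areas (11), spherical spins are meaningless and significance uses
random reassignment permutations instead.

The calibration suite demonstrates both halves of the design rationale: on
independent smooth parcel maps the spin test rejects at the nominal 5%
rate, while naive reassignment applied to the smooth vertexwise maps
rejects at ~35% — spatial autocorrelation breaks exchangeability, which is
exactly why spins are used.

## Expression scoring

Cell-type scores weight each gene's log-expression by its specificity
weight and average over genes within (area, specimen), then across
specimens within area; compartment scores are the unweighted mean over
marker genes (equivalently, indicator weights). The phrase "average across
genes, across specimens, and within area" is ambiguous about order; the
weighted-gene-mean-then-specimen-mean order is used because it is
order-robust for complete panels, and the equivalence of marker averaging
with indicator-weight scoring is tested. Expression is assumed
pre-normalized on the log scale; genes in weight or marker lists but absent
from the panel are dropped with a counted warning, never imputed. Scores
are invariant to gene/specimen order and to weight rescaling; adding a
constant to all expression values shifts scores by that constant and leaves
correlations unchanged.

The 11 areas are matched to the fine parcellation by nearest great-circle
centroid distance — the original matching of expression sampling areas to
surface parcels was done visually and is not reproducible, so
nearest-centroid is the documented algorithmic surrogate, and assignments
can be overridden via a table.

## Map similarity and correlation comparisons

Disorder-map similarity correlates the parcellated score t-map with each
disorder's Cohen's d map on pairwise-complete parcels, with a two-tailed
spin p (significance at p_spin < .025) and Benjamini-Hochberg FDR across
the six disorders (p_FDR < .05). Comparisons of dependent overlapping
correlations implement Zou's confidence interval and Steiger's z (Williams
modification); independent correlations use Fisher's z. The age-group
analysis defaults to the independent Fisher z for pairwise group
comparisons — group maps share parcels, so this is an approximation, but it
matches the plain z/p reporting style of the analyses this reproduces; the
dependent Zou/Steiger route is available via an argument. The correlation
unit count is always the number of pairwise-complete parcels and is
recorded in every report.

## Synthetic-data conditions

Generator defaults emulate the study conditions end to end: 390 subjects
aged uniformly 3-21 years (the reference cohort is roughly flat across this
range), 46.8% female, 3 scanners, 10 genetic principal components, a
standard-normal polygenic score drawn independently of age (the reference
reports a near-zero score-age correlation; the score's true distribution is
unstated, so standard normal is the convention), brain volume ~ N(1.2e6,
1e5) mm^3. Thickness maps are baseline + planted effect x score + smooth
Gaussian noise; the default planted effect is a focal 25-mm patch with
amplitude set by SNR = |beta_1| SD(score)/noise_sd = 0.5 at noise SD 0.5 mm
and noise FWHM 20 mm. Expression panels plant six component gradients
(fixed standardized cosine patterns, distinct per component) over 11 areas
x 12 specimens with specimen noise SD 0.3; disorder maps are Gram-Schmidt
mixtures hitting planted correlations (-0.33, -0.47, -0.54, -0.43, 0, 0)
with the parcellated true effect, mirroring the magnitudes the reference
analysis reports.

What the generator does *not* emulate: cortical folding and real geometry,
non-stationary smoothness, site/batch structure beyond a scanner factor,
non-Gaussian score distributions, realistic gene-gene correlation, or
longitudinal structure. Passing tests therefore certify the statistical
machinery — estimator correctness, null calibration, planted-truth
recovery — not robustness to every property of real imaging-genetics data.

## Problem sizes and numerical choices

Tests and the acceptance script use icosphere resolutions 2-4 (162-2562
vertices), 199-1000 permutations and 50-2000 Monte-Carlo replicates; these
sizes make every distributional claim checkable in minutes while leaving
all calibration conclusions resolution-limited rather than
assumption-limited. Degenerate inputs error loudly rather than return
`NaN` silently: constant maps in correlation tests, zero-variance
references for disorder mixing, constant residual fields, empty marker
sets, rank-deficient designs. Tie-breaks (nearest-neighbour lookups,
union-find roots) always resolve to the lowest index, and every stochastic
routine is a pure function of (inputs, seed).

## Interfaces

The package's functions are its interface: `synthesize_inputs()` /
`run_pipeline()` compose the full flow and write JSON/TSV/CSV artifacts;
readers and writers exist for OBJ meshes with JSON sidecars, subject TSVs,
per-vertex label files with dictionaries, and map CSVs. A bundled
`demo_config.yaml` (see `inst/extdata/`) runs a reduced synthetic study;
`scripts/acceptance.R` recomputes the headline quantities from scratch for
a given seed.
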