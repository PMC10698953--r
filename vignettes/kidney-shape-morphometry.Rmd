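---
title: "Surface-based kidney morphometry: models, parameters and design choices"
author: "nephroShape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based kidney morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroShape)
```

## The analysis in one paragraph

Population imaging studies of the kidney increasingly move beyond
single summary measures (volume, length) to *surface-based
morphometry*: every participant's kidney surface is put into dense
point correspondence with a population template, the signed
surface-to-surface (S2S) distance at each of the ~4,000 template
vertices becomes a per-participant phenotype, and the same linear
model is fitted independently at every vertex (mass univariate
regression, MUR). Spatially coherent signal is amplified with
threshold-free cluster enhancement (TFCE), inference uses permutation
with Benjamini-Hochberg false-discovery-rate control across vertices,
and principal component analysis of the S2S fields yields low-rank
shape scores that feed Cox proportional hazards models of disease
incidence. nephroShape implements that entire chain, together with a
synthetic cohort generator with exactly known ground truth, so every
stage can be validated without access to restricted imaging cohorts.

## The vertex-wise linear model

At each template vertex the model is `Y = X beta + eps`, where `Y`
is the `n_s x n_v` matrix of signed S2S distances, `X` the shared
`n_s x p` design (intercept included) and `eps` zero-mean Gaussian
noise, independent across subjects. All continuous covariates — and,
under the default reporting convention, the response — are
standardised to unit SD, so coefficients are "per SD" and comparable
across covariates; `unstandardise()` converts a standardised
coefficient back to millimetres through the cohort's median
vertex-wise S2S SD. Interaction columns (e.g. age x disease) are
products of the *standardised* parents, formed after
standardisation, so the main-effect columns keep their meaning.
`interactionRateMap()` returns the within-subgroup rate of change as
the elementwise sum of a main-effect and an interaction map.

Assumptions worth stating plainly: linearity in the covariates,
homoscedastic vertex-wise noise, and independence across subjects.
The model is deliberately linear — the cost is insensitivity to
non-linear age or adiposity effects; the benefit is a convex,
closed-form fit at every vertex and exact Freedman-Lane permutation
semantics.

## TFCE on a triangle mesh

A raw t-map thresholded at an arbitrary height trades off height
against extent arbitrarily. TFCE integrates both: for vertex `v`,

    TFCE(v) = sum over h = dh, 2dh, ..., <= t_v of e_v(h)^E * h^H * dh

where `e_v(h)` is the *surface area* (mm^2, the sum of per-vertex
areas, each one third of its incident triangle areas) of the
connected supra-threshold component containing `v` at height `h`.
Both signs are enhanced separately (negated field, re-negated), since
inward and outward associations are reported separately.

Parameter defaults and rationale:

* `E = 1`, `H = 2` — the standard surface-data choice when the extent
  measure is a physical area; `H = 2` emphasises peak height without
  discarding extent.
* `dh = max|t|/100` — a quadrature step, not a statistical tuning
  knob. The enhanced value converges as `dh` shrinks; at 100 steps
  the right-hand Riemann sum overshoots the analytic integral of a
  constant field by about 1.5%, which is immaterial because observed
  and permuted maps share the same grid. Inside the permutation loop
  the step is frozen from the observed map so that enhanced values
  are comparable across permutations.
* Connected components are computed by union-find over the vertex
  edge graph in compiled code; a brute-force R implementation (loop
  over heights, igraph components) serves as an independent oracle in
  the test suite.

## Permutation inference and FDR

The default scheme is Freedman-Lane: fit the reduced model without
the target column, permute its residuals, add them back to the
reduced fit, refit the full model, and enhance the permuted t-map.
This preserves the nuisance structure of the design and is the
standard choice in the SPM lineage this package follows; plain
label permutation (`scheme = "label"`) is available for comparison.
Vertex-wise p-values use the add-one estimator
`p(v) = (1 + #{|TFCE_perm(v)| >= |TFCE_obs(v)|}) / (1 + n_perm)`,
whose smallest attainable value is `1/(1 + n_perm)` — at the
conventional 1,000 permutations, 0.000999. Benjamini-Hochberg is then
applied across vertices, per covariate and model, which is why
per-vertex p-values (not a max-statistic distribution) are computed
first. Perfect-fit vertices (zero residuals, possible in noiseless
synthetic data) would produce infinite t; they are capped at 1000
with a warning so enhancement stays finite.

Two properties of this construction matter for interpretation. The
p-values are valid *marginally*; in a single cohort whose noise is
spatially very coherent relative to the mesh, all vertices can shift
together, so sign-split significance areas fluctuate more than naive
binomial intuition suggests. And BH controls the *expected* false
discovery proportion — individual realisations above the nominal rate
are expected and observed.

## Geometry: masks, meshes, correspondence

`maskToMesh()` extracts the 0.5 isosurface of a binary mask by
marching tetrahedra on the zero-padded volume (six tetrahedra per
cell around the main diagonal), which always yields a closed,
consistently wound surface; coordinates map to world millimetres
through the NIfTI voxel-to-world affine with 0-based voxel indices.
Fragmented masks keep their largest connected component with a
warning, mirroring the usual exclusion of tiny segmentations
upstream. Smoothing is the uniform-weight umbrella operator — the
simplest faithful reading of "a Laplacian filter" — with 10 passes at
relaxation 0.5 by default; both are exposed because no canonical
values exist.

Correspondence follows the conventional cascade: rigid Procrustes
(Kabsch; closest-point ICP when topologies differ — point-to-point
with a 50-iteration cap and 1e-6 mm tolerance, chosen over
point-to-plane for robustness on closed convex-ish organ surfaces at
no observed accuracy cost), then a least-squares 3x4 affine, then
template propagation. The non-rigid step is a deliberately desk-scale
replacement for B-spline free-form deformation toolchains: a
regularised closest-point deformation (the template's displacement
field toward the subject is smoothed over the template adjacency each
iteration) followed by exact projection onto the subject surface.
The contract is the same — a dense, smooth template-to-subject map
with every propagated vertex within 0.5 mm of the subject surface —
and it is validated against constructed deformations (identity,
uniform inflation, localized bumps) rather than against any specific
registration package. Fold-over is detected by face-orientation
reversal and flags the subject rather than failing silently.

The signed S2S distance is the Euclidean distance between
corresponding vertices, signed by the projection onto the template
outward normal (positive = outward). Sign-by-normal-projection was
chosen over point-in-mesh parity because it is cheap, stable for
near-parallel correspondences, and exact for the generator below.

## What the synthetic generator does and does not emulate

The generator exists because the data-generating process of any real
cohort is unknown and the real data are access-controlled. Design:
displacements are applied *strictly along template outward normals*,

    disp_i(v) = sum_k E_k(v) * x_ik  +  noise_i(v)

with standardised covariates `x`, effect maps `E_k` in mm per SD,
and Gaussian noise smoothed over the mesh adjacency and rescaled to
an exact per-vertex SD. Because displacement is normal-directed, the
stored displacement matrix *is* the signed S2S field, giving an
analytic oracle for the whole geometry pipeline (verified to 1e-6 mm).

Defaults are the study conditions, chosen once: covariate marginals
mirror a large population imaging cohort (age 44-82, BMI 26.5 +/- 4.3
kg/m^2, 48.3% male, 96.9% white; CKD/T2D/hypertension prevalences
2.9%/5.3%/36.3%); noise SD 3.0 mm reproduces the reported median
vertex-wise S2S variability of about 3 mm; survival times are
exponential with hazard `h0 exp(x' beta)` (`h0 = 0.02`/year) under
uniform-entry administrative censoring over an 8-year window — the
window solves `1 - (1 - m/C) exp(-h0 m) = 0.5` at `m = 3.7`, so the
median observed follow-up is ~3.7 years by construction, not by
tuning. Ten noise-smoothing passes set the spatial correlation
length; no published value constrains it, so it is an explicit free
parameter of the generator, not an inference.

What it does not emulate: realistic renal anatomy (the template is a
bent superellipsoid with kidney-like semi-axes 18 x 30 x 55 mm),
covariate-dependent noise, non-linear effects, correlated
missingness, or segmentation error. Consequently, passing tests
demonstrate the *statistical machinery* — calibration, power, exact
recovery — under the stated model, and say nothing about
segmentation quality or registration accuracy on real MRI.

## Shape model and survival

PCA uses exact SVD of the centred data matrix (subjects in rows);
eigenvalues use the `n - 1` divisor so training-score variances equal
them exactly. Whether to decompose flattened coordinates, S2S
scalars, or their concatenation is genuinely ambiguous in the
literature this package follows; all three are supported
(`data_kind`), with S2S-only as the default feeding survival models,
since the downstream hazard models are defined on S2S scores. Mode
signs are arbitrary in principle; they are fixed so each mode's
largest-magnitude loading is positive, purely for determinism.

Cox models use the partial likelihood with Efron tie handling and
Wald 95% intervals. Continuous predictors are standardised by default
so hazard ratios are per-SD — whether published analyses scale this
way is typically unstated, so the choice is recorded in the output's
`standardised` attribute and can be switched off. BH-FDR is applied
over whatever family of estimates is passed in one call
(predictors x outcomes x kidneys in the pipeline), and the family
size is recorded.

## Numerical choices and degenerate inputs

* Standardisation uses the population SD (denominator `n`), making
  the operation exactly idempotent; constant columns are an error
  naming the column.
* Rank-deficient designs fail immediately, listing the collinear
  columns (QR with pivoting).
* The one-sided TFCE height loop is integer-indexed
  (`h = k * dh`) to avoid floating-point accumulation dropping the
  final height.
* Meshes are cleaned on construction paths: zero-area faces dropped,
  duplicate vertices merged, largest component kept, winding flipped
  to positive enclosed volume.
* All randomness flows from one root seed through
  `stageSeed(root, stage)` (derived seeds stay below 2^31), so each
  pipeline stage is individually reproducible and a full re-run is
  checksum-identical.

## Problem sizes used by the test and acceptance suites

The suites exercise the same conditions at sizes a single CPU
handles comfortably, chosen as the package's own validation design:
templates of 120-400 vertices (4,000-vertex construction is itself
tested); null calibration over 100-200 replicate cohorts of 60
subjects at 200 permutations; power at 500 subjects, 500
permutations, effect amplitude equal to one noise SD (detection
measured by Dice overlap against the planted support); PCA subspace
recovery at 500 subjects; Cox coverage over 500 replicates of 1,000
subjects; and the end-to-end pipeline at 200 subjects, 300 vertices,
200 permutations, run twice to verify hash-identical outputs.

## Known limitations

Vertex-wise models ignore spatial covariance in estimation (only
inference accounts for it, through TFCE and permutation); the
non-rigid correspondence is validated at the contract level, not
against a specific deformation toolkit; mesh I/O is ASCII-only
(PLY/VTK/OBJ); the generator's covariates are sampled independently,
so collinearity structure of real anthropometrics is not reproduced;
and diagnosis code flags are taken as resolved booleans — no
hospital-coding tables are parsed.
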