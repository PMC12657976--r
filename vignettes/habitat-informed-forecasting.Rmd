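---
title: "Habitat-informed forecasting of tumor response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-informed forecasting of tumor response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tumorhabitats)
```

## The problem

Neoadjuvant chemotherapy for locally advanced breast cancer is monitored with
multiparametric MRI: diffusion-weighted imaging (DW-MRI), whose apparent
diffusion coefficient (ADC) falls as cell density rises, and dynamic
contrast-enhanced imaging (DCE-MRI), whose enhancement curve reports
perfusion and hence drug delivery. A mechanistic reaction-diffusion model of
tumor cell number can be calibrated to the first two imaging visits (V1,
baseline; V2, mid-therapy) and run forward to predict the third (V3). The
proliferation rate in such models is classically fitted either once per
tumor ("global", spatially blind) or once per voxel ("local", expensive and
prone to overfitting). This package implements the intermediate strategy:
cluster tumor voxels across the whole cohort into a small number of imaging
*habitats* using longitudinal ADC and perfusion features, and fit one
proliferation rate per habitat.

## Cellularity and perfusion maps

DW-MRI at two b-values (100 and 800 s/mm^2) gives the ADC in closed form
from the mono-exponential decay `S_b = S_0 exp(-b ADC)`. Cellularity follows
from the linear inverse relation

    N_TC(x) = theta * (ADC_w - ADC(x)) / (ADC_w - ADC_min),

with `ADC_w = 3.0e-3` mm^2/s (free water at 37 C), `ADC_min` the minimum
tumor ADC of that patient across all visits, and the carrying capacity
`theta` the number of 10-um spheres that fit in a voxel at packing density
0.7405 (`carrying_capacity()`; about 2.65e5 cells for a 1 x 1 x 1.5 mm
voxel).

DCE timecourses are resampled to 0-360 s at 10 s and min-max normalized per
voxel. Three semi-quantitative maps summarize each curve: the maximum slope
of increase (MSI, 1/s), the positive enhancement integral (PEI, s; the
rectangle-rule area under the normalized curve over all 37 frames,
*including* the frame at tau = 0 — the defining sum is unrestricted, and this
convention is what makes the unit ramp print PEI = 185 s), and the signal
enhancement ratio SER = (S1 - S0)/(S2 - S0) from raw-frame means at
0/10/20, 110/120/130 and 340/350/360 s. Flat (non-enhancing) curves are
guarded: normalization returns zero and flags the voxel, and SER uses a
relative denominator tolerance of 1e-6. The drug-concentration field C(x) of
the therapy term is the PEI rescaled by its maximum over the breast mask,
computed from the baseline visit only: pre-treatment perfusion governs
delivery, and the model treats C as static.

## Longitudinal habitats

For every tumor voxel of every patient we form the vector {ADC(V1),
ADC(V2), Q(V1), Q(V2)} with Q one of MSI/PEI/SER, pool all vectors in one
matrix, standardize each column, and run k-means for H = 2..16. Because base
`stats::kmeans` does not provide k-means++ seeding, the seeder is
implemented in the package and each of 10 restarts runs Lloyd iterations
from those seeds; the best within-cluster sum of squares wins, under a fixed
seed. Habitat indices are re-labeled by increasing mean V1 ADC so numbering
is reproducible. Each habitat receives a high/low label per feature by
comparing its mean against the all-voxel mean (ties, a measure-zero event,
are labeled "low"); four binary features give the 16 possible label
combinations that motivate the upper bound H = 16.

Spatial coherence is diagnosed with 26-neighborhood statistics restricted to
the ROI: the percentage of voxels with no same-habitat neighbor, and a
spatial interaction matrix of row-normalized ordered neighbor-pair counts
whose diagonal measures within-habitat connectivity. The exact interaction
construction used in the antecedent literature is not fully specified in
public sources; the pair-count reconstruction here is therefore labeled as
such, and its diagonal is compared against size-preserving random
permutations of the labels with a Wilcoxon rank-sum test across the cohort.

## Forward model

Tumor cell number obeys a reaction-diffusion-therapy equation,

    dN/dt = div(D grad N) + k(x) N (1 - N/theta)
            - alpha N C(x) sum_ij exp(-beta_j (t - tau_ij)),

with no-flux boundaries on the breast mask (cells are conserved in the
untreated, non-proliferating limit). Therapy doses at times `tau_ij` decay
with per-drug rates `beta_j`; defaults are 1.0/day (Adriamycin) and 2.0/day
(Cytoxan) with doses at days 0/21/42/63, configurable — these are
order-of-plasma-clearance defaults and nothing downstream depends on them.

Diffusivity is mechanically damped: `D = D0 exp(-gamma sigma_vm)` where the
von Mises stress comes from linear-elastic equilibrium with the tumor
expansion pressure `-kappa N/theta I` in the Cauchy stress, Lame fields from
a two-value Young's modulus map (tumor 20 kPa, background 2 kPa, nu = 0.45
by default) and zero displacement on the mask boundary. Defaults
`kappa = 1 kPa` and `gamma = 2e-2 /kPa` are configurable; at these values
the damping is a mild perturbation, so conclusions about scheme ordering do
not hinge on the mechanics.

Numerics: explicit forward Euler with the step capped at
`0.9 h_min^2 / (6 D_max)`; the therapy factor is sampled at step midpoints,
which keeps the fast post-dose transient accurate at dt = 0.05 day; N is
clipped to [0, theta] after each step. The elasticity system is discretized
with collocated central differences (one-sided at the mask boundary for
stress assembly) and factorized once per patient — the operator depends only
on E, nu and the mask — so each stress refresh is a pair of triangular
solves. Stress is refreshed weekly by default: cellularity changes on the
cycle timescale, and on the default phantom a 1-day refresh changes V3
totals by well under 0.1% while costing 7x more solves. For image-resolution
grids the equilibrium solve can additionally be performed on a strided
(default phantom: 2x) grid with trilinear prolongation of the stress; the
stress field varies on the tumor scale, and the induced change in D is of
order 1e-3 of D0 at default coupling, while the sparse factorization shrinks by
roughly two orders of magnitude.

## Calibration

Two quantities are fitted per patient to the V2 data (V1 is the initial
condition): the proliferation field k(x) — one value per tumor, per habitat,
or per voxel — and a global drug efficacy alpha. The residual is the
theta-normalized voxelwise V2 misfit over the modeling ROI (the union of the
V1 and V2 segmentations). A Levenberg-Marquardt iteration with logistic
reparameterization enforces the bounds (defaults k in [0, 0.5]/day, alpha in
[0, 5]/day; physiologic doubling times and the exponential-death scale),
starting from k = 0.05/day and alpha = 0.1/day. The Jacobian uses forward
differences (relative step 1e-3); damping starts at 1e-3, x10 on rejection,
/10 on acceptance; iteration stops at a relative residual-norm change below
1e-6 or 100 iterations.

For the local scheme a dense forward-difference Jacobian would cost
`n_voxels + 2` simulations per iteration — the very cost explosion the
habitat strategy exists to avoid. The package instead exploits the weak
diffusion coupling: the per-voxel proliferation block of the Jacobian is
approximated by its diagonal, estimated from a single collective
perturbation of all voxel parameters, while the alpha column is computed
exactly. Each iteration then costs three simulations regardless of tumor
size. This is an approximation of the search direction only; the residual
itself is always exact, and accepted steps must reduce it.

Parameter counts follow the identities 2 (global), H + 1 (habitat) and
n + 1 (local), which the calibrator asserts on every run. D0 is held fixed
(0.05 mm^2/day by default) rather than calibrated: only proliferation and
efficacy are treated as patient-specific unknowns, and the V2 data used here
do not constrain diffusivity well.

## Virtual patients

Clinical trial data of this kind are not public, so the package ships a
synthetic cohort generator with known ground truth. A virtual patient is an
ellipsoidal tumor on a 32 x 32 x 16 grid of 1 x 1 x 1.5 mm voxels,
partitioned into three spatially contiguous subregions by seeded Voronoi
growth (Voronoi cells of a convex ROI are connected, which the connectivity
diagnostics verify). The three default archetypes emulate commonly reported
intratumoral contrast: a well-perfused responsive zone (k = 0.04/day, early
DCE peak), a dense poorly responding core (k = 0.08/day, declining
enhancement), and a sparse sluggish rim (k = 0.012/day, late peak). Each
archetype draws voxel cellularity uniformly within an ADC-equivalent range;
the core's range touches the ADC_min anchor so that the data-driven
minimum-ADC estimate is consistent with the generating mapping. Baseline DWI
follows by inverting the ADC-cellularity relation (S_0 = 1000 a.u.),
baseline DCE curves are piecewise-linear wash-in/wash-out with archetypal
onset/peak/plateau, and the true drug map C(x) is derived from the noiseless
baseline DCE exactly as the analysis pipeline would. V2/V3 images are
produced by the forward model run with the true parameters — so parameter
recovery and prediction error have exact references. Visits default to days
0/42/84 (two and four 21-day cycles); DWI noise is multiplicative Gaussian
(SD 2%, unbiased for the inversion at these SNRs, deliberately not Rician),
DCE noise additive (SD 2 a.u.). Cohorts jitter proliferation by +/-20%, DCE
amplitude by +/-15% and draw alpha uniformly on [0.3, 1.2]/day, which yields
a mix of responders and non-responders under the 5%-residual-cellularity
responder surrogate used for the ROC analysis.

What the phantom does *not* emulate: registration error (inputs are defined
as registered), Rician noise floors, coil bias, breast anatomy, and any
pathology-based ground truth for pCR. Passing tests on phantoms therefore
demonstrates the correctness and internal consistency of the machinery, and
the qualitative overfitting phenomenology, but not clinical performance.

## Evaluation

Per patient and scheme: absolute error in percent change of total tumor
cellularity (%dTTC) and total tumor volume (%dTTV, a voxel being
tumor-bearing at 25% of theta by default — the measured-data threshold is
never printed in public sources, so it is configurable and the default is
documented), and the mean squared error of the voxelwise fractional
cellularity change (MSE(%dTC), with a 1-cell guard for voxels empty at V1;
changes enter as fractions, matching the ~0.1 scale of published values).
The optimal habitat number is the smallest H whose three per-patient
V2/V3-averaged error distributions show no significant two-sample
Kolmogorov-Smirnov difference against every larger H (5% level). ROC
machinery (trapezoidal AUC = Mann-Whitney, Youden operating point, DeLong
CI and paired test) is delegated to pROC and cross-checked in the test suite
against brute-force pair counting and the placement-value variance formula;
identical paired predictors short-circuit to p = 1 before the degenerate
0/0 variance.

On aggregate metrics (%dTTC, %dTTV) a noisy phantom does not reliably
discriminate the schemes — voxel errors cancel in the totals — so the
ordering reproduction is asserted on the voxelwise MSE, where it is robust:
local < habitat < global at V2 (fit), local > habitat at V3 (overfitting).

## Problem sizes used by the tests and acceptance script

Parameter recovery runs 10 noiseless virtual patients at the default
32 x 32 x 16 grid; the scheme-ordering experiment uses 5 noisy patients at
20 x 20 x 10; the optimal-H experiment uses 8 patients at 16 x 16 x 8 with
H = 2..4 over three master seeds. These sizes are the package's desk-scale
choices: they keep each experiment's full pipeline (phantom, features,
habitats, calibration, prediction, statistics) exercised end to end with
cohort-level medians stable enough to assert on.

## Known limitations

- The collocated central-difference elasticity stencil admits checkerboard
  pressure modes at nu close to 0.5; the compact-stencil shear term keeps
  the system definite, and desk-scale accuracy is guarded by the
  stride-consistency and localization tests rather than a full staggered
  discretization.
- The diagonal Jacobian approximation for the local scheme slows late-stage
  convergence when diffusion coupling is strong; with the default D0 the
  nested-misfit ordering holds to optimizer tolerance.
- adc_min is estimated from the data minimum, so image-derived cellularity
  carries a small (<1%) multiplicative bias relative to ground truth on
  noiseless phantoms; recovery tolerances account for it.
- The KS-based H selection needs cohort-level separation to reject small H;
  with fewer than ~8 patients the test is conservative and tends to return
  the smallest H.
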