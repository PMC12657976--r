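# tumorhabitats

Forecasting breast tumor response to neoadjuvant chemotherapy from
multiparametric MRI, using *imaging habitats* to set the granularity of a
mechanistic reaction-diffusion model.

## Who this is for

Researchers in quantitative cancer imaging who want a tested, desk-scale
implementation of the habitat-informed calibration pipeline: voxelwise
cellularity from diffusion-weighted MRI, semi-quantitative perfusion maps
from DCE-MRI, cohort-level longitudinal habitat clustering, patient-specific
calibration of a mechanically coupled tumor growth model, and prediction of
a future imaging visit with full evaluation statistics. Because clinical
trial data of this kind are not public, the package ships a synthetic
virtual-patient generator with known ground truth; every stage of the
pipeline is exercisable end to end without any external data.

## The model

Tumor cell number N(x, t) per voxel evolves as

    dN/dt = div( D(x,t) grad N ) + k(x) N (1 - N/theta)
            - alpha N C(x) sum_{i,j} exp( -beta_j (t - tau_ij) )

* `theta` — carrying capacity, the number of 10-micron spheres that fit in a
  voxel at packing density 0.7405;
* `k(x)` — proliferation rate (1/day), calibrated **globally** (one value),
  **by habitat** (one per habitat), or **locally** (one per voxel);
* `alpha` — drug efficacy (1/day), always global; `C(x)` is the normalized
  area under the DCE enhancement curve; each drug dose decays exponentially
  at its plasma clearance rate `beta_j`;
* `D(x,t) = D0 exp(-gamma sigma_vm)` — cell diffusivity damped by the von
  Mises stress of the linear-elastic equilibrium driven by tumor expansion.

Cellularity is read off the ADC by the inverse linear map
`N = theta (ADC_w - ADC)/(ADC_w - ADC_min)`. Habitats are k-means clusters
(k-means++ seeding, 10 restarts) of the pooled, standardized voxel vectors
{ADC(V1), ADC(V2), Q(V1), Q(V2)} with Q one of MSI / PEI / SER. Calibration
is a bound-constrained Levenberg-Marquardt fit of the voxelwise V2 misfit;
V3 is predicted by running the fitted model forward through the full dose
schedule. Evaluation uses absolute errors in percent change of total tumor
cellularity and volume, the MSE of voxelwise fractional cellularity change,
KS-based optimal-habitat-number selection, and ROC/AUC with DeLong
comparisons.

## A worked example

```r
library(tumorhabitats)

cfg <- phantom_config(grid_shape = c(20, 20, 10),
                      roi_axes_frac = c(0.36, 0.36, 0.36))
study <- study_config(phantom = cfg, n_patients = 4, qoi = "MSI",
                      H_range = 2:3, schemes = c("global", "habitat", "local"),
                      seed = 11)
report <- run_study(study)

report$H_opt
#> [1] 3

report$efficiency
#>   calibration n_parameters median_wall_time_s
#> 1  habitat_H2            3             2.4970
#> 2  habitat_H3            4             7.4740
#> 3      global            2             2.1655
#> 4       local          809            19.8820

round(sapply(report$tables, function(t) median(t$msetc_v2)), 5)
#> habitat_H2 habitat_H3     global      local
#>    0.00971    0.00155    0.05153    0.00020

report$connectivity$semantic_labels
#>          adc_v1 adc_v2 q_v1   q_v2
#> habitat1 "low"  "low"  "low"  "low"
#> habitat2 "low"  "high" "high" "high"
#> habitat3 "high" "high" "low"  "low"
```

Reading the output: the optimal habitat number equals the number of regions
actually built into the phantom; the parameter count per scheme follows the
2 / H+1 / n+1 identities (here 809 = one k per ROI voxel + alpha); the V2
voxelwise fit error orders local < habitat < global, the expected
fit-flexibility ordering; and the habitat labels recover the built-in
contrast (e.g. habitat 2: cellularity drops from V1 to V2 in a well-perfused
region — the treatment-responsive habitat).

Individual stages are available as plain functions: `generate_cohort()`,
`fit_adc()`, `cellularity_map()`, `compute_msi()` / `compute_pei()` /
`compute_ser()`, `build_feature_matrix()`, `cluster_habitats()`,
`solve_equilibrium()`, `simulate_tumor()`, `calibrate()`, `predict_v3()`,
`select_optimal_H()`, `roc_auc()`, `delong_test()`. NIfTI/JSON/CSV export is
provided by `write_virtual_patient()`, `write_cohort()` and
`write_study_report()`.

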