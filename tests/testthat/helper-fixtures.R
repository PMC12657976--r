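# Small in-code fixtures shared across test files.

# Desk-scale phantom configuration for fast tests.
tiny_config <- function(grid = c(14, 14, 8), noise_dwi = 0, noise_dce = 0,
                        seed = 1L, ...) {
  phantom_config(grid_shape = grid, roi_axes_frac = c(0.36, 0.36, 0.36),
                 noise = list(dwi_sd = noise_dwi, dce_sd = noise_dce),
                 mechanics = list(E_tumor = 20, E_background = 2, nu = 0.45,
                                  kappa = 1, gamma = 2e-2, stride = 1),
                 seed = seed, ...)
}

# Single-voxel parameter set for ODE-limit tests.
single_voxel_params <- function(k, alpha, theta = 2e5, C = 1,
                                schedule = therapy_schedule(
                                  dose_days = rep(list(numeric(0)), 2))) {
  roi <- array(TRUE, c(1, 1, 1))
  model_parameter_set("global", k = k, alpha = alpha, D0 = 0, theta = theta,
                      C = array(C, c(1, 1, 1)), schedule = schedule,
                      roi = roi, mask = roi)
}

# A 4D linear-ramp DCE signal (0..1 normalized shape) on a small grid.
ramp_dce <- function(d = c(2, 2, 2), lo = 100, hi = 200,
                     times = seq(0, 360, by = 10)) {
  curve <- lo + (hi - lo) * times / max(times)
  array(rep(curve, each = prod(d)), dim = c(d, length(times)))
}
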