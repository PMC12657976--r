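# Synthetic multi-visit virtual patients with known ground truth.
#
# A virtual patient is an ellipsoidal tumor partitioned into spatially
# contiguous subregions (seeded Voronoi growth), each with its own
# proliferation rate, cellularity range (expressed as an ADC-equivalent
# range) and DCE enhancement archetype. Baseline (V1) images are synthesized
# from the cellularity/perfusion fields; V2 and V3 follow from the forward
# model run with the true parameters, so parameter recovery is testable.

#' Default subregion archetypes
#'
#' Three tumor subregions emulating commonly observed intratumoral contrast:
#' a well-perfused responsive zone, a densely cellular poorly responding
#' core, and a low-cellularity sluggishly enhancing rim. Each archetype
#' carries a proliferation rate `k` (1/day), an ADC-equivalent cellularity
#' range (mm^2/s), and a piecewise-linear DCE curve (baseline + amplitude,
#' onset/peak times in seconds, late plateau as a fraction of peak, and a
#' per-visit amplitude scale).
#'
#' @return List of archetype lists.
#' @export
default_archetypes <- function() {
  list(
    list(name = "perfused_responsive", k = 0.040,
         adc_range = c(1.0e-3, 1.6e-3),
         dce = list(base = 100, amp = 120, onset = 20, peak = 60,
                    plateau = 0.80, amp_scale = c(1, 0.8, 0.7))),
    list(name = "dense_core", k = 0.080,
         adc_range = c(0.5e-3, 1.3e-3),
         dce = list(base = 100, amp = 60, onset = 20, peak = 140,
                    plateau = 0.50, amp_scale = c(1, 0.6, 0.5))),
    list(name = "sparse_rim", k = 0.012,
         adc_range = c(1.8e-3, 2.6e-3),
         dce = list(base = 100, amp = 30, onset = 20, peak = 300,
                    plateau = 0.95, amp_scale = c(1, 0.9, 0.85))))
}

#' Phantom configuration
#'
#' @param grid_shape Voxels per axis (default 32 x 32 x 16).
#' @param voxel_size_mm Per-axis spacing, mm (default 1 x 1 x 1.5).
#' @param n_regions True subregion count (default 3).
#' @param region_archetypes List of archetypes (see [default_archetypes()]);
#'   recycled/truncated to `n_regions`.
#' @param background_dce DCE curve parameters for non-tumor breast tissue.
#' @param noise List: `dwi_sd` (multiplicative DWI noise SD) and `dce_sd`
#'   (additive DCE noise SD, arbitrary units). Both non-negative.
#' @param visit_days Times of V1, V2, V3 in days, strictly increasing from 0.
#' @param alpha True drug efficacy, 1/day.
#' @param adc_min Lower ADC anchor of the cellularity mapping, mm^2/s.
#' @param s0 DWI signal at b = 0, arbitrary units.
#' @param D0 Free diffusivity, mm^2/day.
#' @param mechanics List: `E_tumor`, `E_background` (kPa), `nu`, `kappa`
#'   (kPa), `gamma` (1/kPa).
#' @param roi_axes_frac Tumor ellipsoid semi-axes as a fraction of the grid.
#' @param dt Forward-model time step, days.
#' @param seed Integer master seed.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 32, 16),
                           voxel_size_mm = c(1, 1, 1.5),
                           n_regions = 3,
                           region_archetypes = default_archetypes(),
                           background_dce = list(base = 100, amp = 15,
                                                 onset = 20, peak = 180,
                                                 plateau = 0.8,
                                                 amp_scale = c(1, 1, 1)),
                           noise = list(dwi_sd = 0.02, dce_sd = 2),
                           visit_days = c(0, 42, 84),
                           alpha = 0.6,
                           adc_min = 0.5e-3,
                           s0 = 1000,
                           D0 = 0.05,
                           mechanics = list(E_tumor = 20, E_background = 2,
                                            nu = 0.45, kappa = 1, gamma = 2e-2,
                                            stride = 2),
                           roi_axes_frac = c(0.33, 0.33, 0.33),
                           dt = 0.05,
                           seed = 1L) {
  if (any(grid_shape < 4)) stop("grid_shape must be at least 4 per axis", call. = FALSE)
  if (n_regions < 1) stop("n_regions must be >= 1", call. = FALSE)
  if (visit_days[1] != 0 || any(diff(visit_days) <= 0))
    stop("visit_days must be strictly increasing and start at 0", call. = FALSE)
  if (noise$dwi_sd < 0 || noise$dce_sd < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  region_archetypes <- rep(region_archetypes,
                           length.out = n_regions)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, n_regions = n_regions,
                 region_archetypes = region_archetypes,
                 background_dce = background_dce, noise = noise,
                 visit_days = visit_days, alpha = alpha, adc_min = adc_min,
                 s0 = s0, D0 = D0, mechanics = mechanics,
                 roi_axes_frac = roi_axes_frac, dt = dt,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Ellipsoidal ROI mask centered on the grid.
phantom_roi <- function(config) {
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  ax <- pmax(config$roi_axes_frac * d, 1.5)
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  ((ix - ctr[1]) / ax[1])^2 + ((iy - ctr[2]) / ax[2])^2 +
    ((iz - ctr[3]) / ax[3])^2 <= 1
}

#' Generate the baseline cellularity field and region partition
#'
#' Partitions an ellipsoidal tumor ROI into `n_regions` spatially contiguous
#' subregions by seeded Voronoi growth (nearest seed point in physical
#' coordinates; cells of a Voronoi diagram restricted to a convex ROI are
#' connected). Cellularity is drawn per voxel, uniformly within the region
#' archetype's ADC-equivalent range.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @return List: `cellularity` (3D array, cells/voxel), `region_labels`
#'   (3D integer array, 0 outside the ROI), `roi` (logical array), `theta`.
#' @export
generate_cellularity_field <- function(config, seed = config$seed) {
  roi <- phantom_roi(config)
  nv <- sum(roi)
  if (config$n_regions > nv)
    stop(sprintf("degenerate phantom: %d regions requested but ROI has %d voxels",
                 config$n_regions, nv), call. = FALSE)
  d <- config$grid_shape
  vox <- which(roi, arr.ind = TRUE)
  pos <- sweep(vox, 2, config$voxel_size_mm, `*`)
  theta <- carrying_capacity(prod(config$voxel_size_mm))
  with_seed(seed, {
    # Greedy maximin seed placement for well-spread regions.
    seeds <- matrix(NA_real_, nrow = config$n_regions, ncol = 3)
    seeds[1, ] <- pos[sample.int(nv, 1L), ]
    if (config$n_regions > 1) for (r in 2:config$n_regions) {
      cand <- pos[sample.int(nv, min(64L, nv)), , drop = FALSE]
      dmin <- apply(cand, 1, function(p)
        min(colSums((t(seeds[seq_len(r - 1L), , drop = FALSE]) - p)^2)))
      seeds[r, ] <- cand[which.max(dmin), ]
    }
    d2 <- sapply(seq_len(config$n_regions), function(r)
      colSums((t(pos) - seeds[r, ])^2))
    lab <- max.col(-d2, ties.method = "first")
    region_labels <- array(0L, dim = d)
    region_labels[roi] <- lab
    adc <- array(ADC_WATER, dim = d)
    for (r in seq_len(config$n_regions)) {
      rr <- config$region_archetypes[[r]]$adc_range
      sel <- region_labels == r
      adc[sel] <- stats::runif(sum(sel), rr[1], rr[2])
    }
    cellularity <- array(0, dim = d)
    cellularity[roi] <- theta * (ADC_WATER - adc[roi]) / (ADC_WATER - config$adc_min)
    cellularity <- pmin(pmax(cellularity, 0), theta)
    list(cellularity = array(cellularity, dim = d),
         region_labels = region_labels, roi = roi, theta = theta)
  })
}

#' Synthesize a two-b-value DWI signal pair from cellularity
#'
#' Inverts the ADC-cellularity mapping:
#' `ADC = ADC_w - (N/theta) (ADC_w - adc_min)`, then
#' `S_b = S0 exp(-b ADC)` at both b-values, with multiplicative Gaussian
#' noise of the given SD when positive.
#'
#' @param cellularity 3D array in `[0, theta]`.
#' @param theta Carrying capacity.
#' @param adc_min Lower ADC anchor, mm^2/s (`< ADC_WATER`).
#' @param noise_sd Multiplicative noise SD (0 = noiseless).
#' @param seed Integer seed.
#' @param s0 Signal at b = 0.
#' @param b_values Acquired b-values, s/mm^2.
#' @return List: `s_low`, `s_high` (3D arrays), `b_values`.
#' @export
synthesize_dwi <- function(cellularity, theta, adc_min, noise_sd = 0,
                           seed = 1L, s0 = 1000, b_values = c(100, 800)) {
  if (any(cellularity < -1e-9 | cellularity > theta * (1 + 1e-9)))
    stop("cellularity must lie in [0, theta]", call. = FALSE)
  if (adc_min >= ADC_WATER) stop("adc_min must be below ADC_WATER", call. = FALSE)
  adc <- ADC_WATER - (cellularity / theta) * (ADC_WATER - adc_min)
  s_low <- s0 * exp(-b_values[1] * adc)
  s_high <- s0 * exp(-b_values[2] * adc)
  if (noise_sd > 0) {
    with_seed(seed, {
      s_low <- s_low * (1 + array(stats::rnorm(length(s_low), sd = noise_sd),
                                  dim = dim(s_low)))
      s_high <- s_high * (1 + array(stats::rnorm(length(s_high), sd = noise_sd),
                                    dim = dim(s_high)))
    })
  }
  list(s_low = s_low, s_high = s_high, b_values = b_values)
}

# Piecewise-linear enhancement curve: baseline until onset, linear wash-in to
# the peak, then linear wash-out to plateau * peak at the final frame.
dce_curve <- function(p, frame_times, amp) {
  tmax <- max(frame_times)
  ramp <- ifelse(frame_times <= p$onset, 0,
                 ifelse(frame_times <= p$peak,
                        (frame_times - p$onset) / (p$peak - p$onset),
                        1 - (1 - p$plateau) * (frame_times - p$peak) /
                          max(tmax - p$peak, 1)))
  p$base + amp * ramp
}

#' Synthesize a 4D DCE acquisition from the region partition
#'
#' Each voxel receives its region archetype's piecewise-linear enhancement
#' curve (visit-scaled amplitude), background voxels the background curve,
#' plus additive Gaussian noise.
#'
#' @param region_labels 3D integer array (0 = background).
#' @param archetypes List of region archetypes.
#' @param background_dce Background curve parameters.
#' @param frame_times Frame times, seconds (default 0..360 by 10).
#' @param noise_sd Additive noise SD (arbitrary units).
#' @param seed Integer seed.
#' @param visit Visit index (1-3) selecting the amplitude scale.
#' @return List: `signal` (4D array), `frame_times`.
#' @export
synthesize_dce <- function(region_labels, archetypes, background_dce,
                           frame_times = seq(0, 360, by = 10),
                           noise_sd = 0, seed = 1L, visit = 1L) {
  d <- dim(region_labels)
  nt <- length(frame_times)
  sig <- array(0, dim = c(d, nt))
  curves <- c(list(dce_curve(background_dce, frame_times,
                             background_dce$amp * background_dce$amp_scale[visit])),
              lapply(archetypes, function(a)
                dce_curve(a$dce, frame_times,
                          a$dce$amp * a$dce$amp_scale[visit])))
  lab <- as.vector(region_labels)
  mat <- matrix(0, nrow = prod(d), ncol = nt)
  for (r in 0:max(lab)) {
    sel <- lab == r
    if (any(sel)) mat[sel, ] <- matrix(curves[[r + 1L]], nrow = sum(sel),
                                       ncol = nt, byrow = TRUE)
  }
  if (noise_sd > 0)
    mat <- with_seed(seed, mat + matrix(stats::rnorm(length(mat), sd = noise_sd),
                                        nrow = nrow(mat)))
  list(signal = array(mat, dim = c(d, nt)), frame_times = frame_times)
}

#' Generate one virtual patient
#'
#' Builds the baseline tumor, derives the true drug-concentration map from
#' the noiseless baseline DCE, runs the forward model with the true
#' parameters to obtain V2/V3 cellularity, and synthesizes per-visit DWI and
#' DCE signals. All ground-truth fields are recorded.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Object of class `virtual_patient`: per-visit `dwi` and `dce`
#'   lists, `roi_mask` per visit, `roi` (V1-V2 union, the modeling ROI),
#'   `breast_mask`, `schedule`, `mechanics`, `theta`, `config`, and
#'   `ground_truth` (region labels, per-region and voxelwise k, alpha, C,
#'   per-visit cellularity, adc_min).
#' @export
generate_virtual_patient <- function(config, seed = config$seed) {
  d <- config$grid_shape
  base <- generate_cellularity_field(config, seed = derive_seed(seed, 1L))
  theta <- base$theta
  breast_mask <- array(TRUE, dim = d)
  k_by_region <- vapply(config$region_archetypes, `[[`, numeric(1), "k")

  # True drug-concentration map from the noiseless baseline DCE.
  dce_clean <- synthesize_dce(base$region_labels, config$region_archetypes,
                              config$background_dce, noise_sd = 0, visit = 1L)
  C_true <- drug_concentration(normalize_dce(dce_clean$signal)$signal, breast_mask)

  E <- array(config$mechanics$E_background, dim = d)
  E[base$roi] <- config$mechanics$E_tumor
  mech <- mechanical_params(E, nu = config$mechanics$nu,
                            kappa = config$mechanics$kappa,
                            gamma = config$mechanics$gamma,
                            mask = breast_mask,
                            voxel_size_mm = config$voxel_size_mm,
                            stride = config$mechanics$stride %||% 1L)
  schedule <- therapy_schedule()
  truth_params <- model_parameter_set(
    scheme = "habitat", k = k_by_region, alpha = config$alpha, D0 = config$D0,
    theta = theta, C = C_true, schedule = schedule, roi = base$roi,
    mechanics = mech, habitat_map = base$region_labels)
  sim <- simulate_tumor(truth_params, base$cellularity,
                        t_span = c(0, max(config$visit_days)), dt = config$dt,
                        output_times = config$visit_days[-1])
  cell <- c(list(base$cellularity), sim$snapshots)

  dwi <- lapply(seq_along(config$visit_days), function(v)
    synthesize_dwi(cell[[v]], theta, config$adc_min,
                   noise_sd = config$noise$dwi_sd,
                   seed = derive_seed(seed, 10L + v), s0 = config$s0))
  dce <- lapply(seq_along(config$visit_days), function(v)
    synthesize_dce(base$region_labels, config$region_archetypes,
                   config$background_dce, noise_sd = config$noise$dce_sd,
                   seed = derive_seed(seed, 20L + v), visit = v))

  roi_mask <- list(V1 = base$roi,
                   V2 = base$roi & cell[[2]] >= 0.05 * theta,
                   V3 = base$roi & cell[[3]] >= 0.05 * theta)
  k_field <- array(0, dim = d)
  k_field[base$roi] <- k_by_region[base$region_labels[base$roi]]

  structure(list(
    dwi = dwi, dce = dce, roi_mask = roi_mask,
    roi = roi_mask$V1 | roi_mask$V2, breast_mask = breast_mask,
    schedule = schedule, mechanics = mech, theta = theta, config = config,
    visit_days = config$visit_days,
    ground_truth = list(region_labels = base$region_labels,
                        k_by_region = k_by_region, k_field = k_field,
                        alpha = config$alpha, C = C_true,
                        cellularity = cell, adc_min = config$adc_min)),
    class = "virtual_patient")
}

#' Generate a cohort of virtual patients
#'
#' Per-patient seeds are derived deterministically from the master seed and
#' the per-patient biology is jittered: proliferation rates by +/-20%,
#' drug efficacy uniform on `[0.3, 1.2]` per day, DCE amplitudes by +/-15%.
#'
#' @param n_patients Cohort size.
#' @param config Base [phantom_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return List of [generate_virtual_patient()] objects.
#' @export
generate_cohort <- function(n_patients, config, seed = config$seed) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  lapply(seq_len(n_patients), function(i) {
    pseed <- derive_seed(seed, i)
    cfg <- config
    with_seed(derive_seed(pseed, 99L), {
      cfg$region_archetypes <- lapply(cfg$region_archetypes, function(a) {
        a$k <- a$k * stats::runif(1, 0.8, 1.2)
        a$dce$amp <- a$dce$amp * stats::runif(1, 0.85, 1.15)
        a
      })
      cfg$alpha <- stats::runif(1, 0.3, 1.2)
    })
    cfg$seed <- pseed
    generate_virtual_patient(cfg, seed = pseed)
  })
}
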