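# Quantitative feature maps from DW- and DCE-MRI volumes.

#' ADC of free water at body temperature
#'
#' Apparent diffusion coefficient of water at 37 degrees C, the upper anchor
#' of the ADC-to-cellularity mapping.
#'
#' @format Scalar, mm^2/s.
#' @export
ADC_WATER <- 3.0e-3

#' Fit an ADC map from a two-b-value DWI acquisition
#'
#' With exactly two b-values the mono-exponential signal decay
#' `S_b = S_0 exp(-b ADC)` has the closed-form solution
#' `ADC = log(S_b1 / S_b2) / (b2 - b1)`, equivalent to the log-linear
#' regression but exact. Voxels where either signal is non-positive cannot be
#' log-transformed; they are returned as `NA` and recorded in the
#' `"invalid"` attribute so downstream statistics can exclude them. Voxels
#' where the high-b signal exceeds the low-b signal produce a negative ADC,
#' returned as-is but flagged in the `"negative"` attribute.
#'
#' @param s_low,s_high 3D signal arrays at the lower / higher b-value.
#' @param b_values Length-2 numeric, s/mm^2 (default `c(100, 800)`).
#' @return Object of class `adc_map`: the 3D ADC array (mm^2/s) with
#'   attributes `b_values` and `invalid` (logical array).
#' @export
fit_adc <- function(s_low, s_high, b_values = c(100, 800)) {
  if (length(b_values) != 2L || b_values[2] == b_values[1])
    stop("fit_adc() needs two distinct b-values", call. = FALSE)
  if (!identical(dim(s_low), dim(s_high)))
    stop("DWI signal arrays must share dimensions", call. = FALSE)
  invalid <- !(s_low > 0 & s_high > 0)
  adc <- array(NA_real_, dim = dim(s_low))
  ok <- !invalid
  adc[ok] <- log(s_low[ok] / s_high[ok]) / (b_values[2] - b_values[1])
  negative <- !is.na(adc) & adc < 0
  structure(adc, b_values = b_values, invalid = invalid, negative = negative,
            class = c("adc_map", "array"))
}

#' Voxel carrying capacity from sphere packing
#'
#' Maximum number of spherical cells of radius `cell_radius` that fit in a
#' voxel of volume `voxel_volume` at the given packing density.
#'
#' @param voxel_volume Voxel volume, mm^3.
#' @param cell_radius Cell radius, mm (default 0.01, i.e. 10 um).
#' @param packing Packing density (default 0.7405, close sphere packing).
#' @return Carrying capacity theta, cells/voxel.
#' @export
carrying_capacity <- function(voxel_volume, cell_radius = 0.01, packing = 0.7405) {
  stopifnot_scalar(voxel_volume); stopifnot_scalar(cell_radius); stopifnot_scalar(packing)
  if (voxel_volume <= 0 || cell_radius <= 0 || packing < 0)
    stop("carrying_capacity() arguments must be positive", call. = FALSE)
  packing * voxel_volume / ((4 / 3) * pi * cell_radius^3)
}

#' Convert an ADC map to tumor cell number
#'
#' Linear inverse mapping between ADC and cellularity:
#' `N_TC = theta (ADC_w - ADC) / (ADC_w - ADC_min)`, clipped to `[0, theta]`.
#' `adc_min` should be the minimum ADC observed in the patient's tumor across
#' all visits (see [patient_adc_min()]).
#'
#' @param adc `adc_map` or 3D ADC array, mm^2/s.
#' @param adc_min Patient minimum tumor ADC, mm^2/s; must be `< ADC_WATER`.
#' @param theta Carrying capacity, cells/voxel.
#' @param adc_water ADC of free water (default [ADC_WATER]).
#' @return 3D cellularity array in `[0, theta]` (`NA` where ADC is `NA`).
#' @export
cellularity_map <- function(adc, adc_min, theta, adc_water = ADC_WATER) {
  stopifnot_scalar(adc_min); stopifnot_scalar(theta)
  if (adc_min >= adc_water)
    stop("adc_min must be below the free-water ADC", call. = FALSE)
  n <- theta * (adc_water - unclass(adc)) / (adc_water - adc_min)
  n <- pmin(pmax(n, 0), theta)
  array(n, dim = dim(adc))
}

#' Minimum tumor ADC across visits
#'
#' @param adc_list List of ADC arrays (one per visit).
#' @param roi_list List of logical ROI masks matching `adc_list`.
#' @return Scalar minimum ADC over all in-ROI, valid voxels.
#' @export
patient_adc_min <- function(adc_list, roi_list) {
  vals <- unlist(Map(function(a, r) unclass(a)[r], adc_list, roi_list))
  m <- suppressWarnings(min(vals, na.rm = TRUE))
  if (!is.finite(m)) stop("no valid in-ROI ADC values", call. = FALSE)
  m
}

#' Resample a DCE timecourse to the analysis grid
#'
#' Linearly interpolates each voxel's enhancement curve onto frame times
#' 0, 10, ..., 360 s (37 frames) so that curves are comparable across
#' acquisitions with different native temporal resolution.
#'
#' @param signal 4D array (x, y, z, frame).
#' @param frame_times Native frame times, seconds, strictly increasing.
#' @param target_times Target frame times (default `seq(0, 360, by = 10)`).
#' @return List with `signal` (4D array on the target grid) and `frame_times`.
#' @export
resample_dce <- function(signal, frame_times, target_times = seq(0, 360, by = 10)) {
  if (length(frame_times) != dim(signal)[4])
    stop("frame_times length must match the 4th array dimension", call. = FALSE)
  if (any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing", call. = FALSE)
  if (max(frame_times) < max(target_times) || min(frame_times) > min(target_times))
    stop(sprintf("DCE timecourse covers [%g, %g] s; [%g, %g] s required",
                 min(frame_times), max(frame_times),
                 min(target_times), max(target_times)), call. = FALSE)
  d <- dim(signal)
  mat <- matrix(signal, nrow = prod(d[1:3]), ncol = d[4])
  # One interpolation weight set serves every voxel (shared time grid).
  lo <- findInterval(target_times, frame_times, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), length(frame_times) - 1L)
  w <- (target_times - frame_times[lo]) / (frame_times[lo + 1L] - frame_times[lo])
  out <- mat[, lo, drop = FALSE] * rep(1 - w, each = nrow(mat)) +
    mat[, lo + 1L, drop = FALSE] * rep(w, each = nrow(mat))
  list(signal = array(out, dim = c(d[1:3], length(target_times))),
       frame_times = target_times)
}

#' Min-max normalize DCE curves per voxel
#'
#' Maps each voxel curve to `[0, 1]` by subtracting its minimum and dividing
#' by its range. Flat curves (range below `.Machine$double.eps` times the
#' signal scale) are set to all-zero and flagged.
#'
#' @param signal 4D DCE array.
#' @return List: `signal` (normalized 4D array), `flat` (3D logical array of
#'   flagged voxels).
#' @export
normalize_dce <- function(signal) {
  d <- dim(signal)
  mat <- matrix(signal, nrow = prod(d[1:3]), ncol = d[4])
  lo <- do.call(pmin, as.data.frame(mat))
  hi <- do.call(pmax, as.data.frame(mat))
  rng <- hi - lo
  flat <- rng <= .Machine$double.eps * pmax(abs(hi), 1)
  rng[flat] <- 1
  out <- (mat - lo) / rng
  out[flat, ] <- 0
  list(signal = array(out, dim = d), flat = array(flat, dim = d[1:3]))
}

#' Maximum slope of increase (MSI)
#'
#' Largest forward-difference slope of the normalized enhancement curve,
#' `max_tau (DCE_N(tau + dtau) - DCE_N(tau)) / dtau`.
#'
#' @param signal_n Normalized 4D DCE array (see [normalize_dce()]).
#' @param dtau Frame spacing, seconds (default 10).
#' @return 3D array, 1/s.
#' @export
compute_msi <- function(signal_n, dtau = 10) {
  d <- dim(signal_n)
  if (d[4] < 2L) stop("MSI needs at least two frames", call. = FALSE)
  mat <- matrix(signal_n, nrow = prod(d[1:3]), ncol = d[4])
  dif <- mat[, -1L, drop = FALSE] - mat[, -d[4], drop = FALSE]
  msi <- do.call(pmax, as.data.frame(dif)) / dtau
  array(msi, dim = d[1:3])
}

#' Positive enhancement integral (PEI)
#'
#' Rectangle-rule integral of the normalized enhancement curve over the full
#' resampled timecourse, `dtau * sum_tau DCE_N(tau)`; the sum runs over all
#' frames including tau = 0.
#'
#' @inheritParams compute_msi
#' @return 3D array, seconds; values in `[0, dtau * nframes]`.
#' @export
compute_pei <- function(signal_n, dtau = 10) {
  d <- dim(signal_n)
  mat <- matrix(signal_n, nrow = prod(d[1:3]), ncol = d[4])
  array(dtau * rowSums(mat), dim = d[1:3])
}

#' Signal enhancement ratio (SER)
#'
#' `SER = (S1 - S0) / (S2 - S0)` where S0, S1, S2 average the *raw* DCE frames
#' at 0/10/20 s (pre-contrast), 110/120/130 s (early post-contrast) and
#' 340/350/360 s (late post-contrast). Voxels where `|S2 - S0|` falls below
#' `tol * S0` do not enhance; their SER is set to 0 and flagged.
#'
#' @param signal Raw (unnormalized) 4D DCE array on the resampled grid.
#' @param frame_times Frame times, seconds.
#' @param tol Relative guard threshold for the denominator (default 1e-6).
#' @return List: `ser` (3D array), `flagged` (3D logical array).
#' @export
compute_ser <- function(signal, frame_times, tol = 1e-6) {
  pick <- function(times) {
    ix <- match(times, frame_times)
    if (anyNA(ix))
      stop(sprintf("required DCE frames at %s s are missing",
                   paste(times[is.na(ix)], collapse = ", ")), call. = FALSE)
    ix
  }
  d <- dim(signal)
  mat <- matrix(signal, nrow = prod(d[1:3]), ncol = d[4])
  s0 <- rowMeans(mat[, pick(c(0, 10, 20)), drop = FALSE])
  s1 <- rowMeans(mat[, pick(c(110, 120, 130)), drop = FALSE])
  s2 <- rowMeans(mat[, pick(c(340, 350, 360)), drop = FALSE])
  den <- s2 - s0
  flagged <- abs(den) <= tol * pmax(abs(s0), .Machine$double.eps)
  ser <- numeric(length(den))
  ser[!flagged] <- (s1[!flagged] - s0[!flagged]) / den[!flagged]
  list(ser = array(ser, dim = d[1:3]), flagged = array(flagged, dim = d[1:3]))
}

#' Normalized drug concentration map
#'
#' The drug delivery field C(x) in the therapy term is taken as the area
#' under the normalized enhancement curve (the PEI), rescaled by its maximum
#' over the breast mask so that `max C = 1`. Computed from the baseline (V1)
#' DCE acquisition: pre-treatment perfusion governs delivery and the model's
#' C(x) is static in time.
#'
#' @param signal_n Normalized 4D DCE array at the visit used (default V1).
#' @param breast_mask 3D logical array over which the maximum is taken.
#' @inheritParams compute_msi
#' @return 3D array in `[0, 1]`.
#' @export
drug_concentration <- function(signal_n, breast_mask, dtau = 10) {
  pei <- compute_pei(signal_n, dtau)
  mx <- max(pei[breast_mask])
  if (!is.finite(mx) || mx <= 0)
    stop("PEI is zero everywhere in the breast mask; cannot normalize C(x)",
         call. = FALSE)
  pei / mx
}
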