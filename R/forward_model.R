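# Mechanically coupled reaction-diffusion model of therapy response:
#
#   dN/dt = div(D grad N) + k(x) N (1 - N/theta)
#           - alpha N C(x) sum_{i,j} exp(-beta_j (t - tau_ij))
#
# integrated by explicit forward Euler on the breast mask with a zero-flux
# boundary, with D(x,t) = D0 exp(-gamma sigma_vm(x,t)) refreshed at a
# configurable interval.

#' Therapy schedule
#'
#' @param drugs Character vector of drug names.
#' @param beta Per-drug plasma decay rates, 1/day (positive).
#' @param dose_days List (one element per drug) of administration days,
#'   non-negative and sorted.
#' @return Object of class `therapy_schedule`.
#' @export
therapy_schedule <- function(drugs = c("adriamycin", "cytoxan"),
                             beta = c(1.0, 2.0),
                             dose_days = rep(list(c(0, 21, 42, 63)), 2)) {
  if (length(drugs) != length(beta) || length(drugs) != length(dose_days))
    stop("drugs, beta and dose_days must have equal length", call. = FALSE)
  if (any(beta <= 0)) stop("drug decay rates beta must be positive", call. = FALSE)
  dose_days <- lapply(dose_days, function(d) {
    if (any(d < 0)) stop("dose times must be non-negative", call. = FALSE)
    sort(d)
  })
  structure(list(drugs = drugs, beta = beta, dose_days = dose_days),
            class = "therapy_schedule")
}

#' Therapy decay factor at time t
#'
#' `sum_{i,j : tau_ij <= t} exp(-beta_j (t - tau_ij))`; doses in the future
#' contribute nothing (causality). Vectorized over `t`.
#'
#' @param schedule A [therapy_schedule()].
#' @param t Time(s), days.
#' @return Numeric vector the length of `t`.
#' @export
therapy_factor <- function(schedule, t) {
  out <- numeric(length(t))
  for (j in seq_along(schedule$beta)) {
    b <- schedule$beta[j]
    for (tau in schedule$dose_days[[j]]) {
      active <- t >= tau
      out[active] <- out[active] + exp(-b * (t[active] - tau))
    }
  }
  out
}

#' Model parameter set
#'
#' The proliferation field can be parameterized at three granularities:
#' `"global"` (one k per tumor), `"habitat"` (one k per habitat, requires
#' `habitat_map`), or `"local"` (one k per ROI voxel). Drug efficacy `alpha`
#' is always global.
#'
#' @param scheme One of `"global"`, `"habitat"`, `"local"`.
#' @param k Proliferation rate(s), 1/day: scalar, length-H vector, or
#'   length-`sum(roi)` vector according to `scheme`.
#' @param alpha Drug efficacy, 1/day (non-negative).
#' @param D0 Free diffusivity, mm^2/day.
#' @param theta Carrying capacity, cells/voxel.
#' @param C Drug concentration array in `[0, 1]` (see [drug_concentration()]).
#' @param schedule A [therapy_schedule()].
#' @param roi 3D logical tumor ROI mask.
#' @param mask 3D logical breast mask (PDE domain). Defaults to all of the
#'   grid when `mechanics` is absent.
#' @param mechanics Optional [mechanical_params()]; when present, D is damped
#'   by the von Mises stress and `mask` is taken from it.
#' @param habitat_map Integer 3D array of habitat labels (scheme "habitat").
#' @param stress_interval Days between stress/diffusivity refreshes
#'   (default 7).
#' @return Object of class `model_parameter_set`.
#' @export
model_parameter_set <- function(scheme = c("global", "habitat", "local"),
                                k, alpha, D0, theta, C, schedule, roi,
                                mask = NULL, mechanics = NULL,
                                habitat_map = NULL, stress_interval = 7) {
  scheme <- match.arg(scheme)
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (is.null(mask)) mask <- if (!is.null(mechanics)) mechanics$mask else
    array(TRUE, dim = dim(roi))
  n_needed <- switch(scheme,
                     global = 1L,
                     habitat = {
                       if (is.null(habitat_map))
                         stop("habitat scheme requires a habitat_map", call. = FALSE)
                       max(habitat_map[roi], na.rm = TRUE)
                     },
                     local = sum(roi))
  if (length(k) != n_needed)
    stop(sprintf("scheme '%s' needs %d k value(s), got %d",
                 scheme, n_needed, length(k)), call. = FALSE)
  structure(list(scheme = scheme, k = k, alpha = alpha, D0 = D0,
                 theta = theta, C = C, schedule = schedule, roi = roi,
                 mask = mask, mechanics = mechanics, habitat_map = habitat_map,
                 stress_interval = stress_interval),
            class = "model_parameter_set")
}

#' Expand the proliferation parameterization to a voxel field
#'
#' @param params A [model_parameter_set()].
#' @return 3D array of k values, zero outside the ROI.
#' @export
expand_k <- function(params) {
  roi <- params$roi
  kf <- array(0, dim = dim(roi))
  switch(params$scheme,
         global = { kf[roi] <- params$k },
         habitat = {
           lab <- params$habitat_map[roi]
           if (anyNA(lab) || any(lab < 1L) || any(lab > length(params$k)))
             stop("habitat_map labels outside 1..H inside the ROI", call. = FALSE)
           kf[roi] <- params$k[lab]
         },
         local = { kf[roi] <- params$k })
  kf
}

#' Integrate the tumor growth model forward in time
#'
#' Explicit forward-Euler integration of the reaction-diffusion-therapy
#' equation. The time step is reduced automatically to satisfy the explicit
#' stability bound `dt <= 0.9 h_min^2 / (6 D0)`. The stress state (hence D)
#' is refreshed every `stress_interval` days when mechanics are attached;
#' otherwise D = D0 uniformly.
#'
#' @param params A [model_parameter_set()].
#' @param init 3D initial cellularity array, in `[0, theta]`.
#' @param t_span Length-2 numeric, start and end times in days.
#' @param dt Requested time step, days (default 0.05).
#' @param output_times Times (days) at which snapshots are recorded; the end
#'   time is always included.
#' @param clip Clip N to `[0, theta]` after each step (default TRUE).
#' @return Object of class `simulation_result`: list with `snapshots` (list
#'   of 3D arrays), `times`, and `diagnostics` (total mass per snapshot, the
#'   time step used, CFL margin).
#' @export
simulate_tumor <- function(params, init, t_span, dt = 0.05,
                           output_times = numeric(), clip = TRUE) {
  theta <- params$theta
  if (any(init < -1e-9 | init > theta * (1 + 1e-9), na.rm = TRUE))
    stop("init must lie in [0, theta]", call. = FALSE)
  d <- dim(init)
  h <- if (!is.null(params$mechanics)) params$mechanics$h else c(1, 1, 1.5)
  mask <- params$mask
  kf <- expand_k(params)
  ac <- params$alpha * params$C
  dt_stab <- 0.9 * min(h)^2 / (6 * max(params$D0, .Machine$double.eps))
  dt_eff <- min(dt, dt_stab)

  use_mech <- !is.null(params$mechanics) && params$mechanics$gamma > 0 &&
    params$D0 > 0
  refresh <- if (use_mech)
    seq(t_span[1], t_span[2], by = params$stress_interval) else t_span[1]
  out_t <- sort(unique(c(output_times, t_span[2])))
  out_t <- out_t[out_t > t_span[1] & out_t <= t_span[2]]
  events <- sort(unique(c(t_span[1], refresh, out_t, t_span[2])))

  D_field <- function(N) {
    if (!use_mech) return(array(params$D0, dim = d))
    ss <- solve_equilibrium(params$mechanics, N, theta, fields = "svm")
    damped_diffusivity(params$D0, params$mechanics$gamma, ss$svm)
  }

  N <- init
  D <- D_field(N)
  snaps <- list(); times <- numeric(); mass <- numeric()
  for (e in seq_len(length(events) - 1L)) {
    t0 <- events[e]; t1 <- events[e + 1L]
    if (t1 > t0) {
      nst <- max(1L, ceiling((t1 - t0) / dt_eff))
      dts <- (t1 - t0) / nst
      tf <- therapy_factor(params$schedule, t0 + (seq_len(nst) - 0.5) * dts)
      N <- rd_run_cpp(N, D, mask, kf, theta, ac, tf, as.integer(d), h, dts, clip)
      if (anyNA(N) || any(!is.finite(N)))
        stop(sprintf("simulation became non-finite in [%g, %g] days (dt = %g)",
                     t0, t1, dts), call. = FALSE)
    }
    if (use_mech && any(abs(refresh - t1) < 1e-9) && t1 < t_span[2])
      D <- D_field(N)
    if (any(abs(out_t - t1) < 1e-9)) {
      snaps[[length(snaps) + 1L]] <- N
      times <- c(times, t1)
      mass <- c(mass, sum(N))
    }
  }
  structure(list(snapshots = snaps, times = times,
                 diagnostics = list(mass = mass, dt = dt_eff,
                                    cfl_margin = dt_eff / dt_stab)),
            class = "simulation_result")
}
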