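# Patient-specific calibration of proliferation and drug efficacy to the
# V1 -> V2 data, and prediction of V3.
#
# The objective is the vector of voxelwise V2 misfits (model - data)/theta
# over the modeling ROI, minimized by a bound-constrained
# Levenberg-Marquardt iteration. Bounds are enforced by a logistic
# reparameterization so the optimizer works in an unconstrained space.

#' Define a calibration problem
#'
#' @param v1,v2 3D cellularity arrays at the first two visits (cells/voxel).
#' @param roi 3D logical modeling ROI (union of the V1 and V2 masks).
#' @param theta Carrying capacity.
#' @param C Drug concentration array in `[0, 1]`.
#' @param schedule A [therapy_schedule()].
#' @param scheme `"global"`, `"habitat"` or `"local"`.
#' @param habitat_map Integer 3D label array (scheme "habitat").
#' @param mechanics Optional [mechanical_params()].
#' @param D0 Free diffusivity, mm^2/day.
#' @param v2_day,v3_day Visit times in days (defaults 42, 84).
#' @param dt Forward-model time step, days.
#' @param k_bounds,alpha_bounds Parameter bounds, 1/day.
#' @param lm Levenberg-Marquardt settings: `max_iter`, `ftol`, `fd_step`,
#'   `lambda0`.
#' @return Object of class `calibration_problem`.
#' @export
calibration_problem <- function(v1, v2, roi, theta, C, schedule,
                                scheme = c("global", "habitat", "local"),
                                habitat_map = NULL, mechanics = NULL,
                                D0 = 0.05, v2_day = 42, v3_day = 84, dt = 0.05,
                                k_bounds = c(0, 0.5), alpha_bounds = c(0, 5),
                                lm = list(max_iter = 100L, ftol = 1e-6,
                                          fd_step = 1e-3, lambda0 = 1e-3)) {
  scheme <- match.arg(scheme)
  if (!identical(dim(v1), dim(v2)))
    stop("V1 and V2 must share a grid", call. = FALSE)
  if (any(!is.finite(k_bounds)) || any(!is.finite(alpha_bounds)) ||
      diff(k_bounds) <= 0 || diff(alpha_bounds) <= 0)
    stop("bounds must be finite with min < max", call. = FALSE)
  if (scheme == "habitat" && is.null(habitat_map))
    stop("habitat scheme requires habitat_map", call. = FALSE)
  n_k <- switch(scheme, global = 1L,
                habitat = max(habitat_map[roi], na.rm = TRUE),
                local = sum(roi))
  structure(list(v1 = v1, v2 = v2, roi = roi, theta = theta, C = C,
                 schedule = schedule, scheme = scheme,
                 habitat_map = habitat_map, mechanics = mechanics, D0 = D0,
                 v2_day = v2_day, v3_day = v3_day, dt = dt, n_k = n_k,
                 k_bounds = k_bounds, alpha_bounds = alpha_bounds, lm = lm),
            class = "calibration_problem")
}

# Parameter vector layout: c(k_1..k_nk, alpha).
problem_parameter_set <- function(problem, par) {
  model_parameter_set(scheme = problem$scheme, k = par[seq_len(problem$n_k)],
                      alpha = par[problem$n_k + 1L], D0 = problem$D0,
                      theta = problem$theta, C = problem$C,
                      schedule = problem$schedule, roi = problem$roi,
                      mechanics = problem$mechanics,
                      habitat_map = problem$habitat_map)
}

#' Voxelwise V2 residual vector
#'
#' Simulates V1 -> V2 with the given parameter vector and returns the
#' theta-normalized misfit `(N_model - N_data)/theta` at every ROI voxel.
#'
#' @param problem A [calibration_problem()].
#' @param par Parameter vector `c(k..., alpha)` in natural units.
#' @return Numeric residual vector of length `sum(roi)`.
#' @export
residuals_v2 <- function(problem, par) {
  ps <- problem_parameter_set(problem, par)
  sim <- simulate_tumor(ps, problem$v1, t_span = c(0, problem$v2_day),
                        dt = problem$dt)
  n_model <- sim$snapshots[[length(sim$snapshots)]]
  (n_model[problem$roi] - problem$v2[problem$roi]) / problem$theta
}

#' Number of calibrated parameters per scheme
#'
#' Global: one proliferation rate plus one drug efficacy (2). Habitat: one
#' rate per habitat plus efficacy (H + 1). Local: one rate per ROI voxel plus
#' efficacy (n + 1).
#'
#' @param scheme `"global"`, `"habitat"` or `"local"`.
#' @param H Habitat count (habitat scheme).
#' @param n_voxels ROI voxel count (local scheme).
#' @return Integer parameter count.
#' @export
count_parameters <- function(scheme = c("global", "habitat", "local"),
                             H = NULL, n_voxels = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
         global = 2L,
         habitat = {
           if (is.null(H)) stop("habitat scheme needs H", call. = FALSE)
           as.integer(H + 1L)
         },
         local = {
           if (is.null(n_voxels)) stop("local scheme needs n_voxels", call. = FALSE)
           as.integer(n_voxels + 1L)
         })
}

# Logistic bound transform: z unconstrained <-> p in (lo, hi).
bounds_to_z <- function(p, lo, hi) {
  f <- pmin(pmax((p - lo) / (hi - lo), 1e-6), 1 - 1e-6)
  stats::qlogis(f)
}
z_to_bounds <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Bound-constrained Levenberg-Marquardt least squares
#'
#' Minimizes `||r(p)||^2` with box bounds enforced through a logistic
#' reparameterization. The Jacobian is formed by forward differences
#' (relative step `fd_step` in the transformed space). Damping starts at
#' `lambda0`, is multiplied by 10 on a rejected step and divided by 10 on an
#' accepted one; iteration stops when the relative change of the residual
#' norm falls below `ftol` or after `max_iter` iterations.
#'
#' For residuals with one parameter per voxel (`jacobian = "structured"`,
#' used by the local scheme) the per-voxel columns are approximated by their
#' diagonal, estimated from a single collective perturbation, while the final
#' (global) column is computed exactly; see the methods vignette.
#'
#' @param fn Residual function of the natural-units parameter vector.
#' @param init Initial parameter vector (inside the bounds).
#' @param lower,upper Bound vectors (recycled).
#' @param max_iter,ftol,fd_step,lambda0 Algorithm settings.
#' @param jacobian `"dense"` or `"structured"`.
#' @return Object of class `calibration_fit`: `par`, `rss_trace` (residual
#'   norms of accepted iterates), `converged`, `iterations`, `n_evals`,
#'   `wall_time_s`.
#' @export
levenberg_marquardt <- function(fn, init, lower, upper,
                                max_iter = 100L, ftol = 1e-6, fd_step = 1e-3,
                                lambda0 = 1e-3, jacobian = c("dense", "structured")) {
  jacobian <- match.arg(jacobian)
  t_start <- proc.time()[["elapsed"]]
  np <- length(init)
  lower <- rep_len(lower, np); upper <- rep_len(upper, np)
  z <- bounds_to_z(init, lower, upper)
  n_evals <- 0L
  eval_r <- function(z) {
    n_evals <<- n_evals + 1L
    fn(z_to_bounds(z, lower, upper))
  }
  r <- eval_r(z)
  if (any(!is.finite(r)))
    stop("non-finite residual at the initial point", call. = FALSE)
  nr <- length(r)
  norm_r <- sqrt(sum(r^2))
  trace <- norm_r
  lambda <- lambda0
  converged <- FALSE
  iter <- 0L

  num_jac <- function(z, r) {
    if (jacobian == "dense") {
      J <- matrix(0, nr, np)
      for (j in seq_len(np)) {
        dz <- fd_step * max(1, abs(z[j]))
        zj <- z; zj[j] <- zj[j] + dz
        J[, j] <- (eval_r(zj) - r) / dz
      }
      J
    } else {
      # Collective perturbation of the voxel-wise block (params 1..np-1):
      # residual i responds mainly to its own parameter, so the response is
      # attributed to the diagonal. The final column is exact.
      dz <- fd_step
      zk <- z; zk[-np] <- zk[-np] + dz
      diag_g <- (eval_r(zk) - r) / dz
      za <- z
      dza <- fd_step * max(1, abs(z[np]))
      za[np] <- za[np] + dza
      col_a <- (eval_r(za) - r) / dza
      Matrix::sparseMatrix(
        i = c(seq_len(nr), seq_len(nr)),
        j = c(seq_len(min(nr, np - 1L)), rep(np, nr)),
        x = c(diag_g[seq_len(min(nr, np - 1L))], col_a),
        dims = c(nr, np))
    }
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    J <- num_jac(z, r)
    JtJ <- as(Matrix::crossprod(J), "CsparseMatrix")
    g <- as.vector(Matrix::crossprod(J, r))
    dvec <- pmax(Matrix::diag(JtJ), 1e-12)
    accepted <- FALSE
    for (try in 1:10) {
      A <- JtJ + lambda * Matrix::Diagonal(np, dvec)
      step <- tryCatch(as.vector(Matrix::solve(A, -g)),
                       error = function(e) NULL)
      if (!is.null(step)) {
        z_new <- z + step
        r_new <- eval_r(z_new)
        if (all(is.finite(r_new)) && sqrt(sum(r_new^2)) < norm_r) {
          rel <- (norm_r - sqrt(sum(r_new^2))) / max(norm_r, 1e-30)
          z <- z_new; r <- r_new; norm_r <- sqrt(sum(r^2))
          trace <- c(trace, norm_r)
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          if (rel < ftol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
  }
  structure(list(par = z_to_bounds(z, lower, upper), rss_trace = trace,
                 converged = converged, iterations = iter, n_evals = n_evals,
                 wall_time_s = proc.time()[["elapsed"]] - t_start),
            class = "calibration_fit")
}

#' Calibrate a patient
#'
#' Runs the bound-constrained Levenberg-Marquardt fit of the V2 residuals.
#' Initial guess: k = 0.05/day for every component, alpha = 0.1/day.
#'
#' @param problem A [calibration_problem()].
#' @return Object of class `calibration_result`: the fit plus `scheme`,
#'   `n_parameters`, `k`, `alpha`.
#' @export
calibrate <- function(problem) {
  np <- problem$n_k + 1L
  init <- c(rep(0.05, problem$n_k), 0.1)
  lower <- c(rep(problem$k_bounds[1], problem$n_k), problem$alpha_bounds[1])
  upper <- c(rep(problem$k_bounds[2], problem$n_k), problem$alpha_bounds[2])
  fit <- levenberg_marquardt(
    function(p) residuals_v2(problem, p), init, lower, upper,
    max_iter = problem$lm$max_iter %||% 100L,
    ftol = problem$lm$ftol %||% 1e-6,
    fd_step = problem$lm$fd_step %||% 1e-3,
    lambda0 = problem$lm$lambda0 %||% 1e-3,
    jacobian = if (problem$scheme == "local") "structured" else "dense")
  n_par <- count_parameters(problem$scheme, H = problem$n_k,
                            n_voxels = problem$n_k)
  stopifnot(n_par == np)
  structure(c(unclass(fit),
              list(scheme = problem$scheme, n_parameters = n_par,
                   k = fit$par[seq_len(problem$n_k)],
                   alpha = fit$par[problem$n_k + 1L])),
            class = "calibration_result")
}

#' Predict the V3 cellularity field
#'
#' Runs the model forward from V1 to V3 with the fitted parameters and the
#' full dose schedule.
#'
#' @param problem A [calibration_problem()].
#' @param result A [calibrate()] result (or a parameter vector).
#' @return 3D cellularity array at `v3_day`.
#' @export
predict_v3 <- function(problem, result) {
  par <- if (is.numeric(result)) result else result$par
  alpha <- par[problem$n_k + 1L]
  if (alpha <= problem$alpha_bounds[1] + 1e-12 &&
      sum(problem$v2[problem$roi]) < sum(problem$v1[problem$roi]))
    warning("alpha is at its lower bound on shrinking data; the model cannot shrink without the therapy term")
  ps <- problem_parameter_set(problem, par)
  sim <- simulate_tumor(ps, problem$v1, t_span = c(0, problem$v3_day),
                        dt = problem$dt)
  sim$snapshots[[length(sim$snapshots)]]
}
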