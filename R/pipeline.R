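# Desk-scale orchestration of the full study: cohort -> feature maps ->
# habitats (H sweep) -> calibrations (global / habitat / local) -> V3
# prediction -> error metrics, optimal-H selection, scheme comparison and
# pCR-surrogate ROC analysis.

#' Derive all quantitative maps for one virtual patient
#'
#' Computes per-visit ADC and cellularity (using the patient minimum tumor
#' ADC across all visits), the requested DCE quantity of interest at V1 and
#' V2, and the drug-concentration map from the baseline DCE.
#'
#' @param vp A [generate_virtual_patient()] object.
#' @param qoi `"MSI"`, `"PEI"` or `"SER"`.
#' @return List with `adc_v1`, `adc_v2`, `q_v1`, `q_v2`, `roi`,
#'   `cellularity` (list of per-visit arrays), `C`, `theta`, `adc_min`.
#' @export
extract_features <- function(vp, qoi = c("MSI", "PEI", "SER")) {
  qoi <- match.arg(qoi)
  adc <- lapply(vp$dwi, function(w) fit_adc(w$s_low, w$s_high, w$b_values))
  adc_min <- patient_adc_min(adc, list(vp$roi_mask$V1, vp$roi_mask$V2,
                                       vp$roi_mask$V3))
  cellularity <- lapply(adc, cellularity_map, adc_min = adc_min,
                        theta = vp$theta)
  qmap <- function(v) {
    rs <- resample_dce(vp$dce[[v]]$signal, vp$dce[[v]]$frame_times)
    switch(qoi,
           MSI = compute_msi(normalize_dce(rs$signal)$signal),
           PEI = compute_pei(normalize_dce(rs$signal)$signal),
           SER = compute_ser(rs$signal, rs$frame_times)$ser)
  }
  rs1 <- resample_dce(vp$dce[[1]]$signal, vp$dce[[1]]$frame_times)
  C <- drug_concentration(normalize_dce(rs1$signal)$signal, vp$breast_mask)
  list(adc_v1 = adc[[1]], adc_v2 = adc[[2]], q_v1 = qmap(1), q_v2 = qmap(2),
       roi = vp$roi, cellularity = cellularity, C = C, theta = vp$theta,
       adc_min = adc_min)
}

#' Study configuration
#'
#' @param phantom A [phantom_config()].
#' @param n_patients Cohort size.
#' @param qoi DCE quantity used to form habitats.
#' @param H_range Habitat counts to sweep (within 2..16).
#' @param schemes Calibration schemes to run.
#' @param threshold_fraction Tumor-bearing volume threshold (fraction of
#'   theta).
#' @param pcr_fraction Responder surrogate: true V3 total cellularity below
#'   this fraction of V1 labels the patient a responder (default 0.05).
#' @param seed Master seed.
#' @param out_dir Optional directory for per-stage caching and reports.
#' @return Object of class `study_config`.
#' @export
study_config <- function(phantom = phantom_config(), n_patients = 5,
                         qoi = "MSI", H_range = 2:4,
                         schemes = c("global", "habitat", "local"),
                         threshold_fraction = 0.25, pcr_fraction = 0.05,
                         seed = 1L, out_dir = NULL) {
  if (any(H_range < 2) || any(H_range > 16))
    stop("H_range must lie within 2..16", call. = FALSE)
  if (!length(schemes)) stop("at least one scheme required", call. = FALSE)
  structure(list(phantom = phantom, n_patients = n_patients, qoi = qoi,
                 H_range = sort(unique(as.integer(H_range))),
                 schemes = match.arg(schemes,
                                     c("global", "habitat", "local"),
                                     several.ok = TRUE),
                 threshold_fraction = threshold_fraction,
                 pcr_fraction = pcr_fraction, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

# Per-stage cache keyed by a hash of the stage inputs.
stage_cache <- function(dir, key, expr) {
  if (is.null(dir)) return(force(expr))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- file.path(dir, paste0("stage-", key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- force(expr)
  saveRDS(val, f)
  val
}

# Fit one patient under one scheme and compute the V2/V3 error metrics
# against the measured (image-derived) cellularity.
fit_and_score <- function(vp, feat, scheme, habitat_map_p, config) {
  problem <- calibration_problem(
    v1 = feat$cellularity[[1]], v2 = feat$cellularity[[2]], roi = vp$roi,
    theta = vp$theta, C = feat$C, schedule = vp$schedule, scheme = scheme,
    habitat_map = habitat_map_p, mechanics = vp$mechanics,
    D0 = vp$config$D0, v2_day = vp$visit_days[2], v3_day = vp$visit_days[3],
    dt = vp$config$dt)
  fit <- calibrate(problem)
  ps <- problem_parameter_set(problem, fit$par)
  sim <- simulate_tumor(ps, problem$v1, t_span = c(0, problem$v3_day),
                        dt = problem$dt,
                        output_times = c(problem$v2_day, problem$v3_day))
  model_v2 <- sim$snapshots[[1]]; model_v3 <- sim$snapshots[[2]]
  d1 <- feat$cellularity[[1]]; d2 <- feat$cellularity[[2]]
  d3 <- feat$cellularity[[3]]
  roi <- vp$roi; th <- config$threshold_fraction
  err <- function(model, data) c(
    ttc = abs(pct_delta_ttc(d1, model, roi) - pct_delta_ttc(d1, data, roi)),
    ttv = abs(pct_delta_ttv(d1, model, vp$theta, th, roi) -
                pct_delta_ttv(d1, data, vp$theta, th, roi)),
    msetc = mse_pct_delta_tc(d1, model, d1, data, roi))
  list(fit = fit,
       v2 = err(model_v2, d2), v3 = err(model_v3, d3),
       pred_ttc_v3 = sum(model_v3[roi]), pred_ttv_v3 = sum(model_v3[roi] >= th * vp$theta),
       wall_time_s = fit$wall_time_s, n_parameters = fit$n_parameters)
}

#' Run the full desk-scale study
#'
#' Executes every stage on a synthetic cohort and assembles the evaluation
#' report: per-patient/per-scheme error tables at V2 and V3, optimal-H
#' selection from the habitat sweep, KS scheme comparisons at the optimal H,
#' a parameter-count/wall-time efficiency table, the habitat connectivity
#' diagnostics, and the pCR-surrogate ROC analysis.
#'
#' @param config A [study_config()].
#' @return Object of class `study_report` (a list; see elements).
#' @export
run_study <- function(config) {
  dir <- config$out_dir
  cohort <- stage_cache(dir, paste0("cohort-", config_hash(
    list(config$phantom, config$n_patients, config$seed))),
    generate_cohort(config$n_patients, config$phantom, seed = config$seed))
  feats <- stage_cache(dir, paste0("features-", config_hash(
    list(config$phantom, config$n_patients, config$seed, config$qoi))),
    lapply(cohort, extract_features, qoi = config$qoi))

  fm <- build_feature_matrix(feats, qoi = config$qoi)
  assignments <- lapply(config$H_range, function(H)
    cluster_habitats(fm, H, seed = derive_seed(config$seed, 1000L + H)))
  names(assignments) <- as.character(config$H_range)

  # Habitat-informed calibrations across the H sweep.
  errors <- list(); efficiency <- list(); predictions <- list()
  run_scheme <- function(scheme, H = NA_integer_, ha = NULL) {
    lapply(seq_along(cohort), function(p) {
      hm <- if (!is.null(ha)) habitat_map(ha, fm, p) else NULL
      fit_and_score(cohort[[p]], feats[[p]], scheme, hm, config)
    })
  }
  if ("habitat" %in% config$schemes) {
    for (H in config$H_range) {
      key <- paste0("cal-habitat-H", H, "-", config_hash(
        list(config$phantom, config$n_patients, config$seed, config$qoi, H)))
      res <- stage_cache(dir, key,
                         run_scheme("habitat", H, assignments[[as.character(H)]]))
      errors[[paste0("habitat_H", H)]] <- res
    }
  }
  for (scheme in setdiff(config$schemes, "habitat")) {
    key <- paste0("cal-", scheme, "-", config_hash(
      list(config$phantom, config$n_patients, config$seed, scheme)))
    errors[[scheme]] <- stage_cache(dir, key, run_scheme(scheme))
  }

  metric_table <- function(res) data.frame(
    patient = seq_along(res),
    ttc_v2 = vapply(res, function(r) r$v2[["ttc"]], numeric(1)),
    ttv_v2 = vapply(res, function(r) r$v2[["ttv"]], numeric(1)),
    msetc_v2 = vapply(res, function(r) r$v2[["msetc"]], numeric(1)),
    ttc_v3 = vapply(res, function(r) r$v3[["ttc"]], numeric(1)),
    ttv_v3 = vapply(res, function(r) r$v3[["ttv"]], numeric(1)),
    msetc_v3 = vapply(res, function(r) r$v3[["msetc"]], numeric(1)))
  tables <- lapply(errors, metric_table)

  # Optimal habitat number from the per-patient V2/V3-averaged metrics.
  h_selection <- NULL
  if ("habitat" %in% config$schemes && length(config$H_range) >= 2) {
    etabs <- lapply(config$H_range, function(H) {
      t <- tables[[paste0("habitat_H", H)]]
      data.frame(ttc = (t$ttc_v2 + t$ttc_v3) / 2,
                 ttv = (t$ttv_v2 + t$ttv_v3) / 2,
                 msetc = (t$msetc_v2 + t$msetc_v3) / 2)
    })
    names(etabs) <- as.character(config$H_range)
    h_selection <- select_optimal_H(etabs)
  }
  H_opt <- if (!is.null(h_selection)) h_selection$H_opt else config$H_range[1]

  # Scheme comparison (KS) at the optimal H.
  comparisons <- NULL
  keys <- c(if ("global" %in% config$schemes) "global",
            if ("habitat" %in% config$schemes) paste0("habitat_H", H_opt),
            if ("local" %in% config$schemes) "local")
  if (length(keys) >= 2) {
    combs <- utils::combn(keys, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      do.call(rbind, lapply(c("ttc_v2", "ttv_v2", "msetc_v2",
                              "ttc_v3", "ttv_v3", "msetc_v3"), function(m)
        data.frame(scheme_a = a, scheme_b = b, metric = m,
                   p = ks_two_sample(tables[[a]][[m]], tables[[b]][[m]])$p_value)))
    }))
  }

  efficiency <- do.call(rbind, lapply(names(errors), function(k) data.frame(
    calibration = k,
    n_parameters = stats::median(vapply(errors[[k]], `[[`, numeric(1),
                                        "n_parameters")),
    median_wall_time_s = stats::median(vapply(errors[[k]], `[[`, numeric(1),
                                              "wall_time_s")))))

  # Habitat connectivity diagnostics at the optimal H.
  connectivity <- NULL
  if ("habitat" %in% config$schemes) {
    ha <- assignments[[as.character(H_opt)]]
    maps <- lapply(seq_along(cohort), function(p) habitat_map(ha, fm, p))
    rois <- lapply(cohort, `[[`, "roi")
    connectivity <- list(
      pct_unneighbored = lapply(seq_along(maps), function(p)
        pct_unneighbored(maps[[p]], rois[[p]], H_opt)),
      shuffle_test = shuffled_connectivity_test(
        maps, rois, H_opt, n_shuffles = 5L,
        seed = derive_seed(config$seed, 777L)),
      semantic_labels = assign_semantic_labels(ha, fm))
  }

  # pCR surrogate ROC: responder = true V3 total cellularity below
  # pcr_fraction of V1 (ground truth); predictors = predicted V3 totals.
  gt_label <- vapply(cohort, function(vp) {
    gt <- vp$ground_truth$cellularity
    as.integer(sum(gt[[3]][vp$roi]) < config$pcr_fraction * sum(gt[[1]][vp$roi]))
  }, integer(1))
  roc <- NULL
  if (length(unique(gt_label)) == 2) {
    roc <- lapply(errors, function(res) {
      scores <- vapply(res, `[[`, numeric(1), "pred_ttc_v3")
      r <- roc_auc(scores, gt_label, orientation = "lower")
      r$roc <- NULL
      r
    })
    meas <- vapply(seq_along(cohort), function(p)
      sum(feats[[p]]$cellularity[[3]][cohort[[p]]$roi]), numeric(1))
    rm <- roc_auc(meas, gt_label, orientation = "lower"); rm$roc <- NULL
    roc$measured <- rm
  }

  structure(list(tables = tables, h_selection = h_selection, H_opt = H_opt,
                 comparisons = comparisons, efficiency = efficiency,
                 connectivity = connectivity, roc = roc,
                 responder = gt_label, config = config),
            class = "study_report")
}
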