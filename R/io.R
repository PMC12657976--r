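# NIfTI / JSON / CSV export of phantoms and study reports.

#' Write a virtual patient to disk
#'
#' Per-visit DWI volumes (one NIfTI per b-value), 4D DCE NIfTI, ROI and
#' breast masks, plus the therapy schedule and ground truth as JSON.
#'
#' @param vp A [generate_virtual_patient()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_virtual_patient <- function(vp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  wr <- function(arr, name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = vp$config$voxel_size_mm), f)
    files <<- c(files, f)
  }
  for (v in seq_along(vp$dwi)) {
    wr(vp$dwi[[v]]$s_low, sprintf("V%d_dwi_b%d", v, vp$dwi[[v]]$b_values[1]))
    wr(vp$dwi[[v]]$s_high, sprintf("V%d_dwi_b%d", v, vp$dwi[[v]]$b_values[2]))
    wr(vp$dce[[v]]$signal, sprintf("V%d_dce", v))
    wr(vp$roi_mask[[v]] * 1L, sprintf("V%d_roi", v))
  }
  wr(vp$breast_mask * 1L, "breast_mask")
  gt <- vp$ground_truth
  meta <- list(
    visit_days = vp$visit_days, theta = vp$theta,
    schedule = list(drugs = vp$schedule$drugs, beta = vp$schedule$beta,
                    dose_days = vp$schedule$dose_days),
    ground_truth = list(k_by_region = gt$k_by_region, alpha = gt$alpha,
                        adc_min = gt$adc_min))
  jf <- file.path(dir, "patient.json")
  jsonlite::write_json(meta, jf, auto_unbox = TRUE, digits = NA)
  wr(gt$region_labels, "true_regions")
  for (v in seq_along(gt$cellularity))
    wr(gt$cellularity[[v]], sprintf("V%d_true_cellularity", v))
  invisible(c(files, jf))
}

#' Write a cohort with a manifest
#'
#' @param cohort List of virtual patients.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(cohort), function(i) {
    pd <- file.path(dir, sprintf("patient%03d", i))
    write_virtual_patient(cohort[[i]], pd)
    data.frame(patient = i, dir = pd,
               n_roi_voxels = sum(cohort[[i]]$roi),
               alpha_true = cohort[[i]]$ground_truth$alpha)
  })
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
  invisible(mf)
}

#' Write habitat label maps and cluster metadata
#'
#' Per-patient habitat maps as integer NIfTI volumes, semantic labels and
#' standardized cluster centers as JSON, and the per-patient connectivity
#' report (percentage of unneighbored voxels per habitat) as CSV.
#'
#' @param ha A [cluster_habitats()] result.
#' @param fm The matching [build_feature_matrix()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_habitat_maps <- function(ha, fm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  conn <- list()
  for (p in seq_along(fm$rois)) {
    hm <- habitat_map(ha, fm, p)
    f <- file.path(dir, sprintf("patient%03d_habitats_H%d.nii.gz", p, ha$H))
    RNifti::writeNifti(RNifti::asNifti(hm), f)
    files <- c(files, f)
    conn[[p]] <- data.frame(patient = p, habitat = seq_len(ha$H),
                            pct_unneighbored = unname(
                              pct_unneighbored(hm, fm$rois[[p]], ha$H)))
  }
  j <- file.path(dir, sprintf("habitats_H%d.json", ha$H))
  jsonlite::write_json(list(H = ha$H, qoi = fm$qoi, sizes = ha$sizes,
                            centers = ha$centers,
                            semantic_labels = assign_semantic_labels(ha, fm)),
                       j, auto_unbox = TRUE, digits = NA, force = TRUE)
  cf <- file.path(dir, sprintf("connectivity_H%d.csv", ha$H))
  utils::write.csv(do.call(rbind, conn), cf, row.names = FALSE)
  invisible(c(files, j, cf))
}

#' Write study report tables
#'
#' Error-metric tables and the efficiency table as CSV, the selection /
#' comparison / ROC results as JSON, and a short Markdown summary.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  for (k in names(report$tables)) {
    f <- file.path(dir, paste0("errors_", k, ".csv"))
    utils::write.csv(report$tables[[k]], f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "efficiency.csv")
  utils::write.csv(report$efficiency, f, row.names = FALSE)
  files <- c(files, f)
  j <- file.path(dir, "report.json")
  jsonlite::write_json(list(H_opt = report$H_opt,
                            h_selection = report$h_selection,
                            roc = report$roc),
                       j, auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- c(files, j)
  md <- file.path(dir, "summary.md")
  lines <- c("# Study summary", "",
             sprintf("- Patients: %d", report$config$n_patients),
             sprintf("- Habitat QoI: %s", report$config$qoi),
             sprintf("- Optimal habitat number: %d", report$H_opt),
             "", "## Median V2 / V3 total-cellularity error (pp)", "")
  for (k in names(report$tables)) {
    t <- report$tables[[k]]
    lines <- c(lines, sprintf("- %s: V2 %.2f, V3 %.2f", k,
                              stats::median(t$ttc_v2), stats::median(t$ttc_v3)))
  }
  writeLines(lines, md)
  invisible(c(files, md))
}
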