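# Error metrics, optimal-habitat-number selection and ROC machinery.

#' Percent change in total tumor cellularity
#'
#' `100 (sum(N_b) - sum(N_a)) / sum(N_a)`, with sums taken over the ROI when
#' one is supplied.
#'
#' @param cell_a,cell_b 3D cellularity arrays at the two timepoints.
#' @param roi Optional logical mask.
#' @return Percent change (scalar).
#' @export
pct_delta_ttc <- function(cell_a, cell_b, roi = NULL) {
  if (!is.null(roi)) { cell_a <- cell_a[roi]; cell_b <- cell_b[roi] }
  sa <- sum(cell_a)
  if (sa == 0) stop("total cellularity at the first timepoint is zero", call. = FALSE)
  100 * (sum(cell_b) - sa) / sa
}

#' Percent change in total tumor volume
#'
#' A voxel is tumor-bearing when its cellularity reaches
#' `threshold_fraction * theta`; total volume is the count of such voxels
#' times the voxel volume (which cancels in the percent change).
#'
#' @param cell_a,cell_b 3D cellularity arrays.
#' @param theta Carrying capacity.
#' @param threshold_fraction Tumor-bearing threshold as a fraction of theta
#'   (default 0.25).
#' @param roi Optional logical mask.
#' @return Percent change (scalar).
#' @export
pct_delta_ttv <- function(cell_a, cell_b, theta, threshold_fraction = 0.25,
                          roi = NULL) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)", call. = FALSE)
  if (!is.null(roi)) { cell_a <- cell_a[roi]; cell_b <- cell_b[roi] }
  va <- sum(cell_a >= threshold_fraction * theta)
  vb <- sum(cell_b >= threshold_fraction * theta)
  if (va == 0) stop("no tumor-bearing voxels at the first timepoint", call. = FALSE)
  100 * (vb - va) / va
}

#' Mean squared error of voxelwise fractional cellularity change
#'
#' The voxelwise change `(N_b - N_a) / max(N_a, eps)` (a fraction, not a
#' percentage; `eps` = 1 cell guards voxels empty at the first timepoint) is
#' computed for model and data, and the mean squared difference over the ROI
#' returned.
#'
#' @param model_a,model_b Model cellularity at the two timepoints.
#' @param data_a,data_b Measured cellularity at the two timepoints.
#' @param roi Logical mask (non-empty).
#' @param eps Guard for empty voxels (default 1 cell).
#' @return Scalar MSE (unitless).
#' @export
mse_pct_delta_tc <- function(model_a, model_b, data_a, data_b, roi, eps = 1) {
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  fm <- (model_b[roi] - model_a[roi]) / pmax(model_a[roi], eps)
  fd <- (data_b[roi] - data_a[roi]) / pmax(data_a[roi], eps)
  mean((fm - fd)^2)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-norm distance between the two empirical CDFs with the asymptotic
#' p-value.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List: `statistic`, `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Normal approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("samples must be non-empty", call. = FALSE)
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$p.value
}

#' Select the optimal habitat number
#'
#' Given per-patient averaged error metrics for each habitat count, returns
#' the smallest H whose three error distributions show no significant
#' two-sample KS difference against every larger H. If no H qualifies the
#' largest H is returned with a flag.
#'
#' @param error_tables Named list (names = H values) of data frames with one
#'   row per patient and the metric columns `ttc`, `ttv`, `msetc` (average of
#'   the V2 and V3 errors per patient).
#' @param alpha Significance level (default 0.05).
#' @return List: `H_opt`, `qualified` (logical), `p_values` (data.frame of
#'   all pairwise tests).
#' @export
select_optimal_H <- function(error_tables, alpha = 0.05) {
  Hs <- sort(as.integer(names(error_tables)))
  if (length(Hs) < 2) stop("need error tables for at least two H values", call. = FALSE)
  metrics <- c("ttc", "ttv", "msetc")
  if (any(vapply(error_tables, nrow, integer(1)) < 2))
    stop("Kolmogorov-Smirnov comparison needs at least two patients per table",
         call. = FALSE)
  rows <- list()
  for (i in seq_along(Hs)) for (j in seq_along(Hs)) if (j > i) {
    for (m in metrics) {
      p <- ks_two_sample(error_tables[[as.character(Hs[i])]][[m]],
                         error_tables[[as.character(Hs[j])]][[m]])$p_value
      rows[[length(rows) + 1L]] <- data.frame(H1 = Hs[i], H2 = Hs[j],
                                              metric = m, p = p)
    }
  }
  pv <- do.call(rbind, rows)
  for (h in Hs[-length(Hs)]) {
    sub <- pv[pv$H1 == h, ]
    if (all(sub$p >= alpha))
      return(list(H_opt = h, qualified = TRUE, p_values = pv))
  }
  list(H_opt = Hs[length(Hs)], qualified = FALSE, p_values = pv)
}

#' ROC analysis of a continuous predictor
#'
#' AUC by the trapezoidal ROC (equivalent to the normalized Mann-Whitney
#' statistic), DeLong 95% confidence interval, and the operating point
#' maximizing Youden's J (equal weight to false positives and negatives).
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (0/1 or logical), both classes present.
#' @param orientation `"higher"` if larger scores indicate the positive
#'   class, `"lower"` otherwise.
#' @return Object of class `roc_result`: `auc`, `ci` (length 2),
#'   `sensitivity`, `specificity`, `threshold`, `orientation`, and the
#'   underlying `pROC::roc` object in `roc`.
#' @export
roc_auc <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1),
                 direction = if (orientation == "higher") "<" else ">",
                 quiet = TRUE)
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]
  structure(list(auc = as.numeric(pROC::auc(r)), ci = ci,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 threshold = best$threshold, orientation = orientation,
                 roc = r),
            class = "roc_result")
}

#' DeLong test for paired AUC difference
#'
#' Two-sided z-test on the difference of correlated AUCs via placement
#' values. Identical score vectors have an AUC difference of exactly zero
#' with zero variance; that degenerate case returns p = 1.
#'
#' @param scores1,scores2 Paired predictors on the same cases.
#' @param labels Binary outcome.
#' @param orientation As in [roc_auc()].
#' @return p-value.
#' @export
delong_test <- function(scores1, scores2, labels,
                        orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  if (length(scores1) != length(scores2))
    stop("paired scores must have equal length", call. = FALSE)
  if (isTRUE(all.equal(scores1, scores2))) return(1)
  labels <- as.integer(as.logical(labels))
  dir <- if (orientation == "higher") "<" else ">"
  r1 <- pROC::roc(labels, scores1, levels = c(0, 1), direction = dir, quiet = TRUE)
  r2 <- pROC::roc(labels, scores2, levels = c(0, 1), direction = dir, quiet = TRUE)
  out <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  p <- out$p.value
  if (!is.finite(p)) stop("degenerate variance in the DeLong test", call. = FALSE)
  p
}
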