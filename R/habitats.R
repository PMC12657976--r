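# Cohort-level longitudinal habitat analysis.
#
# Tumor voxels from all patients are pooled into one matrix of longitudinal
# features {ADC(V1), ADC(V2), Q(V1), Q(V2)} (Q = MSI, PEI or SER), the
# columns standardized, and k-means applied once across the cohort. Habitat
# indices are re-ordered by increasing mean V1 ADC so the numbering is
# deterministic. Spatial-connectivity diagnostics use the 26-neighborhood.

#' Build the pooled longitudinal feature matrix
#'
#' One row per in-ROI voxel per patient; columns ordered
#' `{ADC V1, ADC V2, Q V1, Q V2}`. Columns are standardized to zero mean and
#' unit SD; a zero-variance column is left at zero and flagged.
#'
#' @param features Per-patient list, each element a list with 3D arrays
#'   `adc_v1`, `adc_v2`, `q_v1`, `q_v2` and logical mask `roi`.
#' @param qoi Name of the DCE quantity of interest (metadata only).
#' @return Object of class `feature_matrix`: `X` (standardized), `X_raw`,
#'   `center`, `scale`, `zero_variance` flags, `index` (data.frame patient /
#'   voxel), `rois` (list of masks), `qoi`.
#' @export
build_feature_matrix <- function(features, qoi = "MSI") {
  need <- c("adc_v1", "adc_v2", "q_v1", "q_v2", "roi")
  rows <- lapply(seq_along(features), function(p) {
    f <- features[[p]]
    miss <- setdiff(need, names(f))
    if (length(miss))
      stop(sprintf("patient %d is missing map(s): %s", p,
                   paste(miss, collapse = ", ")), call. = FALSE)
    v <- which(f$roi)
    cbind(adc_v1 = unclass(f$adc_v1)[v], adc_v2 = unclass(f$adc_v2)[v],
          q_v1 = f$q_v1[v], q_v2 = f$q_v2[v])
  })
  X_raw <- do.call(rbind, rows)
  index <- data.frame(
    patient = rep(seq_along(features), vapply(rows, nrow, integer(1))),
    voxel = unlist(lapply(features, function(f) which(f$roi))))
  ctr <- colMeans(X_raw)
  scl <- apply(X_raw, 2, stats::sd)
  zero_var <- !is.finite(scl) | scl <= .Machine$double.eps * pmax(abs(ctr), 1)
  scl[zero_var] <- 1
  X <- sweep(sweep(X_raw, 2, ctr), 2, scl, `/`)
  X[, zero_var] <- 0
  structure(list(X = X, X_raw = X_raw, center = ctr, scale = scl,
                 zero_variance = zero_var, index = index,
                 rois = lapply(features, `[[`, "roi"), qoi = qoi),
            class = "feature_matrix")
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- colSums((t(X) - centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    if (all(d2 <= 0)) {
      centers[j, ] <- X[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
  }
  centers
}

#' Cluster pooled voxels into habitats
#'
#' k-means on the standardized cohort matrix with k-means++ seeding, 10
#' restarts and Lloyd iterations, under a fixed seed. Habitat indices are
#' re-labeled in order of increasing mean (unstandardized) V1 ADC.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param H Habitat count, 2..16.
#' @param seed Integer seed.
#' @param nstart Restarts (default 10).
#' @param iter_max Lloyd iteration cap (default 300).
#' @return Object of class `habitat_assignment`: `H`, `labels` (per fm row),
#'   `centers` (standardized space, re-ordered), `sizes`, `tot_withinss`.
#' @export
cluster_habitats <- function(fm, H, seed = 1L, nstart = 10L, iter_max = 300L) {
  if (H < 2 || H > 16) stop("H must lie in 2..16", call. = FALSE)
  X <- fm$X
  if (nrow(X) < H) stop("fewer rows than habitats", call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(nstart)) {
      ctr <- kmeanspp_centers(X, H)
      km <- suppressWarnings(stats::kmeans(X, centers = ctr,
                                           iter.max = iter_max,
                                           algorithm = "Lloyd"))
      if (any(km$size == 0)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best))
    stop("k-means produced an empty cluster in every restart", call. = FALSE)
  # Deterministic numbering: increasing mean V1 ADC (raw units).
  mean_adc <- vapply(seq_len(H), function(h)
    mean(fm$X_raw[best$cluster == h, 1L]), numeric(1))
  ord <- order(mean_adc)
  relab <- integer(H); relab[ord] <- seq_len(H)
  labels <- relab[best$cluster]
  structure(list(H = H, labels = labels,
                 centers = best$centers[ord, , drop = FALSE],
                 sizes = tabulate(labels, H),
                 tot_withinss = best$tot.withinss, seed = seed),
            class = "habitat_assignment")
}

#' Per-patient habitat label map
#'
#' Slices the single cohort-level assignment back into one patient's 3D
#' label array (0 outside the ROI).
#'
#' @param ha A [cluster_habitats()] result.
#' @param fm The matching [build_feature_matrix()].
#' @param patient Patient index.
#' @return 3D integer array.
#' @export
habitat_map <- function(ha, fm, patient) {
  sel <- fm$index$patient == patient
  out <- array(0L, dim = dim(fm$rois[[patient]]))
  out[fm$index$voxel[sel]] <- ha$labels[sel]
  out
}

#' Semantic high/low labels for each habitat
#'
#' Compares each habitat's mean of each unstandardized feature to the overall
#' mean across all tumor voxels of all patients: strictly greater gives
#' `"high"`, otherwise `"low"` (ties are "low").
#'
#' @param ha A [cluster_habitats()] result.
#' @param fm The matching [build_feature_matrix()].
#' @return H x 4 character matrix with the feature columns of `fm`.
#' @export
assign_semantic_labels <- function(ha, fm) {
  overall <- colMeans(fm$X_raw)
  out <- matrix("low", nrow = ha$H, ncol = ncol(fm$X_raw),
                dimnames = list(paste0("habitat", seq_len(ha$H)),
                                colnames(fm$X_raw)))
  for (h in seq_len(ha$H)) {
    m <- colMeans(fm$X_raw[ha$labels == h, , drop = FALSE])
    out[h, m > overall] <- "high"
  }
  out
}

#' All possible semantic label combinations
#'
#' Enumerates the high/low assignments over the four longitudinal features.
#'
#' @return Data frame of the label combinations (16 rows).
#' @export
habitat_label_combinations <- function() {
  expand.grid(adc_v1 = c("low", "high"), adc_v2 = c("low", "high"),
              q_v1 = c("low", "high"), q_v2 = c("low", "high"),
              stringsAsFactors = FALSE)
}

#' Percentage of unneighbored voxels per habitat
#'
#' For each habitat, the percentage of its voxels with no 26-neighbor (within
#' the ROI) sharing the habitat label. Voxels at the ROI edge use the
#' neighbors that exist. Empty habitats report `NA`.
#'
#' @param labels 3D integer label array (0/NA outside the ROI).
#' @param roi 3D logical mask.
#' @param H Habitat count (default: max label present).
#' @return Named numeric vector of percentages, length H.
#' @export
pct_unneighbored <- function(labels, roi, H = max(labels[roi], na.rm = TRUE)) {
  has_same <- array(FALSE, dim = dim(labels))
  for (r in seq_len(nrow(neighborhood26()))) {
    off <- neighborhood26()[r, ]
    nb_lab <- shift_array(labels, off, fill = NA)
    nb_roi <- shift_array(roi, off, fill = FALSE)
    same <- nb_roi & !is.na(nb_lab) & (nb_lab == labels)
    same[is.na(same)] <- FALSE
    has_same <- has_same | same
  }
  out <- rep(NA_real_, H)
  for (h in seq_len(H)) {
    sel <- roi & !is.na(labels) & labels == h
    if (any(sel)) out[h] <- 100 * mean(!has_same[sel])
  }
  names(out) <- paste0("habitat", seq_len(H))
  out
}

#' Spatial interaction matrix
#'
#' Counts ordered 26-neighbor voxel pairs (center in habitat a, neighbor in
#' habitat b, both inside the ROI) and row-normalizes, so row a sums to one
#' where habitat a is present. Larger diagonal entries indicate higher
#' within-habitat spatial connectivity. This construction is a reconstruction
#' of a co-occurrence-style interaction matrix; see the methods vignette.
#'
#' @inheritParams pct_unneighbored
#' @return H x H matrix; rows of absent habitats are `NA`.
#' @export
spatial_interaction_matrix <- function(labels, roi, H = max(labels[roi], na.rm = TRUE)) {
  counts <- matrix(0, H, H)
  offs <- neighborhood26()
  for (r in seq_len(nrow(offs))) {
    nb_lab <- shift_array(labels, offs[r, ], fill = NA)
    nb_roi <- shift_array(roi, offs[r, ], fill = FALSE)
    ok <- roi & nb_roi & !is.na(labels) & !is.na(nb_lab) &
      labels >= 1L & nb_lab >= 1L
    if (!any(ok)) next
    tab <- table(factor(labels[ok], levels = seq_len(H)),
                 factor(nb_lab[ok], levels = seq_len(H)))
    counts <- counts + unclass(tab)
  }
  rs <- rowSums(counts)
  out <- counts / ifelse(rs > 0, rs, NA_real_)
  out[rs == 0, ] <- NA_real_
  dimnames(out) <- NULL
  out
}

# Mean diagonal entry over present habitats.
diag_interaction_index <- function(labels, roi, H) {
  m <- spatial_interaction_matrix(labels, roi, H)
  mean(diag(m), na.rm = TRUE)
}

#' Shuffled-null test of habitat spatial connectivity
#'
#' For each patient, computes the mean diagonal of the spatial interaction
#' matrix for the true labels and for labels randomly permuted within the ROI
#' (averaged over `n_shuffles` permutations, preserving habitat sizes). The
#' cohort-level distributions are compared with the two-sided Wilcoxon
#' rank-sum test.
#'
#' @param label_maps List of per-patient 3D label arrays.
#' @param rois List of matching ROI masks.
#' @param H Habitat count.
#' @param n_shuffles Permutations per patient (default 10).
#' @param seed Integer seed.
#' @return List: `p_value`, `true_index`, `null_index` (per-patient vectors).
#' @export
shuffled_connectivity_test <- function(label_maps, rois, H, n_shuffles = 10L,
                                       seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  true_idx <- mapply(function(l, r) diag_interaction_index(l, r, H),
                     label_maps, rois)
  null_idx <- with_seed(seed, mapply(function(l, r) {
    v <- which(r)
    mean(vapply(seq_len(n_shuffles), function(s) {
      ls <- l
      ls[v] <- l[v][sample.int(length(v))]
      diag_interaction_index(ls, r, H)
    }, numeric(1)))
  }, label_maps, rois))
  p <- wilcoxon_rank_sum(true_idx, null_idx)
  list(p_value = p, true_index = true_idx, null_index = null_idx)
}
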