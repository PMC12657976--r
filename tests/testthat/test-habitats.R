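# Synthetic per-patient feature sets with controllable cluster structure.
blob_features <- function(n_per = 50, sep = 8, seed = 1) {
  set.seed(seed)
  d <- c(10, 10, 1)
  mk <- function(center) {
    roi <- array(FALSE, d); roi[seq_len(n_per)] <- TRUE
    half <- n_per %/% 2
    grp <- rep(c(0, 1), c(half, n_per - half))
    list(adc_v1 = array(c(rnorm(n_per, 1e-3 + grp * sep * 1e-4, 1e-5),
                          rep(0, prod(d) - n_per)), d),
         adc_v2 = array(c(rnorm(n_per, 1.2e-3 + grp * sep * 1e-4, 1e-5),
                          rep(0, prod(d) - n_per)), d),
         q_v1 = array(c(rnorm(n_per, 0.1 + grp * 0.2, 1e-3),
                        rep(0, prod(d) - n_per)), d),
         q_v2 = array(c(rnorm(n_per, 0.05 + grp * 0.2, 1e-3),
                        rep(0, prod(d) - n_per)), d),
         roi = roi, grp = grp)
  }
  list(mk(), mk())
}

test_that("the pooled feature matrix counts rows and standardizes columns", {
  feats <- blob_features(n_per = 50)
  fm <- build_feature_matrix(feats)
  expect_equal(dim(fm$X), c(100, 4))
  expect_true(all(abs(colMeans(fm$X)) < 1e-8))
  expect_true(all(abs(apply(fm$X, 2, sd) - 1) < 1e-8))
  # concatenating per-patient slices reproduces the global row order
  expect_equal(fm$index$patient, rep(1:2, each = 50))

  # missing map errors with the patient named
  broken <- feats; broken[[2]]$q_v2 <- NULL
  expect_error(build_feature_matrix(broken), "patient 2")

  # constant column is flagged and left at zero
  const <- feats
  for (p in 1:2) const[[p]]$q_v2 <- array(1, dim(const[[p]]$q_v2))
  fmc <- build_feature_matrix(const)
  expect_true(fmc$zero_variance[["q_v2"]])
  expect_true(all(fmc$X[, "q_v2"] == 0))
})

test_that("k-means habitats recover separated blobs and order by V1 ADC", {
  feats <- blob_features(n_per = 60, sep = 10)
  fm <- build_feature_matrix(feats)
  ha <- cluster_habitats(fm, H = 2, seed = 5)
  grp <- unlist(lapply(feats, `[[`, "grp"))
  # partition matches blob membership exactly (up to label order)
  expect_true(all(table(ha$labels, grp) %in% c(0, 60)))
  # habitat 1 has the lower mean V1 ADC by construction of the ordering
  expect_lt(mean(fm$X_raw[ha$labels == 1, 1]), mean(fm$X_raw[ha$labels == 2, 1]))
  # every row sits closest to its own center (brute-force nearest-center)
  d2 <- sapply(seq_len(2), function(h) colSums((t(fm$X) - ha$centers[h, ])^2))
  expect_equal(max.col(-d2), ha$labels)
  # determinism under a fixed seed
  expect_identical(ha$labels, cluster_habitats(fm, 2, seed = 5)$labels)
})

test_that("within-cluster dispersion is non-increasing in H and H-bounds hold", {
  feats <- blob_features(n_per = 40, sep = 4, seed = 3)
  fm <- build_feature_matrix(feats)
  wss <- vapply(2:6, function(H)
    cluster_habitats(fm, H, seed = 2)$tot_withinss, numeric(1))
  expect_true(all(diff(wss) <= 1e-8))
  expect_error(cluster_habitats(fm, 1, seed = 1), "2..16")
  expect_error(cluster_habitats(fm, 17, seed = 1), "2..16")
})

test_that("semantic labels compare habitat means to the cohort mean", {
  feats <- blob_features(n_per = 60, sep = 10)
  fm <- build_feature_matrix(feats)
  ha <- cluster_habitats(fm, H = 2, seed = 5)
  lab <- assign_semantic_labels(ha, fm)
  expect_equal(dim(lab), c(2, 4))
  # blob 1 sits below the overall mean on every feature, blob 2 above
  expect_true(all(lab[1, ] == "low"))
  expect_true(all(lab[2, ] == "high"))
  expect_equal(nrow(habitat_label_combinations()), 16)
  expect_equal(nrow(unique(habitat_label_combinations())), 16)
})

test_that("unneighbored percentages match exhaustive enumeration", {
  # isolated voxel of habitat 2 in a habitat-1 sea, plus a contiguous block
  d <- c(8, 8, 4)
  roi <- array(TRUE, d)
  lab <- array(1L, d)
  lab[1, 1, 1] <- 2L                       # isolated habitat-2 voxel
  lab[6:8, 6:8, 2] <- 2L                   # 9-voxel contiguous block
  lab[8, 8, 3] <- 2L                       # 11th voxel touching the block
  pct <- pct_unneighbored(lab, roi, 2)
  expect_equal(pct[["habitat1"]], 0)
  expect_equal(pct[["habitat2"]], 100 * 1 / 11)
  expect_equal(unname(pct), oracle_pct_unneighbored(lab, roi, 2))

  # 3D checkerboard: 26-neighborhoods contain same-parity voxels -> 0%
  chk <- array(1L + (outer(outer(1:4, 1:4, `+`), 1:4, `+`) %% 2L), c(4, 4, 4))
  roi4 <- array(TRUE, c(4, 4, 4))
  pc <- pct_unneighbored(chk, roi4, 2)
  expect_equal(unname(pc), oracle_pct_unneighbored(chk, roi4, 2))
  expect_equal(unname(pc), c(0, 0))

  # empty habitat reports missing
  expect_true(is.na(pct_unneighbored(array(1L, d), roi, H = 2)[2]))
})

test_that("spatial interaction matrices are row-normalized pair counts", {
  d <- c(4, 4, 4)
  roi <- array(TRUE, d)
  # single habitat: 1x1 matrix equal to 1
  expect_equal(spatial_interaction_matrix(array(1L, d), roi, 1),
               matrix(1, 1, 1))
  # two habitats in disjoint halves: strong diagonal, verified exhaustively
  lab <- array(1L, d); lab[3:4, , ] <- 2L
  m <- spatial_interaction_matrix(lab, roi, 2)
  expect_equal(m, oracle_interaction(lab, roi, 2), tolerance = 1e-12)
  expect_equal(rowSums(m), c(1, 1), tolerance = 1e-12)
  expect_true(all(diag(m) > 0.6))
  # random labels still row-normalize
  set.seed(1)
  labr <- array(sample(1:3, prod(d), TRUE), d)
  mr <- spatial_interaction_matrix(labr, roi, 3)
  expect_equal(mr, oracle_interaction(labr, roi, 3), tolerance = 1e-12)
  expect_equal(unname(rowSums(mr)), rep(1, 3), tolerance = 1e-12)
})

test_that("contiguous habitats beat their shuffled null; random ones do not", {
  cfg <- tiny_config(grid = c(10, 10, 6))
  cohort_labels <- lapply(1:8, function(i) {
    b <- generate_cellularity_field(cfg, seed = 100 + i)
    list(lab = b$region_labels, roi = b$roi)
  })
  maps <- lapply(cohort_labels, `[[`, "lab")
  rois <- lapply(cohort_labels, `[[`, "roi")
  res <- shuffled_connectivity_test(maps, rois, H = 3, n_shuffles = 5, seed = 2)
  expect_lt(res$p_value, 0.05)
  expect_gt(median(res$true_index), median(res$null_index))

  # labels that are already random should usually not look connected
  big_p <- vapply(1:6, function(s) {
    rnd <- lapply(seq_along(maps), function(i) {
      l <- maps[[i]]; v <- which(rois[[i]])
      set.seed(1000 * s + i)
      l[v] <- sample(l[v])
      l
    })
    shuffled_connectivity_test(rnd, rois, H = 3, n_shuffles = 5,
                               seed = s)$p_value
  }, numeric(1))
  expect_gte(sum(big_p > 0.05), 5)
  expect_error(shuffled_connectivity_test(maps, rois, 3, n_shuffles = 0), ">= 1")
})
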