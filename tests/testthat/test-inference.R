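test_that("bonferroni alpha is exactly base over n", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("connected-component labeling matches an igraph oracle", {
  skip_if_not_installed("igraph")
  dims <- c(10, 9, 7)
  set.seed(101)
  for (conn in c(6L, 26L)) {
    for (rep in 1:4) {
      vox <- sample(prod(dims), 140)
      comps <- label_clusters(vox, dims, conn)
      # oracle: graph over the voxel set, edges between neighbors
      coords <- arrayInd(vox, dims)
      edges <- c()
      for (i in seq_along(vox)) {
        for (j in seq_along(vox)) {
          if (i >= j) next
          d <- abs(coords[i, ] - coords[j, ])
          adj <- if (conn == 6) sum(d) == 1 else max(d) == 1
          if (adj) edges <- c(edges, i, j)
        }
      }
      g <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
      memb <- igraph::components(g)$membership
      oracle <- lapply(split(vox, memb), sort)
      got <- lapply(comps, sort)
      expect_setequal(
        vapply(got, paste, character(1), collapse = ","),
        vapply(oracle, paste, character(1), collapse = ","))
    }
  }
})

test_that("ROI volume thresholding cuts exactly at 1500 mm^3", {
  # 96 voxels x 2.5^3 mm^3 = 1500 exactly: retained; 95 voxels: dropped
  geom <- volume_geometry(c(20, 10, 6), mask = array(TRUE, c(20, 10, 6)))
  expect_equal(voxel_volume_mm3(geom), 15.625)
  blob96 <- which(array(
    slice.index(array(0, geom$dim), 1) <= 8 &
      slice.index(array(0, geom$dim), 2) <= 4 &
      slice.index(array(0, geom$dim), 3) <= 3, geom$dim))
  expect_length(blob96, 96)
  rs <- extract_rois(blob96, geom, 1500)
  expect_length(rs$rois, 1)
  expect_equal(rs$rois[[1]]$volume_mm3, 1500)
  rs95 <- extract_rois(blob96[-1], geom, 1500)
  expect_length(rs95$rois, 0)
  # empty suprathreshold set is an empty ROISet, not an error
  expect_length(extract_rois(integer(0), geom, 1500)$rois, 0)
})

test_that("overlapping ROIs keep only the larger one", {
  geom <- volume_geometry(c(12, 12, 6), mask = array(TRUE, c(12, 12, 6)))
  a <- extract_rois(1:200, geom, min_volume_mm3 = 100, source = "mapA")
  b <- extract_rois(150:269, geom, min_volume_mm3 = 100, source = "mapB")
  merged <- resolve_roi_overlaps(list(a, b))
  expect_length(merged$rois, 1)
  expect_equal(merged$rois[[1]]$n_voxels, 200)
  expect_match(attr(merged, "overlap_log")[1], "dropped")
  # disjoint ROIs are both kept
  c2 <- extract_rois(300:420, geom, min_volume_mm3 = 100, source = "mapC")
  both <- resolve_roi_overlaps(list(a, c2))
  expect_length(both$rois, 2)
})

test_that("cluster FWE finds a strong planted blob and reports valid p", {
  geom <- volume_geometry(c(10, 10, 8), mask = array(TRUE, c(10, 10, 8)))
  midx <- mask_indices(geom)
  set.seed(103)
  n_sub <- 12
  blob <- which(array(
    slice.index(array(0, geom$dim), 1) %in% 4:6 &
      slice.index(array(0, geom$dim), 2) %in% 4:6 &
      slice.index(array(0, geom$dim), 3) %in% 3:5, geom$dim))
  maps <- t(sapply(seq_len(n_sub), function(p) {
    v <- stats::rnorm(length(midx), 0, 1)
    v[match(blob, midx)] <- v[match(blob, midx)] + 2.5
    v
  }))
  cf <- cluster_fwe(maps, geometry = geom, voxels = midx, n_perm = 500,
                    cft_p = 0.001, alpha = 0.025, seed = 9L)
  expect_gt(nrow(cf$clusters), 0)
  expect_true(any(cf$clusters$significant))
  expect_true(all(cf$clusters$p_fwe > 0 & cf$clusters$p_fwe <= 1))
  expect_equal(cf$clusters$volume_mm3,
               cf$clusters$n_voxels * voxel_volume_mm3(geom))
  # the winning cluster overlaps the blob
  big <- cf$cluster_voxels[[which.max(cf$clusters$n_voxels)]]
  expect_gt(length(intersect(big, blob)) / length(big), 0.5)
})

test_that("degenerate zero-variance voxels are excluded, not fatal", {
  geom <- volume_geometry(c(6, 6, 4), mask = array(TRUE, c(6, 6, 4)))
  midx <- mask_indices(geom)
  set.seed(104)
  maps <- matrix(stats::rnorm(8 * length(midx)), 8)
  maps[, 1:5] <- 1  # identical across participants: zero variance
  expect_warning(
    cf <- cluster_fwe(maps, geometry = geom, voxels = midx, n_perm = 200,
                      seed = 2L),
    "zero-variance")
  expect_equal(cf$n_excluded_voxels, 5)
  expect_true(all(is.na(cf$t_map[midx[1:5]])))
})

test_that("roi_phase_lme recovers a planted phase effect on reinstatement", {
  set.seed(105)
  n <- 20
  tab <- expand.grid(participant = seq_len(n),
                     phase = c("acquisition", "reversal"),
                     cs_type = cs_types(), stringsAsFactors = FALSE)
  b <- stats::rnorm(n, 0, 0.05)
  tab$value <- 0.1 + 0.08 * (tab$phase == "reversal") + b[tab$participant] +
    stats::rnorm(nrow(tab), 0, 0.05)
  res <- roi_phase_lme(tab)
  expect_lt(res$fixed$p[res$fixed$term == "phase"], 0.001)
  expect_gt(res$fixed$p[res$fixed$term == "cs_type"], 0.01)
  expect_false(res$singular)
  expect_error(roi_phase_lme(within(tab, value <- 1)), "constant")
  expect_error(roi_phase_lme(tab[tab$participant == 1, ]), "2 participants")
})

test_that("specificity linkage recovers a planted interaction and FDR works", {
  set.seed(106)
  n <- 24
  spec_v <- stats::rnorm(n, 0, 1)
  b <- stats::rnorm(n, 0, 0.1)
  mk <- function(slope_minus, slope_plus, noise) {
    data.frame(
      participant = rep(seq_len(n), 2),
      cs_type = rep(c("CS-+", "CS+-"), each = n),
      specificity = rep(spec_v, 2),
      reinstatement = c(b + slope_minus * spec_v,
                        b + slope_plus * spec_v) +
        stats::rnorm(2 * n, 0, noise)
    )
  }
  res <- suppressWarnings(
    specificity_reinstatement_lme(mk(-0.2, 0.2, 0.1), "generalized"))
  expect_gt(res$interaction$estimate[1], 0)
  expect_lt(res$interaction$p[1], 0.01)
  expect_gt(res$slopes$slope[res$slopes$cs_type == "CS+-"],
            res$slopes$slope[res$slopes$cs_type == "CS-+"])
  null_res <- suppressWarnings(
    specificity_reinstatement_lme(mk(0, 0, 0.1), "item"))
  pair <- linkage_pair_fdr(null_res, res)
  expect_true(all(pair$p_fdr >= pair$p_raw - 1e-12))
  expect_equal(nrow(pair), 2)
  # missing cue type errors
  bad <- mk(0, 0, 0.1)
  expect_error(
    specificity_reinstatement_lme(bad[bad$cs_type == "CS-+", ]),
    "missing cue type")
  expect_error(
    specificity_reinstatement_lme(bad[bad$participant == 1, ]),
    "2 participants")
})

test_that("cluster volume bookkeeping conserves suprathreshold voxels", {
  geom <- volume_geometry(c(8, 8, 6), mask = array(TRUE, c(8, 8, 6)))
  set.seed(107)
  supra <- sample(prod(geom$dim), 60)
  comps <- label_clusters(supra, geom$dim, 26)
  expect_equal(sum(lengths(comps)), length(supra))
  expect_setequal(unlist(comps), supra)
})
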