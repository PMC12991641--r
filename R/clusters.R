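neighbor_offsets <- function(connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  offs
}

#' Label connected components of a voxel set
#'
#' Breadth-first 3D connected-component labeling under 6- or
#' 26-connectivity.
#'
#' @param voxel_indices linear voxel indices (column-major) of the set.
#' @param dims length-3 grid shape.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return list of integer vectors, one per component (linear voxel
#'   indices), in decreasing size order.
#' @export
label_clusters <- function(voxel_indices, dims, connectivity = 26) {
  n <- length(voxel_indices)
  if (!n) return(list())
  lab <- array(0L, dims)
  lab[voxel_indices] <- -1L
  offs <- neighbor_offsets(connectivity)
  coords <- arrayInd(voxel_indices, dims)
  comps <- list()
  for (i in seq_len(n)) {
    v <- voxel_indices[i]
    if (lab[v] != -1L) next
    id <- length(comps) + 1L
    lab[v] <- id
    members <- v
    frontier <- coords[i, , drop = FALSE]
    while (nrow(frontier)) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                       drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + (cand[, 2] - 1) * dims[1] +
                      (cand[, 3] - 1) * dims[1] * dims[2])
      lin <- lin[lab[lin] == -1L]
      if (!length(lin)) break
      lab[lin] <- id
      members <- c(members, lin)
      frontier <- arrayInd(lin, dims)
    }
    comps[[id]] <- sort(members)
  }
  comps[order(-lengths(comps))]
}

#' Bonferroni-adjusted alpha threshold
#'
#' The cluster-significance threshold applied to FWE-corrected p-values when
#' several contrasts are tested per phase: `base_alpha / n_comparisons`
#' (0.05 / 2 = 0.025; 0.05 / 4 = 0.0125).
#'
#' @param base_alpha base alpha (default 0.05).
#' @param n_comparisons number of comparisons in the family.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_comparisons) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1")
  base_alpha / n_comparisons
}

#' Nonparametric cluster-level FWE inference on participant maps
#'
#' One-sample group test of per-participant contrast maps: voxelwise t
#' statistic, clusters formed at the one-sided voxel threshold
#' `qt(1 - cft_p, n - 1)`, and a null distribution of the maximum cluster
#' size built by random sign flipping of whole participant maps. Cluster
#' `p_fwe = (1 + #(null max >= observed size)) / (1 + n_perm)`; clusters are
#' significant iff `p_fwe < alpha` (pass a Bonferroni-adjusted alpha from
#' [bonferroni_alpha()] when several contrasts share a phase).
#'
#' @param maps list of `searchlight_map`s, or a participants x voxels matrix
#'   with `voxels` giving the linear indices of its columns.
#' @param geometry a `volume_geometry` (taken from maps when omitted).
#' @param voxels linear voxel indices for matrix input.
#' @param n_perm number of sign-flip permutations (default 10000).
#' @param cft_p cluster-forming (uncorrected, one-sided) p threshold.
#' @param alpha adjusted significance threshold for `p_fwe`.
#' @param connectivity 6 or 26 (default 26).
#' @param seed integer seed for the sign flips.
#' @return object of class `cluster_fwe`: `t_map` (3D array), `clusters`
#'   data.frame (`cluster`, `n_voxels`, `volume_mm3`, `peak_t`, `p_fwe`,
#'   `significant`), `cluster_voxels` (list), `null_max_size`,
#'   `n_excluded_voxels` (zero-variance), and the parameters.
#' @export
cluster_fwe <- function(maps, geometry = NULL, voxels = NULL, n_perm = 10000,
                        cft_p = 0.001, alpha = 0.05, connectivity = 26,
                        seed = 1L) {
  if (is.list(maps) && inherits(maps[[1]], "searchlight_map")) {
    geometry <- maps[[1]]$geometry
    defined <- Reduce(`&`, lapply(maps, function(m) !is.na(m$values)))
    voxels <- which(defined)
    m <- do.call(rbind, lapply(maps, function(mm) mm$values[voxels]))
  } else {
    m <- as.matrix(maps)
    if (is.null(voxels) || is.null(geometry)) {
      stop("matrix input needs `voxels` and `geometry`")
    }
    if (ncol(m) != length(voxels)) stop("maps are not voxel-aligned")
  }
  n <- nrow(m)
  if (n < 2) stop("need at least 2 participant maps")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")

  mu <- colMeans(m)
  ss <- colSums(m^2)
  sd2 <- (ss - n * mu^2) / (n - 1)
  bad <- sd2 <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance voxel(s) excluded from inference")
    m <- m[, !bad, drop = FALSE]
    voxels <- voxels[!bad]
    mu <- mu[!bad]; ss <- ss[!bad]; sd2 <- sd2[!bad]
  }
  tval <- mu / sqrt(sd2 / n)
  thresh <- stats::qt(1 - cft_p, df = n - 1)
  dims <- geometry$dim

  obs <- label_clusters(voxels[tval > thresh], dims, connectivity)

  set.seed(seed)
  null_max <- numeric(n_perm)
  block <- 500L
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    s <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    means <- s %*% m / n
    tmat <- means / sqrt(pmax(
      sweep(-n * means^2, 2, ss, "+") / (n - 1), 0) / n)
    for (b in seq_len(nb)) {
      supra <- voxels[tmat[b, ] > thresh]
      null_max[done + b] <- if (length(supra)) {
        max(lengths(label_clusters(supra, dims, connectivity)))
      } else 0
    }
    done <- done + nb
  }

  sizes <- lengths(obs)
  p_fwe <- vapply(sizes, function(sz) (1 + sum(null_max >= sz)) / (1 + n_perm),
                  numeric(1))
  t_map <- array(NA_real_, dims)
  t_map[voxels] <- tval
  clusters <- data.frame(
    cluster = seq_along(obs),
    n_voxels = sizes,
    volume_mm3 = sizes * voxel_volume_mm3(geometry),
    peak_t = vapply(obs, function(vx) max(t_map[vx]), numeric(1)),
    p_fwe = p_fwe,
    significant = p_fwe < alpha
  )
  if (!length(obs)) clusters <- clusters[0, ]
  structure(
    list(t_map = t_map, clusters = clusters, cluster_voxels = obs,
         null_max_size = null_max, n_excluded_voxels = sum(bad),
         n_perm = n_perm, cft_p = cft_p, alpha = alpha,
         connectivity = connectivity, geometry = geometry),
    class = "cluster_fwe"
  )
}

#' @export
print.cluster_fwe <- function(x, ...) {
  cat(sprintf("cluster_fwe: %d cluster(s) at cft p<%g, alpha %g, %d perms\n",
              nrow(x$clusters), x$cft_p, x$alpha, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, digits = 3)
  invisible(x)
}

#' Extract volume-thresholded ROIs from a thresholded map
#'
#' Labels connected components of a boolean suprathreshold set and retains
#' those with volume at least `min_volume_mm3` (1500 mm^3 = 96 voxels at
#' 2.5 mm isotropic).
#'
#' @param supra logical 3D array or linear voxel indices.
#' @param geometry a `volume_geometry`.
#' @param min_volume_mm3 minimum ROI volume.
#' @param connectivity 6 or 26.
#' @param source label recorded for provenance (e.g. contrast/phase).
#' @return object of class `roi_set`: list of ROIs (`name`, `voxels`,
#'   `n_voxels`, `volume_mm3`, `source`); empty when nothing survives.
#' @export
extract_rois <- function(supra, geometry, min_volume_mm3 = 1500,
                         connectivity = 26, source = "map") {
  if (is.logical(supra)) supra <- which(supra)
  comps <- label_clusters(supra, geometry$dim, connectivity)
  vv <- voxel_volume_mm3(geometry)
  rois <- list()
  for (i in seq_along(comps)) {
    vol <- length(comps[[i]]) * vv
    if (vol >= min_volume_mm3) {
      rois[[length(rois) + 1]] <- list(
        name = sprintf("%s_roi%d", source, length(rois) + 1),
        voxels = comps[[i]], n_voxels = length(comps[[i]]),
        volume_mm3 = vol, source = source
      )
    }
  }
  structure(list(rois = rois, geometry = geometry,
                 min_volume_mm3 = min_volume_mm3),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d ROI(s) >= %g mm^3\n", length(x$rois),
              x$min_volume_mm3))
  for (r in x$rois) {
    cat(sprintf("  %s: %d voxels (%.1f mm^3)\n", r$name, r$n_voxels,
                r$volume_mm3))
  }
  invisible(x)
}

#' Resolve overlaps between ROIs from different source maps
#'
#' When two ROIs share voxels, only the one with the larger voxel count is
#' retained; each application of the rule is logged.
#'
#' @param roi_sets list of `roi_set`s (or one).
#' @return a `roi_set` of the retained ROIs with an `overlap_log` attribute.
#' @export
resolve_roi_overlaps <- function(roi_sets) {
  if (inherits(roi_sets, "roi_set")) roi_sets <- list(roi_sets)
  rois <- do.call(c, lapply(roi_sets, function(s) s$rois))
  keep <- rep(TRUE, length(rois))
  log <- character(0)
  if (length(rois) > 1) {
    ord <- order(-vapply(rois, function(r) r$n_voxels, numeric(1)))
    rois <- rois[ord]
    for (i in seq_along(rois)) {
      if (!keep[i]) next
      for (j in seq_along(rois)) {
        if (j <= i || !keep[j]) next
        if (length(intersect(rois[[i]]$voxels, rois[[j]]$voxels))) {
          keep[j] <- FALSE
          log <- c(log, sprintf("dropped %s (%d vox) overlapping %s (%d vox)",
                                rois[[j]]$name, rois[[j]]$n_voxels,
                                rois[[i]]$name, rois[[i]]$n_voxels))
        }
      }
    }
  }
  out <- structure(
    list(rois = rois[keep], geometry = roi_sets[[1]]$geometry,
         min_volume_mm3 = roi_sets[[1]]$min_volume_mm3),
    class = "roi_set"
  )
  attr(out, "overlap_log") <- log
  out
}
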