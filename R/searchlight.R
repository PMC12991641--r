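#' Cubic searchlight neighborhoods
#'
#' For every in-mask center voxel, the cubic box of half-width
#' `round(radius_mm / voxel_size)` voxels per axis (radius 5 mm at 2.5 mm
#' voxels: +/-2 voxels, 125 positions). Centers are retained only if at
#' least `min_in_mask_frac` of the full ideal box (out-of-bounds positions
#' counted against the fraction) lies inside the mask. Members are the
#' in-mask, in-bounds box voxels.
#'
#' @param geometry a `volume_geometry`.
#' @param radius_mm searchlight radius in mm (default 5, i.e. twice the
#'   default voxel size).
#' @param min_in_mask_frac minimum in-mask fraction for a retained center.
#' @return object of class `neighborhood_set`: `centers` (linear voxel
#'   indices), `members` (list of integer vectors indexing into
#'   `mask_indices(geometry)`), `center_cols` (centers as columns of the
#'   masked voxel axis), `radius_mm`, `half_width`.
#' @export
build_neighborhoods <- function(geometry, radius_mm = 5.0,
                                min_in_mask_frac = 0.5) {
  vs <- geometry$voxel_size_mm
  if (radius_mm < vs) stop("radius_mm must be at least one voxel size")
  w <- as.integer(round(radius_mm / vs))
  dims <- geometry$dim
  offs <- as.matrix(expand.grid(dx = -w:w, dy = -w:w, dz = -w:w))
  box_n <- nrow(offs)

  midx <- mask_indices(geometry)
  col_of <- array(0L, dims)
  col_of[midx] <- seq_along(midx)
  coords <- arrayInd(midx, dims)

  centers <- integer(0)
  members <- list()
  center_cols <- integer(0)
  for (i in seq_along(midx)) {
    p <- coords[i, ]
    xs <- p[1] + offs[, 1]; ys <- p[2] + offs[, 2]; zs <- p[3] + offs[, 3]
    inb <- xs >= 1 & xs <= dims[1] & ys >= 1 & ys <= dims[2] &
      zs >= 1 & zs <= dims[3]
    lin <- xs[inb] + (ys[inb] - 1) * dims[1] +
      (zs[inb] - 1) * dims[1] * dims[2]
    memb_cols <- col_of[lin]
    memb_cols <- memb_cols[memb_cols > 0L]
    if (length(memb_cols) / box_n >= min_in_mask_frac) {
      centers <- c(centers, midx[i])
      members[[length(members) + 1]] <- memb_cols
      center_cols <- c(center_cols, i)
    }
  }
  if (!length(centers)) stop("no searchlight centers retained")
  structure(
    list(centers = centers, members = members, center_cols = center_cols,
         radius_mm = radius_mm, half_width = w, geometry = geometry,
         box_size = box_n),
    class = "neighborhood_set"
  )
}

#' @export
print.neighborhood_set <- function(x, ...) {
  cat(sprintf(
    "neighborhood_set: %d centers, half-width %d voxels (box %d), radius %.1f mm\n",
    length(x$centers), x$half_width, x$box_size, x$radius_mm))
  invisible(x)
}

#' Map an RSA metric over the brain with a searchlight
#'
#' At each retained center, restricts the beta series (or pair of series) to
#' the neighborhood's member voxels, applies `metric_fun`, and writes the
#' scalar to the map. A metric error at a center leaves that voxel undefined
#' (logged via warning count), it is not fatal.
#'
#' @param series a `beta_series`, or list of them (passed through to
#'   `metric_fun`).
#' @param neighborhoods a `neighborhood_set`.
#' @param metric_fun function taking the voxel-restricted series (same shape
#'   as `series`) and returning one number.
#' @return object of class `searchlight_map`: `values` (3D array, `NA`
#'   outside retained centers), `geometry`, `n_failed`.
#' @export
run_searchlight <- function(series, neighborhoods, metric_fun) {
  geometry <- neighborhoods$geometry
  vol <- array(NA_real_, geometry$dim)
  n_failed <- 0L
  single <- inherits(series, "beta_series")
  for (k in seq_along(neighborhoods$centers)) {
    vox <- neighborhoods$members[[k]]
    sub <- if (single) subset_voxels(series, vox) else
      lapply(series, subset_voxels, voxels = vox)
    val <- tryCatch(metric_fun(sub), error = function(e) NA_real_)
    if (is.na(val)) n_failed <- n_failed + 1L
    vol[neighborhoods$centers[k]] <- val
  }
  if (n_failed > 0) {
    warning(n_failed, " searchlight center(s) returned undefined values")
  }
  structure(
    list(values = vol, geometry = geometry, n_failed = n_failed),
    class = "searchlight_map"
  )
}

#' @export
print.searchlight_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("searchlight_map: %d defined voxels, range [%.3f, %.3f]\n",
              length(v), min(v), max(v)))
  invisible(x)
}

masked_mean <- function(z, mask) mean(z[mask], na.rm = TRUE)

#' Searchlight metric: cue-generalization contrast between CS-type groups
#'
#' Returns a function computing mean cue generalization of `plus_types`
#' minus that of `minus_types` from a within-phase cue RSM built locally.
#' Pair masks depend only on trial metadata, so they are computed once at
#' the first center and reused.
#'
#' @param plus_types,minus_types CS-type labels entering each side.
#' @param restrict_unreinforced passed to the metric.
#' @export
sl_cue_generalization_contrast <- function(plus_types, minus_types,
                                           restrict_unreinforced = TRUE) {
  masks <- NULL
  function(series) {
    rsm <- build_rsm(series)
    if (is.null(masks)) {
      types <- c(plus_types, minus_types)
      masks <<- lapply(types, function(cs) {
        m <- outer(rsm$meta_row$cs_type == cs, rsm$meta_col$cs_type == cs,
                   "&") & outer(rsm$meta_row$cue_id, rsm$meta_col$cue_id,
                                "!=")
        if (restrict_unreinforced) {
          m <- m & outer(!rsm$meta_row$reinforced, !rsm$meta_col$reinforced,
                         "&")
        }
        m
      })
      names(masks) <<- types
    }
    vals <- vapply(masks, masked_mean, numeric(1), z = rsm$z)
    mean(vals[plus_types]) - mean(vals[minus_types])
  }
}

#' Searchlight metric: item-stability contrast between CS-type groups
#' @inheritParams sl_cue_generalization_contrast
#' @export
sl_item_stability_contrast <- function(plus_types, minus_types,
                                       restrict_unreinforced = TRUE) {
  masks <- NULL
  cs_of <- NULL
  function(series) {
    rsm <- build_rsm(series)
    if (is.null(masks)) {
      cues <- sort(unique(rsm$meta_row$cue_id))
      masks <<- lapply(cues, function(cue) {
        m <- outer(rsm$meta_row$cue_id == cue, rsm$meta_col$cue_id == cue,
                   "&")
        diag(m) <- FALSE
        if (restrict_unreinforced) {
          m <- m & outer(!rsm$meta_row$reinforced, !rsm$meta_col$reinforced,
                         "&")
        }
        m
      })
      names(masks) <<- cues
      cs_of <<- rsm$meta_row$cs_type[match(cues, rsm$meta_row$cue_id)]
    }
    per_cue <- vapply(masks, masked_mean, numeric(1), z = rsm$z)
    per_cs <- tapply(per_cue, cs_of, mean)
    mean(per_cs[plus_types]) - mean(per_cs[minus_types])
  }
}

#' Searchlight metric: context-specificity difference between two phases
#'
#' Expects `series` to be a list of two context-model `beta_series`
#' (first minus second).
#' @param restrict_unreinforced passed to the metric.
#' @export
sl_context_specificity_diff <- function(restrict_unreinforced = TRUE) {
  cache <- list()
  spec_masks <- function(rsm) {
    same <- outer(rsm$meta_row$context_id, rsm$meta_col$context_id, "==")
    keep <- !diag(TRUE, nrow(same))
    if (restrict_unreinforced) {
      keep <- keep & outer(!rsm$meta_row$reinforced, !rsm$meta_col$reinforced,
                           "&")
    }
    list(within = same & keep, between = !same & keep)
  }
  function(series) {
    val <- numeric(2)
    for (i in 1:2) {
      rsm <- build_rsm(series[[i]])
      if (length(cache) < i) cache[[i]] <<- spec_masks(rsm)
      val[i] <- masked_mean(rsm$z, cache[[i]]$within) -
        masked_mean(rsm$z, cache[[i]]$between)
    }
    val[1] - val[2]
  }
}
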