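#' Volume geometry for synthetic BOLD data
#'
#' Describes the scanning grid the generator writes into: voxel grid shape,
#' isotropic voxel size, repetition time, and a boolean brain mask. Defaults
#' follow a typical 3T EPI protocol (2.5 mm isotropic, TR 2.53 s) at a
#' desk-scale grid small enough that searchlight and permutation machinery run
#' in minutes.
#'
#' @param dim integer length-3 grid shape (x, y, z).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param tr_s repetition time in seconds.
#' @param mask logical array of `dim` marking in-brain voxels; default is an
#'   inscribed ellipsoid.
#' @return an object of class `volume_geometry`.
#' @export
volume_geometry <- function(dim = c(18, 18, 12), voxel_size_mm = 2.5,
                            tr_s = 2.53, mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_size_mm > 0, tr_s > 0)
  if (is.null(mask)) mask <- ellipsoid_mask(dim)
  stopifnot(is.logical(mask), all(dim(mask) == dim))
  if (!any(mask)) stop("mask is empty")
  structure(
    list(dim = dim, voxel_size_mm = voxel_size_mm, tr_s = tr_s, mask = mask),
    class = "volume_geometry"
  )
}

#' Ellipsoidal brain-like mask inscribed in a grid
#' @param dim integer length-3 grid shape.
#' @return logical array.
#' @export
ellipsoid_mask <- function(dim) {
  cx <- (dim + 1) / 2
  semi <- dim / 2
  idx <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  d2 <- ((idx$x - cx[1]) / semi[1])^2 + ((idx$y - cx[2]) / semi[2])^2 +
    ((idx$z - cx[3]) / semi[3])^2
  array(d2 <= 1, dim = dim)
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf(
    "volume_geometry: %dx%dx%d voxels at %.2f mm, TR %.2f s, %d in-mask\n",
    x$dim[1], x$dim[2], x$dim[3], x$voxel_size_mm, x$tr_s, sum(x$mask)
  ))
  invisible(x)
}

#' Linear indices of in-mask voxels
#' @param geometry a `volume_geometry`.
#' @return integer vector of linear voxel indices (column-major).
#' @export
mask_indices <- function(geometry) which(geometry$mask)

#' Voxel volume in cubic millimetres
#' @param geometry a `volume_geometry`.
#' @export
voxel_volume_mm3 <- function(geometry) geometry$voxel_size_mm^3

#' Affine matrix (voxel index to world mm) for NIfTI export
#' @param geometry a `volume_geometry`.
#' @return 4x4 numeric matrix, scaled identity orientation.
#' @export
geometry_affine <- function(geometry) {
  a <- diag(c(rep(geometry$voxel_size_mm, 3), 1))
  a
}
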