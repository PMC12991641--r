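#' Write a phase design as a BIDS-events-style table
#'
#' Long format, tab-separated: one row per event with columns `onset` (s,
#' 0 = phase start), `duration` (s), `event_type` (context/cue/rating/us),
#' `cue_id`, `context_id`, `cs_type`, `reinforced` (0/1), `phase`.
#'
#' @param design a scheduled `phase_design`.
#' @param path output file path (`.tsv`).
#' @export
write_events <- function(design, path) {
  row_for <- function(onset, duration, type) {
    data.frame(
      onset = onset, duration = duration, event_type = type,
      cue_id = design$cue_id, context_id = design$context_id,
      cs_type = design$cs_type, reinforced = as.integer(design$reinforced),
      phase = design$phase
    )
  }
  ev <- rbind(
    row_for(design$onset_context, design$onset_cue - design$onset_context,
            "context"),
    row_for(design$onset_cue, design$onset_rating - design$onset_cue, "cue"),
    row_for(design$onset_rating, design$onset_iti - design$onset_rating,
            "rating"),
    row_for(design$onset_us, 0, "us")[design$reinforced, ]
  )
  ev <- ev[order(ev$onset, match(ev$event_type,
                                 c("context", "cue", "rating", "us"))), ]
  rownames(ev) <- NULL
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events table written by [write_events()]
#' @param path events `.tsv` path.
#' @return data.frame of events; malformed columns raise a named error.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "event_type", "cue_id", "context_id",
            "cs_type", "reinforced", "phase")
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    stop("events table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(ev$event_type %in% c("context", "cue", "rating", "us"))) {
    stop("events table contains unknown event_type values")
  }
  ev
}

#' Reconstruct a `phase_design` from an events table
#' @param events data.frame from [read_events()].
#' @return a `phase_design` with onset columns (ITI durations recovered from
#'   consecutive context onsets; the final trial's ITI is `NA`).
#' @export
events_to_design <- function(events) {
  cue <- events[events$event_type == "cue", ]
  ctx <- events[events$event_type == "context", ]
  rat <- events[events$event_type == "rating", ]
  us <- events[events$event_type == "us", ]
  ord <- order(cue$onset)
  cue <- cue[ord, ]
  n <- nrow(cue)
  d <- data.frame(
    phase = cue$phase, trial_index = seq_len(n) - 1L, cue_id = cue$cue_id,
    cs_type = cue$cs_type, context_id = cue$context_id,
    reinforced = cue$reinforced == 1,
    onset_context = sort(ctx$onset), onset_cue = cue$onset,
    onset_rating = sort(rat$onset)
  )
  d$onset_us <- NA_real_
  if (nrow(us)) {
    d$onset_us[match(round(us$onset - 2.5 - 1, 6),
                     round(d$onset_cue, 6))] <- us$onset
  }
  d$onset_iti <- sort(rat$onset) + rat$duration[order(rat$onset)]
  d$iti_duration <- c(diff(d$onset_context), NA) -
    (d$onset_iti - d$onset_context)
  attr(d, "phase") <- d$phase[1]
  class(d) <- c("phase_design", "data.frame")
  d
}

#' Write / read a confound table (tab-separated, one row per scan)
#' @param confounds data.frame of confound series.
#' @param path file path.
#' @export
write_confounds <- function(confounds, path) {
  utils::write.table(confounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_confounds
#' @param n_scans expected row count; mismatch raises a validation error.
#' @export
read_confounds <- function(path, n_scans = NULL) {
  cf <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!is.null(n_scans) && nrow(cf) != n_scans) {
    stop(sprintf("confound table has %d rows but %d scans expected",
                 nrow(cf), n_scans))
  }
  cf
}

#' Write a 3D or 4D volume as NIfTI-1
#'
#' Masked-voxel data are placed back into the full grid; the affine is the
#' scaled-identity voxel-to-world mapping of the geometry.
#'
#' @param data 3D array, 4D array, or matrix (volumes x masked voxels,
#'   scattered into the mask).
#' @param geometry a `volume_geometry`.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume <- function(data, geometry, path) {
  if (is.matrix(data)) {
    arr <- array(NA_real_, c(geometry$dim, nrow(data)))
    midx <- mask_indices(geometry)
    nvol <- prod(geometry$dim)
    for (i in seq_len(nrow(data))) {
      v <- array(NA_real_, geometry$dim)
      v[midx] <- data[i, ]
      arr[(i - 1) * nvol + seq_len(nvol)] <- v
    }
    data <- arr
  }
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  img <- RNifti::`pixdim<-`(img, c(rep(geometry$voxel_size_mm, 3),
                                   rep(1, nd - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume, validating against a geometry
#' @param path NIfTI path.
#' @param geometry expected `volume_geometry`; grid or voxel-size mismatch
#'   raises a validation error.
#' @return numeric array.
#' @export
read_volume <- function(path, geometry = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!is.null(geometry)) {
    if (!all(dim(arr)[1:3] == geometry$dim)) {
      stop(sprintf("volume grid %s does not match geometry %s",
                   paste(dim(arr)[1:3], collapse = "x"),
                   paste(geometry$dim, collapse = "x")))
    }
    pd <- RNifti::pixdim(img)[1:3]
    if (any(abs(pd - geometry$voxel_size_mm) > 1e-4)) {
      stop(sprintf("voxel size %.3f mm does not match geometry %.3f mm",
                   pd[1], geometry$voxel_size_mm))
    }
  }
  arr
}

#' Persist a beta series as NIfTI + metadata sidecar
#' @param series a `beta_series`.
#' @param nifti_path 4D NIfTI output (trial as 4th dimension).
#' @param meta_path tab-separated trial metadata sidecar.
#' @export
write_beta_series <- function(series, nifti_path, meta_path) {
  write_volume(series$betas, series$geometry, nifti_path)
  utils::write.table(series$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(nifti_path)
}

#' Read a beta series written by [write_beta_series()]
#' @param nifti_path,meta_path paths written by [write_beta_series()].
#' @param geometry the `volume_geometry`.
#' @param model_kind `"cue"` or `"context"`.
#' @export
read_beta_series <- function(nifti_path, meta_path, geometry, model_kind) {
  arr <- read_volume(nifti_path, geometry)
  midx <- mask_indices(geometry)
  n <- dim(arr)[4]
  nvol <- prod(geometry$dim)
  betas <- t(vapply(seq_len(n), function(i) {
    arr[(i - 1) * nvol + midx]
  }, numeric(length(midx))))
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  structure(
    list(betas = betas, meta = meta, model_kind = model_kind,
         geometry = geometry),
    class = "beta_series"
  )
}
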