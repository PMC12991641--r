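#' Cosine high-pass drift basis
#'
#' Discrete-cosine columns up to a cutoff period, the standard drift model
#' for event-related GLMs.
#'
#' @param n_scans number of scans.
#' @param tr repetition time in seconds.
#' @param cutoff_s high-pass cutoff period in seconds (default 128 s).
#' @return `n_scans` x K matrix (possibly 0 columns).
#' @export
cosine_drift_basis <- function(n_scans, tr, cutoff_s = 128) {
  k_max <- floor(2 * n_scans * tr / cutoff_s)
  if (k_max < 1) return(matrix(0, n_scans, 0))
  t <- (seq_len(n_scans) - 0.5) / n_scans
  m <- vapply(seq_len(k_max), function(k) cos(pi * k * t), numeric(n_scans))
  colnames(m) <- sprintf("drift%d", seq_len(k_max))
  m
}

nuisance_matrix <- function(design, confounds, n_scans, tr,
                            cutoff_s = 128, us_impulse = TRUE) {
  stopifnot(nrow(confounds) == n_scans)
  cols <- list()
  us_onsets <- design$onset_us[design$reinforced]
  if (length(us_onsets)) {
    dur <- if (us_impulse) 0 else 0.5
    cols$us <- hrf_regressor(us_onsets, dur, n_scans, tr)
  }
  conf <- as.matrix(confounds)
  colnames(conf) <- colnames(confounds)
  drift <- cosine_drift_basis(n_scans, tr, cutoff_s)
  n <- do.call(cbind, c(cols, list(conf, drift, intercept = rep(1, n_scans))))
  n
}

#' Build the design matrix of one least-squares-separate model
#'
#' One GLM per trial: the target trial's HRF-convolved event gets its own
#' column, all other events of the same model kind share one column, then
#' US-onset regressors of no interest (only in phases with USs), the six
#' motion parameters, WM and CSF mean signals, a cosine high-pass drift
#' basis, and an intercept. Cue models use 1 s cue boxcars; context models
#' use the video-onset-to-cue-onset epoch and contain no cue regressors
#' (and vice versa).
#'
#' @param design a scheduled `phase_design`.
#' @param target_trial 0-based `trial_index` of the trial of interest.
#' @param model_kind `"cue"` or `"context"`.
#' @param confounds confound table (`n_scans` rows, 8 columns).
#' @param n_scans number of scans.
#' @param tr repetition time in seconds.
#' @param cutoff_s drift high-pass cutoff (seconds).
#' @return list with `X` (labeled design matrix) and `target_col`.
#' @export
build_lss_design <- function(design, target_trial, model_kind, confounds,
                             n_scans, tr, cutoff_s = 128) {
  stopifnot(model_kind %in% c("cue", "context"))
  pos <- match(target_trial, design$trial_index)
  if (is.na(pos)) stop("target trial ", target_trial, " not found in events")
  if (nrow(confounds) != n_scans) {
    stop(sprintf("confound table has %d rows but %d scans", nrow(confounds),
                 n_scans))
  }
  c_all <- trial_regressors(design, model_kind, n_scans, tr)
  target <- c_all[, pos]
  others <- rowSums(c_all[, -pos, drop = FALSE])
  nuis <- nuisance_matrix(design, confounds, n_scans, tr, cutoff_s)
  x <- cbind(target = target, others = others, nuis)
  list(X = x, target_col = 1L)
}

check_full_rank <- function(x) {
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Estimate a trial-wise LSS beta series
#'
#' Fits one ordinary-least-squares GLM per trial (target column + shared
#' others column + nuisance set; see [build_lss_design()]) and collects the
#' target-trial coefficient for every masked voxel. Cue and context model
#' kinds yield separate series that are never mixed.
#'
#' @param bold scans x voxels matrix, or a `synthetic_dataset`.
#' @param design a scheduled `phase_design` (ignored if `bold` is a dataset).
#' @param confounds confound table (ignored if `bold` is a dataset).
#' @param model_kind `"cue"` or `"context"`.
#' @param geometry optional `volume_geometry` carried along for searchlights.
#' @param tr repetition time (taken from `geometry` when given).
#' @param cutoff_s drift high-pass cutoff (seconds).
#' @return object of class `beta_series`: `betas` (trial x voxel, rows in
#'   `trial_index` order), `meta` (trial metadata), `model_kind`, `geometry`.
#' @export
estimate_lss_betas <- function(bold, design = NULL, confounds = NULL,
                               model_kind = "cue", geometry = NULL,
                               tr = NULL, cutoff_s = 128) {
  if (inherits(bold, "synthetic_dataset")) {
    design <- bold$design
    confounds <- bold$confounds
    geometry <- bold$geometry
    bold <- bold$bold
  }
  stopifnot(model_kind %in% c("cue", "context"))
  if (is.null(tr)) tr <- geometry$tr_s
  n_scans <- nrow(bold)
  design <- design[order(design$trial_index), ]
  n_trials <- nrow(design)
  c_all <- trial_regressors(design, model_kind, n_scans, tr)
  others_all <- rowSums(c_all)
  nuis <- nuisance_matrix(design, confounds, n_scans, tr, cutoff_s)

  cmat <- matrix(0, n_scans, n_trials)
  for (t in seq_len(n_trials)) {
    x <- cbind(target = c_all[, t], others = others_all - c_all[, t], nuis)
    xtx <- crossprod(x)
    ch <- tryCatch(chol(xtx), error = function(e) NULL)
    if (is.null(ch)) {
      check_full_rank(x)  # raises with collinear column names
      stop("design matrix is numerically singular for trial ", t - 1)
    }
    inv1 <- backsolve(ch, backsolve(ch, c(1, rep(0, ncol(x) - 1)),
                                    transpose = TRUE))
    cmat[, t] <- x %*% inv1
  }
  betas <- crossprod(cmat, bold)
  rownames(betas) <- design$trial_index
  structure(
    list(betas = betas, meta = as.data.frame(design), model_kind = model_kind,
         geometry = geometry),
    class = "beta_series"
  )
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("beta_series (%s model): %d trials x %d voxels, phase %s\n",
              x$model_kind, nrow(x$betas), ncol(x$betas), x$meta$phase[1]))
  invisible(x)
}

#' Restrict a beta series to a voxel subset
#' @param series a `beta_series`.
#' @param voxels column indices into the series' voxel axis.
#' @return a `beta_series` over the subset.
#' @export
subset_voxels <- function(series, voxels) {
  series$betas <- series$betas[, voxels, drop = FALSE]
  series
}

#' First-level condition contrast map
#'
#' Condition-wise GLM (one HRF-convolved column per CS type, same nuisance
#' set as the LSS models) followed by a weighted sum of condition
#' coefficients per voxel, e.g. `c("CS++" = 0.5, "CS+-" = 0.5, "CS-+" = -0.5,
#' "CS--" = -0.5)` for CS+ > CS- in acquisition.
#'
#' @param bold scans x voxels matrix, or a `synthetic_dataset`.
#' @param design,confounds as in [estimate_lss_betas()].
#' @param condition_weights named numeric vector of CS-type weights.
#' @param geometry,tr,cutoff_s as in [estimate_lss_betas()].
#' @return numeric vector: contrast value per voxel.
#' @export
first_level_contrast <- function(bold, design = NULL, confounds = NULL,
                                 condition_weights, geometry = NULL,
                                 tr = NULL, cutoff_s = 128) {
  if (inherits(bold, "synthetic_dataset")) {
    design <- bold$design
    confounds <- bold$confounds
    geometry <- bold$geometry
    bold <- bold$bold
  }
  if (is.null(tr)) tr <- geometry$tr_s
  n_scans <- nrow(bold)
  conds <- sort(unique(design$cs_type))
  unknown <- setdiff(names(condition_weights), conds)
  if (length(unknown)) {
    stop("weights reference unknown condition(s): ",
         paste(unknown, collapse = ", "))
  }
  cond_cols <- vapply(conds, function(cs) {
    sel <- design$cs_type == cs
    hrf_regressor(design$onset_cue[sel],
                  design$onset_rating[sel] - design$onset_cue[sel],
                  n_scans, tr)
  }, numeric(n_scans))
  nuis <- nuisance_matrix(design, confounds, n_scans, tr, cutoff_s)
  x <- cbind(cond_cols, nuis)
  check_full_rank(x)
  coefs <- qr.coef(qr(x), bold)[seq_along(conds), , drop = FALSE]
  w <- numeric(length(conds))
  names(w) <- conds
  w[names(condition_weights)] <- condition_weights
  as.numeric(w %*% coefs)
}
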