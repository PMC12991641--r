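#' Canonical double-gamma haemodynamic response function
#'
#' `h(t) = dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6`: response peaking about
#' 5-6 s after the event with an undershoot around 16 s, no derivative terms.
#'
#' @param t time in seconds (vectorized); zero for `t < 0`.
#' @return HRF value(s).
#' @export
hrf_double_gamma <- function(t) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- stats::dgamma(t[pos], shape = 6, rate = 1) -
    stats::dgamma(t[pos], shape = 16, rate = 1) / 6
  out
}

#' HRF-convolved event regressor sampled at scan times
#'
#' Convolves a boxcar (or impulse, `duration = 0`) with the double-gamma HRF
#' by direct quadrature at `dt` resolution and samples the result at
#' `tr * (0:(n_scans - 1))`.
#'
#' @param onsets event onsets in seconds.
#' @param durations event durations in seconds (recycled).
#' @param n_scans number of scans.
#' @param tr repetition time in seconds.
#' @param dt quadrature step for the boxcar integral.
#' @return numeric vector of length `n_scans`.
#' @export
hrf_regressor <- function(onsets, durations, n_scans, tr, dt = 0.1) {
  scan_t <- tr * (seq_len(n_scans) - 1)
  durations <- rep_len(durations, length(onsets))
  reg <- numeric(n_scans)
  for (i in seq_along(onsets)) {
    rel <- scan_t - onsets[i]
    win <- rel > 0 & rel < durations[i] + 33
    if (!any(win)) next
    if (durations[i] <= 0) {
      reg[win] <- reg[win] + hrf_double_gamma(rel[win])
    } else {
      u <- seq(dt / 2, durations[i], by = dt)
      lags <- outer(rel[win], u, "-")
      reg[win] <- reg[win] + dt * rowSums(matrix(hrf_double_gamma(lags),
                                                 nrow = sum(win)))
    }
  }
  reg
}

#' Per-trial convolved regressors for one event stream
#'
#' @param design a `phase_design` with onsets scheduled.
#' @param model_kind `"cue"` (1 s cue boxcars) or `"context"` (context-video
#'   epochs from video onset to cue onset).
#' @param n_scans number of scans.
#' @param tr repetition time in seconds.
#' @return `n_scans` x `n_trials` matrix, one column per trial.
#' @export
trial_regressors <- function(design, model_kind, n_scans, tr) {
  if (model_kind == "cue") {
    onsets <- design$onset_cue
    durations <- design$onset_rating - design$onset_cue
  } else {
    onsets <- design$onset_context
    durations <- design$onset_cue - design$onset_context
  }
  vapply(seq_len(nrow(design)), function(t) {
    hrf_regressor(onsets[t], durations[t], n_scans, tr)
  }, numeric(n_scans))
}

#' Number of scans covering a scheduled phase
#' @param design a `phase_design` with onsets.
#' @param geometry a `volume_geometry`.
#' @export
phase_n_scans <- function(design, geometry) {
  as.integer(ceiling(attr(design, "total_duration_s") / geometry$tr_s))
}

#' Simulate confound time series (6 motion + WM + CSF)
#'
#' Motion parameters are Gaussian random walks (slow drifts, as after
#' realignment); white-matter and CSF mean signals are stationary AR(1)
#' series.
#'
#' @param n_scans number of scans.
#' @param seed integer seed.
#' @return data.frame with columns `trans_x..rot_z`, `wm`, `csf`.
#' @export
simulate_confounds <- function(n_scans, seed) {
  set.seed(seed)
  motion <- vapply(1:6, function(i) cumsum(stats::rnorm(n_scans, 0, 0.02)),
                   numeric(n_scans))
  ar1 <- function() {
    e <- stats::rnorm(n_scans)
    as.numeric(stats::filter(e, 0.5, method = "recursive"))
  }
  out <- data.frame(motion, wm = ar1(), csf = ar1())
  names(out) <- c("trans_x", "trans_y", "trans_z",
                  "rot_x", "rot_y", "rot_z", "wm", "csf")
  out
}

#' Synthesize BOLD-like data for one phase
#'
#' Per-voxel time series = sum over cue trials of (true cue pattern x
#' HRF-convolved 1 s cue boxcar) + the analogous context-epoch responses +
#' US responses (impulse events, shared US pattern) + confound loadings x
#' confound series (each with its own random spatial pattern) + per-voxel
#' linear drift + stationary AR(1) Gaussian scan noise.
#'
#' @param design a scheduled `phase_design`.
#' @param bank a `pattern_bank`.
#' @param geometry a `volume_geometry`.
#' @param effects an `effect_spec`.
#' @param seed integer seed.
#' @return object of class `synthetic_dataset`: `bold` (scans x masked
#'   voxels), `confounds`, true `patterns_cue` / `patterns_context`, the
#'   `design`, `geometry`, `n_scans`.
#' @export
synthesize_bold <- function(design, bank, geometry, effects, seed) {
  n_scans <- phase_n_scans(design, geometry)
  tr <- geometry$tr_s
  v <- bank$n_voxels
  stopifnot(v == sum(geometry$mask))

  p_cue <- compose_trial_patterns(design, bank, effects, "cue",
                                  seed = derive_seed(seed, 1L))
  p_ctx <- compose_trial_patterns(design, bank, effects, "context",
                                  seed = derive_seed(seed, 2L))
  c_cue <- trial_regressors(design, "cue", n_scans, tr)
  c_ctx <- trial_regressors(design, "context", n_scans, tr)
  y <- c_cue %*% p_cue + c_ctx %*% p_ctx

  us_onsets <- design$onset_us[design$reinforced]
  if (length(us_onsets)) {
    us_reg <- hrf_regressor(us_onsets, 0, n_scans, tr)
    y <- y + us_reg %o% (effects$us_amp * bank_pattern(bank, "us"))
  }

  confounds <- simulate_confounds(n_scans, derive_seed(seed, 3L))
  set.seed(derive_seed(seed, 4L))
  conf_patterns <- matrix(stats::rnorm(8 * v), 8, v)
  y <- y + as.matrix(confounds) %*% (effects$confound_loadings * conf_patterns)

  drift_coef <- stats::rnorm(v, 0, effects$drift_amp)
  ramp <- seq(-0.5, 0.5, length.out = n_scans)
  y <- y + ramp %o% drift_coef

  if (effects$scan_noise_sd > 0) {
    rho <- effects$ar1_rho
    e <- matrix(stats::rnorm(n_scans * v, 0,
                             effects$scan_noise_sd * sqrt(1 - rho^2)),
                n_scans, v)
    if (rho != 0) {
      for (t in 2:n_scans) e[t, ] <- e[t, ] + rho * e[t - 1, ]
    }
    y <- y + e
  }

  structure(
    list(bold = y, confounds = confounds, patterns_cue = p_cue,
         patterns_context = p_ctx, design = design, geometry = geometry,
         effects = effects, n_scans = n_scans),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: phase %s, %d scans x %d voxels\n",
              attr(x$design, "phase"), x$n_scans, ncol(x$bold)))
  invisible(x)
}
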