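# Shared fixtures and independent oracles used across the suite.

tiny_geometry <- function(dim = c(8, 8, 6), ...) {
  volume_geometry(dim, ...)
}

quick_spec <- function(p = 0L) assign_counterbalancing(p, 1L)

# Brute-force normal-equations solution for a single regression target:
# coefficient vector via explicit pseudoinverse, independent of the LSS path.
normal_equations_coef <- function(x, y) {
  solve(t(x) %*% x) %*% t(x) %*% y
}

# Pair-enumeration RSM oracle: explicit double loop over trial pairs,
# Pearson r computed by cor() per pair, then atanh.
rsm_oracle <- function(a, b = NULL) {
  within <- is.null(b)
  if (within) b <- a
  z <- matrix(NA_real_, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (within && i == j) next
      z[i, j] <- atanh(stats::cor(a[i, ], b[j, ]))
    }
  }
  z
}

# Enumeration oracle for masked metric means: loop over all pairs and
# average the z entries whose metadata match the predicate.
metric_oracle <- function(z, meta_row, meta_col, pred, within = TRUE) {
  vals <- c()
  for (i in seq_len(nrow(z))) {
    for (j in seq_len(ncol(z))) {
      if (within && i == j) next
      if (pred(meta_row[i, ], meta_col[j, ])) vals <- c(vals, z[i, j])
    }
  }
  mean(vals)
}

# Minimal hand-made beta series for toy RSM tests.
toy_series <- function(betas, meta, kind = "cue") {
  structure(
    list(betas = betas, meta = meta, model_kind = kind, geometry = NULL),
    class = "beta_series"
  )
}

toy_meta <- function(n, cue_id, cs_type, context_id = "ctx01",
                     reinforced = FALSE, phase = "acquisition") {
  data.frame(
    phase = phase, trial_index = seq_len(n) - 1L,
    cue_id = rep_len(cue_id, n), cs_type = rep_len(cs_type, n),
    context_id = rep_len(context_id, n),
    reinforced = rep_len(reinforced, n)
  )
}

# Random LSS instance at <= 100 scans used for oracle-equivalence checks.
random_lss_instance <- function(seed, n_scans = NULL, n_voxels = 5) {
  set.seed(seed)
  if (is.null(n_scans)) n_scans <- sample(40:100, 1)
  n_trials <- sample(4:8, 1)
  tr <- 2.0
  onsets <- sort(stats::runif(n_trials, 0, n_scans * tr * 0.7))
  design <- data.frame(
    phase = "acquisition", trial_index = seq_len(n_trials) - 1L,
    cue_id = sprintf("cue%d", sample(1:8, n_trials, replace = TRUE)),
    cs_type = sample(cs_types(), n_trials, replace = TRUE),
    context_id = "ctx01",
    reinforced = c(FALSE, sample(c(TRUE, FALSE), n_trials - 1, replace = TRUE)),
    onset_context = onsets, onset_cue = onsets + 2,
    onset_rating = onsets + 3
  )
  design$onset_us <- ifelse(design$reinforced, design$onset_rating + 2.5, NA)
  design$onset_iti <- design$onset_rating + 2.5
  design$iti_duration <- 8
  attr(design, "phase") <- "acquisition"
  class(design) <- c("phase_design", "data.frame")
  confounds <- as.data.frame(matrix(stats::rnorm(n_scans * 8), n_scans, 8))
  names(confounds) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z", "wm", "csf")
  bold <- matrix(stats::rnorm(n_scans * n_voxels), n_scans, n_voxels)
  list(design = design, confounds = confounds, bold = bold,
       n_scans = n_scans, tr = tr)
}
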