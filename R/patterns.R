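#' Latent voxel-pattern bank for one simulated brain
#'
#' Draws the latent codes planted in the synthetic BOLD data, one pattern per
#' masked-voxel vector: a baseline pattern shared by all events, a persistent
#' item pattern per cue (8), a phase-specific item pattern per cue x phase
#' (32), persistent threat and safe valence-category patterns, one context
#' pattern per context video (16), and a US response pattern. Patterns are
#' i.i.d. Gaussian, orthogonalized within the masked subspace and rescaled so
#' each has unit per-voxel variance; orthogonalization makes all planted
#' components uncorrelated by construction (pairwise |r| far below 0.1).
#'
#' @param geometry a [volume_geometry()].
#' @param seed integer seed.
#' @param orthogonalize orthogonalize the bank (default TRUE).
#' @return object of class `pattern_bank`: list of named pattern matrices,
#'   each column a voxel pattern over `mask_indices(geometry)`.
#' @export
make_pattern_bank <- function(geometry, seed, orthogonalize = TRUE) {
  v <- sum(geometry$mask)
  cue_ids <- sprintf("cue%d", 1:8)
  ctx_ids <- sprintf("ctx%02d", 1:16)
  item_phase_names <- as.vector(outer(cue_ids, phases(), paste, sep = "."))
  nms <- c("baseline", cue_ids, item_phase_names, "threat", "safe",
           ctx_ids, "us")
  n_pat <- length(nms)
  if (v < n_pat) {
    stop(sprintf("mask has %d voxels but %d patterns requested", v, n_pat))
  }
  set.seed(seed)
  m <- matrix(stats::rnorm(v * n_pat), v, n_pat)
  if (orthogonalize) m <- qr.Q(qr(m))
  ## unit per-voxel variance so effect weights are in noise-SD units
  m <- sweep(m, 2, apply(m, 2, stats::sd), "/")
  m <- sweep(m, 2, colMeans(m), "-")
  colnames(m) <- nms
  structure(
    list(patterns = m, n_voxels = v, seed = as.integer(seed),
         cue_ids = cue_ids, context_ids = ctx_ids),
    class = "pattern_bank"
  )
}

bank_pattern <- function(bank, name) {
  if (!name %in% colnames(bank$patterns)) stop("no bank pattern: ", name)
  bank$patterns[, name]
}

#' Ground-truth effect weights planted in the synthetic data
#'
#' Weights, in per-voxel noise-SD units, of each latent component in the true
#' trial patterns. Component structure (per phase p and CS type c):
#' `w_item_shared[p, c]` scales the persistent per-cue pattern (carries
#' cross-phase item reinstatement), `w_item_phase[p, c]` a phase-private
#' per-cue pattern (item stability without reinstatement), `w_threat[p, c]` /
#' `w_safe[p, c]` the persistent valence-category patterns (cue
#' generalization; their cross-phase products carry generalized
#' reinstatement), and `w_ctx[p]` the context pattern of the trial's video.
#'
#' Defaults plant the qualitative structure the pipeline is designed to
#' recover: higher threat- than safe-cue generalization during acquisition
#' and reversal; higher item stability for valence-changing cues (CS-+,
#' CS+-) during reversal; higher context specificity in reversal than
#' acquisition; and weak residual category traces during test.
#'
#' @param trial_noise_sd SD of Gaussian trial-pattern noise.
#' @param scan_noise_sd SD of AR(1) scan noise.
#' @param ar1_rho lag-1 autocorrelation of scan noise, in (-1, 1).
#' @param baseline_amp amplitude of the shared baseline pattern.
#' @param us_amp amplitude of the US response pattern.
#' @param drift_amp per-voxel SD of the linear drift component.
#' @param confound_loadings length-8 loadings (6 motion, WM, CSF).
#' @param w_item_shared,w_item_phase,w_threat,w_safe 4x4 phase x CS-type
#'   matrices; `NULL` uses the defaults described above.
#' @param w_ctx named length-4 vector of context-pattern weights per phase.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(trial_noise_sd = 0.5, scan_noise_sd = 1.0,
                        ar1_rho = 0.3, baseline_amp = 0.5, us_amp = 1.5,
                        drift_amp = 0.5,
                        confound_loadings = c(rep(0.2, 6), 0.3, 0.3),
                        w_item_shared = NULL, w_item_phase = NULL,
                        w_threat = NULL, w_safe = NULL, w_ctx = NULL) {
  stopifnot(abs(ar1_rho) < 1, trial_noise_sd >= 0, scan_noise_sd >= 0,
            length(confound_loadings) == 8)
  wmat <- function(x, default) {
    if (is.null(x)) x <- default
    x <- as.matrix(x)
    stopifnot(all(dim(x) == c(4, 4)))
    dimnames(x) <- list(phases(), cs_types())
    x
  }
  ## columns: CS++, CS+-, CS-+, CS--
  d_item_shared <- matrix(c(
    0.6, 0.6, 0.6, 0.6,   # acquisition
    0.8, 0.8, 0.8, 0.8,   # reversal
    0.6, 0.6, 0.6, 0.6,   # test_new
    0.6, 0.6, 0.6, 0.6    # test_old
  ), 4, 4, byrow = TRUE)
  d_item_phase <- matrix(c(
    0.4, 0.4, 0.4, 0.4,
    0.4, 0.8, 0.8, 0.4,   # reversal: valence-changing cues more item-stable
    0.4, 0.4, 0.4, 0.4,
    0.4, 0.4, 0.4, 0.4
  ), 4, 4, byrow = TRUE)
  d_threat <- matrix(c(
    0.7, 0.7, 0.0, 0.0,   # acquisition threat = CS++, CS+-
    0.7, 0.0, 0.7, 0.0,   # reversal threat = CS++, CS-+
    0.15, 0.0, 0.15, 0.0, # tests: residual trace of reversal valence
    0.15, 0.3, 0.15, 0.0  # test_old: CS+- acquisition-threat trace returns
  ), 4, 4, byrow = TRUE)
  d_safe <- matrix(c(
    0.0, 0.0, 0.25, 0.25,
    0.0, 0.25, 0.0, 0.25,
    0.0, 0.1, 0.0, 0.1,
    0.0, 0.1, 0.3, 0.1    # test_old: CS-+ acquisition-safe trace returns
  ), 4, 4, byrow = TRUE)
  if (is.null(w_ctx)) {
    w_ctx <- c(acquisition = 0.4, reversal = 0.8, test_new = 0.4, test_old = 0.4)
  }
  stopifnot(all(names(w_ctx) == phases()))
  structure(
    list(
      w_item_shared = wmat(w_item_shared, d_item_shared),
      w_item_phase = wmat(w_item_phase, d_item_phase),
      w_threat = wmat(w_threat, d_threat),
      w_safe = wmat(w_safe, d_safe),
      w_ctx = w_ctx,
      trial_noise_sd = trial_noise_sd, scan_noise_sd = scan_noise_sd,
      ar1_rho = ar1_rho, baseline_amp = baseline_amp, us_amp = us_amp,
      drift_amp = drift_amp, confound_loadings = confound_loadings
    ),
    class = "effect_spec"
  )
}

#' A fully null effect specification
#'
#' All signal weights zero; only baseline, confounds, drift, and noise remain.
#' Used for type-I-error studies.
#' @param ... overrides passed to [effect_spec()].
#' @export
null_effect_spec <- function(...) {
  z <- matrix(0, 4, 4)
  effect_spec(
    w_item_shared = z, w_item_phase = z, w_threat = z, w_safe = z,
    w_ctx = c(acquisition = 0, reversal = 0, test_new = 0, test_old = 0),
    ...
  )
}

#' Compose ground-truth trial patterns for one phase
#'
#' True voxel pattern of trial t (cue model):
#' `baseline + w_item_shared * P_item(cue) + w_item_phase * P_item(cue, phase)
#'  + w_threat * P_threat + w_safe * P_safe + w_ctx * P_context(context)
#'  + trial noise`.
#' Context-model trial patterns carry `baseline + w_ctx * P_context + noise`.
#' Under the default weights the valence semantics follow the paradigm: the
#' threat pattern loads on CS++/CS+- in acquisition and on CS++/CS-+ in
#' reversal (CS-+ is safe in acquisition and threatening in reversal).
#'
#' @param design a `phase_design`.
#' @param bank a `pattern_bank`.
#' @param effects an `effect_spec`.
#' @param model_kind `"cue"` or `"context"`.
#' @param seed integer seed for the trial noise.
#' @return trial x voxel matrix of true patterns (rows follow `trial_index`).
#' @export
compose_trial_patterns <- function(design, bank, effects, model_kind = "cue",
                                   seed = 1L) {
  stopifnot(inherits(bank, "pattern_bank"), inherits(effects, "effect_spec"),
            model_kind %in% c("cue", "context"))
  ph <- attr(design, "phase")
  v <- bank$n_voxels
  n <- nrow(design)
  set.seed(seed)
  out <- matrix(stats::rnorm(n * v, 0, effects$trial_noise_sd), n, v)
  pat_names <- colnames(bank$patterns)
  w <- matrix(0, n, length(pat_names), dimnames = list(NULL, pat_names))
  w[, "baseline"] <- effects$baseline_amp
  w[cbind(seq_len(n), match(design$context_id, pat_names))] <-
    effects$w_ctx[[ph]]
  if (model_kind == "cue") {
    cs <- design$cs_type
    w[cbind(seq_len(n), match(design$cue_id, pat_names))] <-
      effects$w_item_shared[ph, cs]
    w[cbind(seq_len(n),
            match(paste(design$cue_id, ph, sep = "."), pat_names))] <-
      effects$w_item_phase[ph, cs]
    w[, "threat"] <- effects$w_threat[ph, cs]
    w[, "safe"] <- effects$w_safe[ph, cs]
  }
  out <- out + w %*% t(bank$patterns)
  rownames(out) <- design$trial_index
  out
}
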