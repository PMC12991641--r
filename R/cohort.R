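#' Per-participant effect specification with individual differences
#'
#' Draws one participant's ground-truth weights around the defaults of
#' [effect_spec()]: a Gaussian deviation `delta` scales reversal context
#' specificity up or down, and the same `delta` is coupled into the test_old
#' category-trace weights of the contingency-changing cues (stronger
#' acquisition-threat trace of CS+- and weaker acquisition-safe trace of
#' CS-+ for high-specificity participants). This plants the
#' specificity-by-cue-type reinstatement interaction that the linkage model
#' is asked to recover.
#'
#' @param delta participant deviation (SD about 0.25 across a cohort).
#' @param coupling strength of the specificity-reinstatement coupling.
#' @param ... further overrides passed to [effect_spec()].
#' @return an `effect_spec` with attribute `delta`.
#' @export
participant_effect_spec <- function(delta = 0, coupling = 0.6, ...) {
  es <- effect_spec(...)
  es$w_ctx["reversal"] <- max(0.05, es$w_ctx["reversal"] * (1 + delta))
  es$w_threat["test_old", "CS+-"] <-
    clamp(es$w_threat["test_old", "CS+-"] + coupling * delta, 0, 1.5)
  es$w_safe["test_old", "CS-+"] <-
    clamp(es$w_safe["test_old", "CS-+"] - coupling * delta, 0, 1.5)
  attr(es, "delta") <- delta
  es
}

#' Simulate one participant and compute whole-mask RSA metrics
#'
#' Runs the generator and estimation pipeline for one participant over the
#' requested phases: counterbalanced design, pattern bank, BOLD synthesis,
#' LSS beta series (cue and context models), and the whole-mask metric set:
#' cue generalization and item stability per CS type and phase, context
#' specificity per phase, and item/generalized reinstatement between
#' acquisition/reversal and test_old.
#'
#' @param participant_index 0-based participant number.
#' @param seed base integer seed.
#' @param geometry a `volume_geometry`.
#' @param effects an `effect_spec` for this participant.
#' @param use_phases phases to simulate (default: the three needed for all
#'   whole-mask metrics).
#' @return list with `metrics` (tidy data.frame), `series` (beta series per
#'   phase/kind), `effects`.
#' @export
simulate_participant <- function(participant_index, seed, geometry, effects,
                                 use_phases = c("acquisition", "reversal",
                                                "test_old")) {
  spec <- assign_counterbalancing(participant_index, seed)
  bank <- make_pattern_bank(geometry, derive_seed(seed, participant_index, 1L))
  series <- list()
  rows <- list()
  for (ph in use_phases) {
    i <- match(ph, phases())
    design <- build_phase_design(
      spec, ph, seed = derive_seed(seed, participant_index, 10L + i))
    ds <- synthesize_bold(design, bank, geometry, effects,
                          seed = derive_seed(seed, participant_index, 20L + i))
    cue_series <- estimate_lss_betas(ds, model_kind = "cue")
    ctx_series <- estimate_lss_betas(ds, model_kind = "context")
    series[[ph]] <- list(cue = cue_series, context = ctx_series)

    rsm_cue <- build_rsm(cue_series)
    gen <- cue_generalization(rsm_cue)
    stab <- item_stability(rsm_cue)$per_cs_type
    spec_val <- context_specificity(build_rsm(ctx_series))
    rows[[length(rows) + 1]] <- data.frame(
      participant = participant_index, phase = ph,
      metric = "cue_generalization", condition = gen$cs_type,
      value = gen$value)
    rows[[length(rows) + 1]] <- data.frame(
      participant = participant_index, phase = ph,
      metric = "item_stability", condition = stab$cs_type,
      value = stab$value)
    rows[[length(rows) + 1]] <- data.frame(
      participant = participant_index, phase = ph,
      metric = "context_specificity", condition = "all", value = spec_val)
  }
  for (src in intersect(c("acquisition", "reversal"), use_phases)) {
    if (!"test_old" %in% use_phases) next
    rsm_x <- build_rsm(series[[src]]$cue, series$test_old$cue)
    for (mode in c("item", "generalized")) {
      re <- reinstatement(rsm_x, mode)
      rows[[length(rows) + 1]] <- data.frame(
        participant = participant_index, phase = paste0(src, "-test_old"),
        metric = paste0(mode, "_reinstatement"), condition = re$cs_type,
        value = re$value)
    }
  }
  list(metrics = do.call(rbind, rows), series = series, effects = effects)
}

#' Simulate a cohort and return its group-level recovery summary
#'
#' Simulates `n_participants` independent participants (each with their own
#' counterbalancing, pattern bank, and individual-difference `delta`), and
#' computes the group quantities whose planted signs the pipeline should
#' recover: the acquisition CS+ > CS- cue-generalization contrast, the
#' reversal change > no-change item-stability contrast, the reversal minus
#' acquisition context-specificity difference, and the specificity x
#' cue-type interaction on generalized reinstatement of acquisition traces
#' during test_old.
#'
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @param geometry a `volume_geometry`.
#' @param delta_sd SD of the participant deviation.
#' @param coupling see [participant_effect_spec()].
#' @return list with `group` (named group-level values), `metrics` (stacked
#'   per-participant table), `linkage` (the fitted interaction results).
#' @export
simulate_cohort <- function(n_participants = 12, seed = 1L,
                            geometry = volume_geometry(),
                            delta_sd = 0.25, coupling = 0.6) {
  set.seed(derive_seed(seed, 77L))
  deltas <- stats::rnorm(n_participants, 0, delta_sd)
  parts <- lapply(seq_len(n_participants), function(p) {
    es <- participant_effect_spec(deltas[p], coupling)
    simulate_participant(p - 1L, derive_seed(seed, 100L + p), geometry, es)
  })
  metrics <- do.call(rbind, lapply(parts, function(x) x$metrics))

  pick <- function(metric, phase, conds) {
    sub <- metrics[metrics$metric == metric & metrics$phase == phase &
                     metrics$condition %in% conds, ]
    tapply(sub$value, sub$participant, mean)
  }
  cue_gen_contrast <- mean(
    pick("cue_generalization", "acquisition", c("CS++", "CS+-")) -
      pick("cue_generalization", "acquisition", c("CS-+", "CS--")))
  item_stab_contrast <- mean(
    pick("item_stability", "reversal", c("CS-+", "CS+-")) -
      pick("item_stability", "reversal", c("CS++", "CS--")))
  ctx_spec_diff <- mean(
    pick("context_specificity", "reversal", "all") -
      pick("context_specificity", "acquisition", "all"))

  spec_part <- pick("context_specificity", "reversal", "all") -
    pick("context_specificity", "acquisition", "all")
  link_tables <- lapply(c("generalized", "item"), function(mode) {
    sub <- metrics[metrics$metric == paste0(mode, "_reinstatement") &
                     metrics$phase == "acquisition-test_old" &
                     metrics$condition %in% c("CS-+", "CS+-"), ]
    data.frame(
      participant = sub$participant, cs_type = sub$condition,
      specificity = as.numeric(spec_part[as.character(sub$participant)]),
      reinstatement = sub$value
    )
  })
  link_gen <- specificity_reinstatement_lme(link_tables[[1]], "generalized")
  link_item <- specificity_reinstatement_lme(link_tables[[2]], "item")

  list(
    group = c(
      cue_generalization_contrast = cue_gen_contrast,
      item_stability_contrast = item_stab_contrast,
      context_specificity_diff = ctx_spec_diff,
      linkage_interaction = link_gen$interaction$estimate[1]
    ),
    metrics = metrics,
    linkage = list(generalized = link_gen, item = link_item,
                   fdr = linkage_pair_fdr(link_item, link_gen))
  )
}

#' Multi-cohort parameter-recovery study
#'
#' Repeats [simulate_cohort()] over independent cohorts and reports, per
#' group quantity, the fraction of cohorts recovering the planted sign
#' (all four planted effects are positive under the default weights).
#'
#' @param n_cohorts number of cohorts.
#' @param n_participants participants per cohort.
#' @param seed integer seed.
#' @param geometry a `volume_geometry`.
#' @return list with `values` (cohort x quantity matrix) and `sign_rate`
#'   (named fraction positive).
#' @export
recovery_study <- function(n_cohorts = 20, n_participants = 12, seed = 1L,
                           geometry = volume_geometry()) {
  vals <- t(vapply(seq_len(n_cohorts), function(k) {
    simulate_cohort(n_participants, derive_seed(seed, 1000L + k),
                    geometry)$group
  }, numeric(4)))
  list(values = vals, sign_rate = colMeans(vals > 0))
}

#' Separable Gaussian smoothing of a 3D array
#' @param arr 3D numeric array.
#' @param sigma_vox kernel SD in voxels.
#' @return smoothed array (same shape).
#' @export
smooth_volume <- function(arr, sigma_vox = 1.5) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  sm1 <- function(a, dim_idx) {
    a <- aperm(a, c(dim_idx, setdiff(1:3, dim_idx)))
    d <- dim(a)
    m <- matrix(a, d[1], d[2] * d[3])
    padded <- rbind(m[rep(1, r), , drop = FALSE], m,
                    m[rep(d[1], r), , drop = FALSE])
    out <- matrix(0, d[1], ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1) + seq_len(d[1]), , drop = FALSE]
    }
    aperm(array(out, d), order(c(dim_idx, setdiff(1:3, dim_idx))))
  }
  for (dd in 1:3) arr <- sm1(arr, dd)
  arr
}

#' Type-I-error study of the cluster-FWE family
#'
#' Generates null cohorts of spatially smooth participant maps (Gaussian
#' noise smoothed to emulate the spatial correlation of searchlight output),
#' runs [cluster_fwe()] on each, and reports the fraction of cohorts with
#' any significant cluster. Under the null this should approximate `alpha`.
#'
#' @param n_cohorts number of null cohorts.
#' @param n_participants maps per cohort.
#' @param seed integer seed.
#' @param geometry a `volume_geometry` (small grids keep this fast).
#' @param n_perm sign-flip permutations per cohort.
#' @param alpha significance threshold for `p_fwe`.
#' @param cft_p cluster-forming p.
#' @param smooth_sigma map smoothness (voxels).
#' @return list with `rejections` (logical per cohort) and `rate`.
#' @export
null_cluster_fwe_study <- function(n_cohorts = 200, n_participants = 12,
                                   seed = 1L,
                                   geometry = volume_geometry(c(12, 12, 8)),
                                   n_perm = 500, alpha = 0.05,
                                   cft_p = 0.001, smooth_sigma = 1.5) {
  midx <- mask_indices(geometry)
  rej <- vapply(seq_len(n_cohorts), function(k) {
    set.seed(derive_seed(seed, 2000L + k))
    maps <- t(vapply(seq_len(n_participants), function(p) {
      vol <- smooth_volume(array(stats::rnorm(prod(geometry$dim)),
                                 geometry$dim), smooth_sigma)
      v <- vol[midx]
      (v - mean(v)) / stats::sd(v)
    }, numeric(length(midx))))
    cf <- cluster_fwe(maps, geometry = geometry, voxels = midx,
                      n_perm = n_perm, cft_p = cft_p, alpha = alpha,
                      seed = derive_seed(seed, 3000L + k))
    any(cf$clusters$significant)
  }, logical(1))
  list(rejections = rej, rate = mean(rej))
}

#' Type-I-error study of the behavioral mixed model
#'
#' Simulates rating cohorts with all phase x CS-type cell means equal and
#' reports the rejection rate of the interaction term at `alpha`.
#'
#' @param n_reps replicates.
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @param alpha nominal level.
#' @return list with `p_values` and `rate`.
#' @export
null_behavior_study <- function(n_reps = 200, n_participants = 12, seed = 1L,
                                alpha = 0.05) {
  spec <- assign_counterbalancing(0L)
  designs <- build_all_phases(spec, derive_seed(seed, 1L))
  mm <- matrix(2.5, 4, 4, dimnames = list(phases(), cs_types()))
  p_values <- vapply(seq_len(n_reps), function(k) {
    pars <- behavior_params(mean_matrix = mm, participant_sd = 0.4,
                            noise_sd = 0.8, seed = derive_seed(seed, 10L + k))
    ratings <- simulate_expectancy(designs, pars, n_participants)
    res <- suppressWarnings(analyze_expectancy(summarize_expectancy(ratings)))
    res$fixed$p[res$fixed$term == "cs_type:phase"]
  }, numeric(1))
  list(p_values = p_values, rate = mean(p_values < alpha))
}

#' Type-I-error study of the specificity-reinstatement linkage model
#'
#' Simulates participant tables in which context specificity and
#' reinstatement are independent (reinstatement = participant intercept +
#' noise) and reports the rejection rate of the interaction term.
#'
#' @param n_reps replicates.
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @param alpha nominal level.
#' @return list with `p_values` and `rate`.
#' @export
null_linkage_study <- function(n_reps = 200, n_participants = 24, seed = 1L,
                               alpha = 0.05) {
  p_values <- vapply(seq_len(n_reps), function(k) {
    set.seed(derive_seed(seed, 500L + k))
    spec_v <- stats::rnorm(n_participants)
    b <- stats::rnorm(n_participants, 0, 0.5)
    tab <- data.frame(
      participant = rep(seq_len(n_participants), 2),
      cs_type = rep(c("CS-+", "CS+-"), each = n_participants),
      specificity = rep(spec_v, 2),
      reinstatement = rep(b, 2) + stats::rnorm(2 * n_participants)
    )
    res <- suppressWarnings(specificity_reinstatement_lme(tab))
    res$interaction$p[1]
  }, numeric(1))
  list(p_values = p_values, rate = mean(p_values < alpha))
}
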