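#' Parameters of the US-expectancy rating generator
#'
#' Latent-mean model for the 4-point US-expectancy ratings: each phase x
#' CS-type cell has a latent mean, each participant a Gaussian random
#' intercept, each trial Gaussian noise; the latent value is rounded and
#' clipped onto {1..4}. Default cell means follow the contingencies of the
#' paradigm (high expectancy for currently US-paired cues, rapid contingency
#' learning, overall decline over the unreinforced test phases).
#'
#' @param mean_matrix 4x4 numeric matrix (phase x cs_type) of latent means,
#'   rows named by [phases()], columns by [cs_types()].
#' @param participant_sd random-intercept SD (rating units).
#' @param noise_sd trial noise SD (rating units).
#' @param seed integer seed.
#' @return object of class `behavior_params`.
#' @export
behavior_params <- function(mean_matrix = NULL, participant_sd = 0.4,
                            noise_sd = 0.8, seed = 1L) {
  if (is.null(mean_matrix)) {
    mean_matrix <- rbind(
      acquisition = c(3.3, 3.3, 1.5, 1.5),
      reversal    = c(3.6, 2.2, 3.0, 1.4),
      test_new    = c(2.8, 2.2, 1.9, 1.4),
      test_old    = c(2.6, 2.1, 1.8, 1.3)
    )
    colnames(mean_matrix) <- cs_types()
  }
  stopifnot(
    all(rownames(mean_matrix) == phases()),
    all(colnames(mean_matrix) == cs_types()),
    participant_sd >= 0, noise_sd >= 0
  )
  structure(
    list(mean_matrix = mean_matrix, participant_sd = participant_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "behavior_params"
  )
}

#' Simulate trial-wise US-expectancy ratings
#'
#' @param designs named list of `phase_design` (one per phase), as from
#'   [build_all_phases()]; all participants rate the same trial structure,
#'   each with their own intercept and noise stream.
#' @param params a `behavior_params`.
#' @param n_participants number of simulated participants.
#' @return data.frame (`participant_id`, `phase`, `trial_index`, `cs_type`,
#'   `rating`) with one row per cue trial.
#' @export
simulate_expectancy <- function(designs, params, n_participants) {
  stopifnot(inherits(params, "behavior_params"), n_participants >= 1)
  set.seed(params$seed)
  intercepts <- stats::rnorm(n_participants, 0, params$participant_sd)
  out <- vector("list", n_participants * length(designs))
  k <- 0L
  for (p in seq_len(n_participants)) {
    for (ph in names(designs)) {
      d <- designs[[ph]]
      mu <- params$mean_matrix[ph, d$cs_type]
      latent <- mu + intercepts[p] + stats::rnorm(nrow(d), 0, params$noise_sd)
      k <- k + 1L
      out[[k]] <- data.frame(
        participant_id = p,
        phase = ph,
        trial_index = d$trial_index,
        cs_type = d$cs_type,
        rating = as.integer(clamp(round(latent), 1L, 4L))
      )
    }
  }
  do.call(rbind, out)
}

#' Average ratings per participant, phase, and CS type
#'
#' Collapses the trial-wise table to the four averaged US-expectancy values
#' per experimental phase per participant that enter the group analysis.
#'
#' @param ratings a rating table from [simulate_expectancy()] (or real data
#'   with the same columns).
#' @return data.frame (`participant_id`, `phase`, `cs_type`, `mean_rating`).
#' @export
summarize_expectancy <- function(ratings) {
  req <- c("participant_id", "phase", "cs_type", "rating")
  stopifnot(all(req %in% names(ratings)))
  agg <- stats::aggregate(rating ~ participant_id + phase + cs_type,
                          data = ratings, FUN = mean)
  names(agg)[names(agg) == "rating"] <- "mean_rating"
  ## completeness: every participant must have every phase x cs_type cell
  full <- expand.grid(
    participant_id = unique(ratings$participant_id),
    phase = phases(), cs_type = cs_types(),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  full <- full[full$phase %in% unique(ratings$phase), ]
  key_have <- paste(agg$participant_id, agg$phase, agg$cs_type)
  key_want <- paste(full$participant_id, full$phase, full$cs_type)
  missing <- setdiff(key_want, key_have)
  if (length(missing)) {
    stop("missing rating cell(s): ", paste(missing, collapse = "; "))
  }
  agg <- agg[order(agg$participant_id, match(agg$phase, phases()),
                   match(agg$cs_type, cs_types())), ]
  rownames(agg) <- NULL
  agg
}

#' Mixed-effects analysis of US expectancy with Wilcoxon post-hocs
#'
#' Fits `mean_rating ~ cs_type * phase + (1 | participant)` by REML with
#' Satterthwaite denominator degrees of freedom, then runs paired Wilcoxon
#' signed-rank post-hocs in two separately Bonferroni-corrected families:
#' CS-type pairs within each phase (6 per phase) and phase pairs pooled over
#' CS types (6).
#'
#' @param summary_table output of [summarize_expectancy()].
#' @return object of class `behavior_result` with elements `fixed`
#'   (term, F, df, p), `posthoc` (pair, family, statistic, p_raw,
#'   p_bonferroni, tie_flag), `singular` flag, and the fitted model.
#' @export
analyze_expectancy <- function(summary_table) {
  stopifnot(length(unique(summary_table$participant_id)) >= 2)
  df <- summary_table
  df$cs_type <- factor(df$cs_type, levels = cs_types())
  df$phase <- factor(df$phase, levels = phases())
  df$participant <- factor(df$participant_id)

  fit <- suppressMessages(lmerTest::lmer(
    mean_rating ~ cs_type * phase + (1 | participant),
    data = df, REML = TRUE
  ))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular random-effect fit; reporting ordinary F-test fallback")
    aovfit <- stats::aov(mean_rating ~ cs_type * phase +
                           Error(participant), data = df)
    sm <- summary(aovfit)$`Error: Within`[[1]]
    fixed <- data.frame(
      term = trimws(rownames(sm)[seq_len(nrow(sm) - 1)]),
      F = sm$`F value`[seq_len(nrow(sm) - 1)],
      df_num = sm$Df[seq_len(nrow(sm) - 1)],
      df_den = sm$Df[nrow(sm)],
      p = sm$`Pr(>F)`[seq_len(nrow(sm) - 1)]
    )
  } else {
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    fixed <- data.frame(
      term = rownames(an),
      F = an$`F value`,
      df_num = an$NumDF,
      df_den = an$DenDF,
      p = an$`Pr(>F)`
    )
  }
  rownames(fixed) <- NULL

  posthoc <- rbind(
    posthoc_cs_pairs(df),
    posthoc_phase_pairs(df)
  )
  structure(
    list(fixed = fixed, posthoc = posthoc, singular = singular, model = fit),
    class = "behavior_result"
  )
}

paired_wilcoxon <- function(x, y, label, family, n_family) {
  d <- x - y
  if (all(d == 0)) {
    return(data.frame(pair = label, family = family, statistic = NA_real_,
                      p_raw = 1, p_bonferroni = 1, tie_flag = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                            correct = TRUE))
  data.frame(
    pair = label, family = family, statistic = unname(wt$statistic),
    p_raw = wt$p.value,
    p_bonferroni = min(1, wt$p.value * n_family),
    tie_flag = FALSE
  )
}

posthoc_cs_pairs <- function(df) {
  out <- list()
  for (ph in levels(droplevels(df$phase))) {
    sub <- df[df$phase == ph, ]
    wide <- stats::reshape(sub[, c("participant", "cs_type", "mean_rating")],
                           idvar = "participant", timevar = "cs_type",
                           direction = "wide")
    prs <- utils::combn(cs_types(), 2)
    fam <- sprintf("cs_within_%s", ph)
    for (k in seq_len(ncol(prs))) {
      a <- wide[[paste0("mean_rating.", prs[1, k])]]
      b <- wide[[paste0("mean_rating.", prs[2, k])]]
      out[[length(out) + 1]] <- paired_wilcoxon(
        a, b, sprintf("%s vs %s (%s)", prs[1, k], prs[2, k], ph),
        fam, ncol(prs)
      )
    }
  }
  do.call(rbind, out)
}

posthoc_phase_pairs <- function(df) {
  ## per participant mean over CS types within phase
  agg <- stats::aggregate(mean_rating ~ participant + phase, data = df, FUN = mean)
  phs <- levels(droplevels(df$phase))
  prs <- utils::combn(phs, 2)
  out <- list()
  for (k in seq_len(ncol(prs))) {
    a <- agg$mean_rating[agg$phase == prs[1, k]]
    b <- agg$mean_rating[agg$phase == prs[2, k]]
    out[[length(out) + 1]] <- paired_wilcoxon(
      a, b, sprintf("%s vs %s", prs[1, k], prs[2, k]),
      "phase_pairs", ncol(prs)
    )
  }
  do.call(rbind, out)
}

#' @export
print.behavior_result <- function(x, ...) {
  cat("behavior_result: fixed effects\n")
  print(x$fixed, digits = 4)
  cat(sprintf("post-hoc comparisons: %d (Bonferroni within family)\n",
              nrow(x$posthoc)))
  if (x$singular) cat("NOTE: singular fit; ordinary F-test fallback used\n")
  invisible(x)
}
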