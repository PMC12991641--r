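#' Counterbalanced experiment specification for one participant
#'
#' Builds the full paradigm specification: 8 cues in 4 CS types of 2 items
#' each, 16 context videos partitioned into sets A (4, acquisition), B (4,
#' reversal) and C (8, test in new contexts), trial timing, and the 50%
#' reinforcement rate. Cue-to-CS-type assignment rotates over participants as
#' a Latin-square style schedule: over any block of 8 consecutive participants
#' each cue serves each CS type exactly twice. The A/B context-set assignment
#' alternates with participant parity.
#'
#' @param participant_index 0-based participant number.
#' @param seed integer seed (kept for reproducibility bookkeeping; the
#'   rotation itself is a deterministic function of `participant_index`).
#' @return an object of class `experiment_spec`.
#' @export
assign_counterbalancing <- function(participant_index, seed = 0L) {
  stopifnot(participant_index >= 0)
  cue_ids <- sprintf("cue%d", 1:8)
  types <- cs_types()
  ## rotation: cue c occupies slot (c - p) mod 8; slots 0:1 -> CS++, 2:3 -> CS+-, ...
  slot <- (seq_along(cue_ids) - 1 - participant_index) %% 8
  cs_map <- types[slot %/% 2 + 1]
  names(cs_map) <- cue_ids

  ctx_ids <- sprintf("ctx%02d", 1:16)
  four_a <- ctx_ids[1:4]
  four_b <- ctx_ids[5:8]
  if (participant_index %% 2 == 1) {
    tmp <- four_a; four_a <- four_b; four_b <- tmp
  }
  context_sets <- list(A = four_a, B = four_b, C = ctx_ids[9:16])

  structure(
    list(
      participant_index = as.integer(participant_index),
      seed = as.integer(seed),
      cue_ids = cue_ids,
      cs_type_map = cs_map,
      context_sets = context_sets,
      phase_context_table = list(
        acquisition = "A", reversal = "B",
        test_new = "C", test_old = c("A", "B")
      ),
      timing = list(
        context_s = 2.0, cue_s = 1.0, rating_s = 2.5,
        iti_range_s = c(7.0, 9.0)
      ),
      reinforcement_rate = 0.5,
      n_trials_per_phase = 128L,
      rating_scale = 1:4
    ),
    class = "experiment_spec"
  )
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("experiment_spec: participant %d\n", x$participant_index))
  for (ty in cs_types()) {
    cat(sprintf("  %s: %s\n", ty,
                paste(names(x$cs_type_map)[x$cs_type_map == ty], collapse = ", ")))
  }
  cat(sprintf("  contexts A: %s\n", paste(x$context_sets$A, collapse = ", ")))
  cat(sprintf("  contexts B: %s\n", paste(x$context_sets$B, collapse = ", ")))
  invisible(x)
}

#' Contexts shown in a phase
#' @param spec an `experiment_spec`.
#' @param phase phase name.
#' @return character vector of context ids (4 for acquisition/reversal, 8 for tests).
#' @export
phase_contexts <- function(spec, phase) {
  sets <- spec$phase_context_table[[phase]]
  if (is.null(sets)) stop("unknown phase: ", phase)
  unlist(spec$context_sets[sets], use.names = FALSE)
}

#' Build one phase's pseudorandomized trial sequence
#'
#' Generates the 128-trial sequence of one phase under the paradigm's
#' constraints: each of the 8 cues appears 16 times, every cue x context
#' pairing appears equally often (4 times with 4 contexts, 2 with 8), each
#' US-paired cue is reinforced on exactly half of its presentations, the
#' first and last trials are unreinforced, and no cue occurs more than twice
#' in a row. Order is a constrained shuffle with rejection sampling.
#'
#' @param spec an `experiment_spec`.
#' @param phase one of `phases()`.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap before erroring.
#' @return an object of class `phase_design`: a data.frame of trials with
#'   attributes `phase` and `seed`. Onsets are filled by [schedule_onsets()].
#' @export
build_phase_design <- function(spec, phase, seed, max_tries = 2000L) {
  stopifnot(inherits(spec, "experiment_spec"), phase %in% phases())
  n_trials <- spec$n_trials_per_phase
  cues <- spec$cue_ids
  ctxs <- phase_contexts(spec, phase)
  per_pair <- n_trials / (length(cues) * length(ctxs))
  if (per_pair != round(per_pair)) {
    stop(sprintf(
      "infeasible design: %d trials not divisible by %d cues x %d contexts",
      n_trials, length(cues), length(ctxs)
    ))
  }
  cells <- expand.grid(cue_id = cues, context_id = ctxs,
                       rep = seq_len(per_pair), stringsAsFactors = FALSE)
  paired <- us_paired_types(phase)
  per_cue <- n_trials / length(cues)
  n_reinf <- as.integer(round(spec$reinforcement_rate * per_cue))

  set.seed(seed)
  for (try in seq_len(max_tries)) {
    ord <- sample.int(nrow(cells))
    trials <- cells[ord, c("cue_id", "context_id")]
    ## no cue more than twice consecutively
    r <- rle(trials$cue_id)
    if (any(r$lengths > 2)) next
    trials$cs_type <- unname(spec$cs_type_map[trials$cue_id])
    trials$reinforced <- FALSE
    for (cue in cues) {
      if (spec$cs_type_map[[cue]] %in% paired) {
        pos <- which(trials$cue_id == cue)
        trials$reinforced[sample(pos, n_reinf)] <- TRUE
      }
    }
    if (trials$reinforced[1] || trials$reinforced[n_trials]) next
    trials$phase <- phase
    trials$trial_index <- seq_len(n_trials) - 1L
    rownames(trials) <- NULL
    design <- trials[, c("phase", "trial_index", "cue_id", "cs_type",
                         "context_id", "reinforced")]
    attr(design, "phase") <- phase
    attr(design, "seed") <- as.integer(seed)
    class(design) <- c("phase_design", "data.frame")
    return(schedule_onsets(design, spec, seed = derive_seed(seed, 911L)))
  }
  stop("could not satisfy design constraints after ", max_tries, " tries")
}

#' Assign event onsets to an ordered trial sequence
#'
#' Sequential timing per trial: context video onset, cue at +2 s, rating
#' window at +3 s for 2.5 s, US (if reinforced) at the rating-window offset
#' (+5.5 s; the trace-conditioning gap between cue offset and US), then a
#' fixation ITI drawn uniformly from 7-9 s. The next trial's context starts
#' at the end of the ITI.
#'
#' @param design a `phase_design` (ordered trials).
#' @param spec the `experiment_spec`.
#' @param seed integer seed for the ITI jitter.
#' @return the design with onset columns (`onset_context`, `onset_cue`,
#'   `onset_rating`, `onset_us`, `onset_iti`, `iti_duration`) and a
#'   `total_duration_s` attribute.
#' @export
schedule_onsets <- function(design, spec, seed) {
  tm <- spec$timing
  n <- nrow(design)
  set.seed(seed)
  iti <- stats::runif(n, tm$iti_range_s[1], tm$iti_range_s[2])
  pre_iti <- tm$context_s + tm$cue_s + tm$rating_s   # 5.5 s
  trial_len <- pre_iti + iti
  onset_context <- c(0, cumsum(trial_len))[seq_len(n)]
  design$onset_context <- onset_context
  design$onset_cue <- onset_context + tm$context_s
  design$onset_rating <- design$onset_cue + tm$cue_s
  design$onset_us <- ifelse(design$reinforced,
                            design$onset_rating + tm$rating_s, NA_real_)
  design$onset_iti <- design$onset_rating + tm$rating_s
  design$iti_duration <- iti
  attr(design, "total_duration_s") <- onset_context[n] + pre_iti + iti[n]
  design
}

#' Build all four phase designs for one participant
#' @param spec an `experiment_spec`.
#' @param seed integer base seed; each phase gets a derived stream.
#' @return named list of `phase_design`, in phase order.
#' @export
build_all_phases <- function(spec, seed) {
  out <- lapply(seq_along(phases()), function(i) {
    build_phase_design(spec, phases()[i], seed = derive_seed(seed, i))
  })
  names(out) <- phases()
  out
}

#' Tabulate a phase design against its closed-form constraints
#'
#' Exhaustive count check used by tests and the acceptance report: trial
#' count, per-cue count, per cue-x-context count, reinforcement counts per
#' cue, first/last-trial reinforcement, and the CS-type x context
#' contingency table (orthogonality).
#'
#' @param design a `phase_design`.
#' @param spec the generating `experiment_spec`.
#' @return list of counts and logical flags.
#' @export
tabulate_design <- function(design, spec) {
  phase <- attr(design, "phase")
  ctxs <- phase_contexts(spec, phase)
  pair_tab <- table(design$cue_id, design$context_id)
  type_ctx <- table(design$cs_type, design$context_id)
  reinf_per_cue <- tapply(design$reinforced, design$cue_id, sum)
  list(
    n_trials = nrow(design),
    per_cue = as.vector(table(design$cue_id)),
    per_pair = as.vector(pair_tab),
    per_pair_expected = nrow(design) / (length(spec$cue_ids) * length(ctxs)),
    reinforced_per_cue = stats::setNames(as.integer(reinf_per_cue[spec$cue_ids]),
                                         spec$cue_ids),
    n_reinforced = sum(design$reinforced),
    first_last_unreinforced = !design$reinforced[1] &&
      !design$reinforced[nrow(design)],
    cs_context_uniform = length(unique(as.vector(type_ctx))) == 1L
  )
}
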