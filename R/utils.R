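#' Derive a reproducible child seed from a base seed
#'
#' Deterministic integer mixing used to split one user-supplied seed into
#' independent streams (per participant, per phase, per stage) without
#' correlated low bits. Result is always a valid 32-bit R seed.
#'
#' @param base integer base seed.
#' @param ... one or more integer stream labels.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base, ...) {
  ks <- c(base, ...)
  h <- 0
  for (k in ks) {
    h <- (h * 2654435761 + (as.numeric(k) + 1) * 40503 + 97) %% 2147483629
  }
  as.integer(h)
}

#' Fisher r-to-z transform
#' @param r correlation value(s) in `[-1, 1]`.
#' @return `atanh(r)`; infinite at `|r| = 1`.
#' @export
fisher_z <- function(r) atanh(r)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CS types of the paradigm
#'
#' The four cue types, named by their reinforcement during acquisition /
#' reversal: paired/paired (CS++), paired/unpaired (CS+-), unpaired/paired
#' (CS-+), unpaired/unpaired (CS--).
#' @export
cs_types <- function() c("CS++", "CS+-", "CS-+", "CS--")

#' Experimental phases, in order
#' @export
phases <- function() c("acquisition", "reversal", "test_new", "test_old")

#' Cue valence in a given phase
#'
#' Acquisition: CS++ and CS+- are US-paired (threat); reversal: CS++ and CS-+
#' are US-paired. In the test phases no US is ever delivered; the "current"
#' valence is taken as the most recently learned (reversal) contingency.
#'
#' @param phase phase name.
#' @param cs_type CS type label(s).
#' @return `"threat"` or `"safe"` per element.
#' @export
cs_valence <- function(phase, cs_type) {
  stopifnot(phase %in% phases())
  threat <- if (phase == "acquisition") c("CS++", "CS+-") else c("CS++", "CS-+")
  ifelse(cs_type %in% threat, "threat", "safe")
}

#' CS types paired with the US in a phase
#' @param phase phase name.
#' @return character vector (empty in test phases).
#' @export
us_paired_types <- function(phase) {
  switch(phase,
    acquisition = c("CS++", "CS+-"),
    reversal = c("CS++", "CS-+"),
    test_new = character(0),
    test_old = character(0),
    stop("unknown phase: ", phase)
  )
}
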