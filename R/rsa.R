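## center and scale rows to unit norm so tcrossprod gives Pearson r
row_standardize <- function(m) {
  m <- m - rowMeans(m)
  s <- sqrt(rowSums(m^2))
  zero <- s == 0
  s[zero] <- 1
  out <- m / s
  attr(out, "zero_variance") <- zero
  out
}

#' Build a Fisher-z representational similarity matrix
#'
#' Entry (i, j) is `atanh(Pearson r)` across voxels between trial patterns i
#' and j. With one series the RSM is square (within phase) and self-pairs
#' are undefined; with two series it is rectangular (cross-phase). Patterns
#' with zero voxel variance yield undefined entries that are excluded from
#' every mask, with a warning.
#'
#' @param series_a a `beta_series`.
#' @param series_b optional second `beta_series` over the same voxel set.
#' @return object of class `rsm`: `z` matrix, `meta_row`, `meta_col`,
#'   `within` flag, `phases`.
#' @export
build_rsm <- function(series_a, series_b = NULL) {
  within <- is.null(series_b)
  if (within) series_b <- series_a
  if (ncol(series_a$betas) != ncol(series_b$betas)) {
    stop("beta series have different voxel sets")
  }
  za <- row_standardize(series_a$betas)
  zb <- row_standardize(series_b$betas)
  bad_a <- attr(za, "zero_variance")
  bad_b <- attr(zb, "zero_variance")
  if (any(bad_a) || any(bad_b)) {
    warning(sum(bad_a) + sum(bad_b),
            " zero-variance pattern(s); entries set undefined")
  }
  r <- tcrossprod(za, zb)
  r[bad_a, ] <- NA
  r[, bad_b] <- NA
  z <- fisher_z(clamp(r, -1, 1))
  if (within) diag(z) <- NA
  structure(
    list(z = z, meta_row = series_a$meta, meta_col = series_b$meta,
         within = within,
         phases = c(series_a$meta$phase[1], series_b$meta$phase[1])),
    class = "rsm"
  )
}

#' @export
print.rsm <- function(x, ...) {
  cat(sprintf("rsm: %d x %d trials (%s), phases %s/%s\n",
              nrow(x$z), ncol(x$z),
              if (x$within) "within-phase" else "cross-phase",
              x$phases[1], x$phases[2]))
  invisible(x)
}

#' Boolean pair mask over an RSM
#'
#' Selects the trial pairs of one similarity category. Within-phase
#' categories: `same_item`, `same_cstype_different_item`, `within_context`,
#' `between_context`; cross-phase categories: `cross_same_item`,
#' `cross_same_cstype_different_item` (rectangular RSMs only). With
#' `restrict_unreinforced = TRUE`, any pair touching a reinforced (US-paired
#' and delivered) trial is excluded. Self-pairs and undefined entries are
#' always excluded.
#'
#' @param rsm an `rsm`.
#' @param category category label (see above).
#' @param restrict_unreinforced exclude pairs touching reinforced trials.
#' @param cue_id,cs_type,context_id optional filters restricting the pairs
#'   to one cue / CS type / context.
#' @return logical matrix congruent with `rsm$z`, with attribute `n_pairs`
#'   (unordered pair count for square RSMs, cell count for rectangular).
#' @export
make_pair_mask <- function(rsm, category, restrict_unreinforced = TRUE,
                           cue_id = NULL, cs_type = NULL, context_id = NULL) {
  cross_cats <- c("cross_same_item", "cross_same_cstype_different_item")
  within_cats <- c("same_item", "same_cstype_different_item",
                   "within_context", "between_context")
  if (!category %in% c(cross_cats, within_cats)) {
    stop("unknown pair category: ", category)
  }
  if (category %in% cross_cats && rsm$within) {
    stop("cross-phase category '", category, "' on a within-phase RSM")
  }
  mr <- rsm$meta_row
  mc <- rsm$meta_col
  same_cue <- outer(mr$cue_id, mc$cue_id, "==")
  same_cs <- outer(mr$cs_type, mc$cs_type, "==")
  same_ctx <- outer(mr$context_id, mc$context_id, "==")
  m <- switch(category,
    same_item = ,
    cross_same_item = same_cue,
    same_cstype_different_item = ,
    cross_same_cstype_different_item = same_cs & !same_cue,
    within_context = same_ctx,
    between_context = !same_ctx
  )
  if (!is.null(cue_id)) {
    m <- m & outer(mr$cue_id %in% cue_id, mc$cue_id %in% cue_id, "&")
  }
  if (!is.null(cs_type)) {
    m <- m & outer(mr$cs_type %in% cs_type, mc$cs_type %in% cs_type, "&")
  }
  if (!is.null(context_id)) {
    m <- m & outer(mr$context_id %in% context_id,
                   mc$context_id %in% context_id, "&")
  }
  if (restrict_unreinforced) {
    m <- m & outer(!mr$reinforced, !mc$reinforced, "&")
  }
  if (rsm$within) {
    diag(m) <- FALSE
  }
  m <- m & !is.na(rsm$z)
  attr(m, "n_pairs") <- if (rsm$within) sum(m) / 2 else sum(m)
  m
}

mask_mean <- function(rsm, mask) {
  if (!any(mask)) stop("empty pair mask")
  mean(rsm$z[mask])
}

#' Item stability: mean similarity among presentations of the same item
#'
#' Per-cue mean over same-item pairs, plus per-CS-type values (mean of the
#' type's two cues).
#'
#' @param rsm a within-phase `rsm` (cue model).
#' @param restrict_unreinforced exclude pairs touching reinforced trials.
#' @return list with data.frames `per_cue` (`cue_id`, `cs_type`, `n_pairs`,
#'   `value`) and `per_cs_type` (`cs_type`, `value`).
#' @export
item_stability <- function(rsm, restrict_unreinforced = TRUE) {
  cues <- sort(unique(rsm$meta_row$cue_id))
  per_cue <- do.call(rbind, lapply(cues, function(cue) {
    m <- make_pair_mask(rsm, "same_item", restrict_unreinforced, cue_id = cue)
    data.frame(
      cue_id = cue,
      cs_type = rsm$meta_row$cs_type[match(cue, rsm$meta_row$cue_id)],
      n_pairs = attr(m, "n_pairs"),
      value = mask_mean(rsm, m)
    )
  }))
  per_cs <- stats::aggregate(value ~ cs_type, data = per_cue, FUN = mean)
  list(per_cue = per_cue, per_cs_type = per_cs)
}

#' Cue generalization: mean similarity between different items of a CS type
#'
#' @param rsm a within-phase `rsm` (cue model).
#' @param restrict_unreinforced exclude pairs touching reinforced trials.
#' @return data.frame (`cs_type`, `n_pairs`, `value`).
#' @export
cue_generalization <- function(rsm, restrict_unreinforced = TRUE) {
  types <- sort(unique(rsm$meta_row$cs_type))
  do.call(rbind, lapply(types, function(cs) {
    m <- make_pair_mask(rsm, "same_cstype_different_item",
                        restrict_unreinforced, cs_type = cs)
    data.frame(cs_type = cs, n_pairs = attr(m, "n_pairs"),
               value = mask_mean(rsm, m))
  }))
}

#' Context stability: mean within-context similarity
#' @param rsm a within-phase `rsm` built from a context-model beta series.
#' @param restrict_unreinforced exclude pairs touching reinforced trials
#'   (mirrors the cue rule; configurable).
#' @return scalar Fisher-z mean.
#' @export
context_stability <- function(rsm, restrict_unreinforced = TRUE) {
  if (length(unique(rsm$meta_row$context_id)) < 2) {
    stop("need at least 2 contexts in the phase")
  }
  mask_mean(rsm, make_pair_mask(rsm, "within_context", restrict_unreinforced))
}

#' Context generalization: mean between-context similarity
#' @inheritParams context_stability
#' @export
context_generalization <- function(rsm, restrict_unreinforced = TRUE) {
  if (length(unique(rsm$meta_row$context_id)) < 2) {
    stop("need at least 2 contexts in the phase")
  }
  mask_mean(rsm, make_pair_mask(rsm, "between_context", restrict_unreinforced))
}

#' Context specificity: within-context minus between-context similarity
#'
#' Exactly `context_stability(rsm) - context_generalization(rsm)`; positive
#' values mean more distinct context representations.
#' @inheritParams context_stability
#' @export
context_specificity <- function(rsm, restrict_unreinforced = TRUE) {
  context_stability(rsm, restrict_unreinforced) -
    context_generalization(rsm, restrict_unreinforced)
}

#' Cross-phase reinstatement of cue representations
#'
#' Item mode averages cross-phase same-item pairs; generalized mode averages
#' cross-phase different-item same-CS-type pairs; reported per CS type.
#'
#' @param rsm_cross a rectangular cross-phase `rsm` (cue models).
#' @param mode `"item"` or `"generalized"`.
#' @param restrict_unreinforced exclude pairs touching reinforced trials.
#' @return data.frame (`cs_type`, `mode`, `n_pairs`, `value`).
#' @export
reinstatement <- function(rsm_cross, mode = c("item", "generalized"),
                          restrict_unreinforced = TRUE) {
  mode <- match.arg(mode)
  if (rsm_cross$within) stop("reinstatement needs a cross-phase RSM")
  category <- if (mode == "item") "cross_same_item" else
    "cross_same_cstype_different_item"
  types <- sort(unique(rsm_cross$meta_row$cs_type))
  do.call(rbind, lapply(types, function(cs) {
    m <- make_pair_mask(rsm_cross, category, restrict_unreinforced,
                        cs_type = cs)
    data.frame(cs_type = cs, mode = mode, n_pairs = attr(m, "n_pairs"),
               value = mask_mean(rsm_cross, m))
  }))
}
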