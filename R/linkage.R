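#' Mixed-effects model of ROI metric values over phase and CS type
#'
#' Fits `value ~ phase * cs_type + (1 | participant)` (or phase only) by
#' REML with Satterthwaite denominator degrees of freedom, then paired
#' Wilcoxon post-hocs over the levels of `posthoc_term` with the stated
#' correction. Intended for one ROI's metric table; apply FDR across
#' ROI-level comparisons with [stats::p.adjust()] over the combined results.
#'
#' @param metric_table data.frame with columns `participant`, `value`, and
#'   the predictors in `fixed`.
#' @param fixed character vector of fixed-effect column names (interaction
#'   included when there are two).
#' @param posthoc_term which fixed effect to compare pairwise (`NULL` skips).
#' @param correction `"bonferroni"` or `"fdr"` for the post-hoc family.
#' @return object of class `linkage_result`: `fixed` (term, F, df, p),
#'   `posthoc`, `singular` flag, fitted model.
#' @export
roi_phase_lme <- function(metric_table, fixed = c("phase", "cs_type"),
                          posthoc_term = fixed[1],
                          correction = c("bonferroni", "fdr")) {
  correction <- match.arg(correction)
  stopifnot(all(c("participant", "value", fixed) %in% names(metric_table)))
  if (length(unique(metric_table$participant)) < 2) {
    stop("need at least 2 participants")
  }
  if (stats::sd(metric_table$value) == 0) {
    stop("metric values are constant; no variance to model")
  }
  df <- metric_table
  df$participant <- factor(df$participant)
  for (f in fixed) df[[f]] <- factor(df[[f]])
  rhs <- paste(fixed, collapse = " * ")
  form <- stats::as.formula(paste("value ~", rhs, "+ (1 | participant)"))

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = df, REML = TRUE)),
    error = function(e) NULL
  )
  singular <- is.null(fit) || lme4::isSingular(fit)
  if (singular) {
    warning("singular or failed random-effect fit; ordinary F-test fallback")
    lmfit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = df)
    an <- stats::anova(lmfit)
    k <- nrow(an) - 1
    fixed_tab <- data.frame(
      term = trimws(rownames(an)[seq_len(k)]),
      F = an$`F value`[seq_len(k)], df_num = an$Df[seq_len(k)],
      df_den = an$Df[k + 1], p = an$`Pr(>F)`[seq_len(k)]
    )
  } else {
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    fixed_tab <- data.frame(
      term = rownames(an), F = an$`F value`,
      df_num = an$NumDF, df_den = an$DenDF, p = an$`Pr(>F)`
    )
  }
  rownames(fixed_tab) <- NULL

  posthoc <- NULL
  if (!is.null(posthoc_term)) {
    lev <- levels(df[[posthoc_term]])
    if (length(lev) >= 2) {
      agg <- stats::aggregate(
        stats::as.formula(paste("value ~ participant +", posthoc_term)),
        data = df, FUN = mean
      )
      prs <- utils::combn(lev, 2)
      rows <- lapply(seq_len(ncol(prs)), function(k) {
        a <- agg$value[agg[[posthoc_term]] == prs[1, k]]
        b <- agg$value[agg[[posthoc_term]] == prs[2, k]]
        paired_wilcoxon(a, b, sprintf("%s vs %s", prs[1, k], prs[2, k]),
                        posthoc_term, ncol(prs))
      })
      posthoc <- do.call(rbind, rows)
      if (correction == "fdr") {
        posthoc$p_fdr <- stats::p.adjust(posthoc$p_raw, method = "BH")
        posthoc$p_bonferroni <- NULL
      }
    }
  }
  structure(
    list(fixed = fixed_tab, posthoc = posthoc, singular = singular,
         model = fit),
    class = "linkage_result"
  )
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("linkage_result: fixed effects\n")
  print(x$fixed, digits = 4)
  if (x$singular) cat("NOTE: singular fit; fallback used\n")
  invisible(x)
}

#' Context specificity as a predictor of reinstatement
#'
#' Fits `reinstatement ~ specificity * cs_type + (1 | participant)` over the
#' contingency-changing cue types (CS-+ and CS+-), REML with Satterthwaite
#' df, and reports the coefficient table plus per-cue-type simple slopes.
#' Run once per (ROI, reinstatement mode); adjust the item/generalized pair
#' with [linkage_pair_fdr()].
#'
#' @param table data.frame with columns `participant`, `cs_type` (exactly
#'   the levels `CS-+` and `CS+-`), `specificity`, `reinstatement`.
#' @param mode label recorded in the output (`"item"` or `"generalized"`).
#' @return object of class `linkage_result` with elements `coefficients`
#'   (term, estimate, t, df, p), `interaction` row, `slopes` (per cue type),
#'   `mode`, `singular`.
#' @export
specificity_reinstatement_lme <- function(table, mode = "item") {
  need <- c("participant", "cs_type", "specificity", "reinstatement")
  stopifnot(all(need %in% names(table)))
  if (length(unique(table$participant)) < 2) {
    stop("need at least 2 participants")
  }
  missing_cs <- setdiff(c("CS-+", "CS+-"), unique(table$cs_type))
  if (length(missing_cs)) {
    stop("missing cue type(s): ", paste(missing_cs, collapse = ", "))
  }
  df <- table
  df$participant <- factor(df$participant)
  df$cs_type <- factor(df$cs_type, levels = c("CS-+", "CS+-"))

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      reinstatement ~ specificity * cs_type + (1 | participant),
      data = df, REML = TRUE
    )),
    error = function(e) NULL
  )
  singular <- is.null(fit) || lme4::isSingular(fit)
  if (singular) {
    lmfit <- stats::lm(reinstatement ~ specificity * cs_type, data = df)
    cf <- summary(lmfit)$coefficients
    coefs <- data.frame(
      term = rownames(cf), estimate = cf[, 1], t = cf[, 3],
      df = stats::df.residual(lmfit), p = cf[, 4]
    )
  } else {
    cf <- summary(fit)$coefficients
    coefs <- data.frame(
      term = rownames(cf), estimate = cf[, "Estimate"],
      t = cf[, "t value"], df = cf[, "df"], p = cf[, "Pr(>|t|)"]
    )
  }
  rownames(coefs) <- NULL
  inter <- coefs[grepl(":", coefs$term), , drop = FALSE]

  slopes <- do.call(rbind, lapply(levels(df$cs_type), function(cs) {
    sub <- df[df$cs_type == cs, ]
    sl <- stats::coef(stats::lm(reinstatement ~ specificity, data = sub))[2]
    data.frame(cs_type = cs, slope = unname(sl))
  }))
  structure(
    list(coefficients = coefs, interaction = inter, slopes = slopes,
         mode = mode, singular = singular, model = fit),
    class = c("specificity_linkage", "linkage_result")
  )
}

#' FDR over one item/generalized linkage pair
#'
#' Benjamini-Hochberg adjustment of the two interaction p-values of one
#' ROI's item- and generalized-reinstatement models.
#'
#' @param item,generalized `specificity_linkage` results for one ROI.
#' @return data.frame (mode, estimate, t, df, p_raw, p_fdr).
#' @export
linkage_pair_fdr <- function(item, generalized) {
  rows <- rbind(
    cbind(mode = item$mode, item$interaction),
    cbind(mode = generalized$mode, generalized$interaction)
  )
  rows$p_fdr <- stats::p.adjust(rows$p, method = "BH")
  names(rows)[names(rows) == "p"] <- "p_raw"
  rownames(rows) <- NULL
  rows
}

#' @export
print.specificity_linkage <- function(x, ...) {
  cat(sprintf("specificity_linkage (%s reinstatement)\n", x$mode))
  print(x$coefficients, digits = 4)
  print(x$slopes, digits = 4)
  invisible(x)
}
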