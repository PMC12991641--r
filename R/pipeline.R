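#' Default study configuration
#'
#' All analysis defaults are the study's stated constants: 5 mm searchlight
#' radius, 0.5 in-mask fraction, 10,000 permutations, cluster-forming
#' p < 0.001, base alpha 0.05 with Bonferroni families, and 1500 mm^3
#' minimum ROI volume. The geometry and cohort blocks default to the
#' desk-scale simulation (18x18x12 grid at 2.5 mm, 12 participants).
#'
#' @param output_dir where [run_study()] writes its artifact tree.
#' @return a validated `study_config` list.
#' @export
default_study_config <- function(output_dir = tempfile("fearrsa_study_")) {
  cfg <- list(
    geometry = list(dim = c(18L, 18L, 12L), voxel_size_mm = 2.5, tr_s = 2.53),
    cohort = list(n_participants = 12L, base_seed = 1L),
    effects = list(delta_sd = 0.25, coupling = 0.6),
    behavior = list(participant_sd = 0.4, noise_sd = 0.8),
    analysis = list(
      radius_mm = 5.0, min_in_mask_frac = 0.5, n_perm = 10000L,
      cft_p = 0.001, base_alpha = 0.05, min_roi_volume_mm3 = 1500,
      connectivity = 26L,
      comparisons = list(cue_generalization_acq = 2L,
                         item_stability_rev = 4L,
                         context_specificity = 2L)
    ),
    outputs = list(dir = output_dir, write_volumes = FALSE),
    phases = phases()
  )
  validate_study_config(cfg)
}

#' Validate a study configuration
#'
#' Schema check run before any stage: block and field presence, types, and
#' ranges. Returns the config invisibly amended with defaults for optional
#' fields.
#'
#' @param config a `study_config`-like list.
#' @return the validated config (class `study_config`).
#' @export
validate_study_config <- function(config) {
  need_block <- c("geometry", "cohort", "effects", "behavior", "analysis",
                  "outputs")
  missing <- setdiff(need_block, names(config))
  if (length(missing)) {
    stop("config missing block(s): ", paste(missing, collapse = ", "))
  }
  g <- config$geometry
  stopifnot(length(g$dim) == 3, all(g$dim >= 4), g$voxel_size_mm > 0,
            g$tr_s > 0)
  a <- config$analysis
  stopifnot(a$radius_mm >= g$voxel_size_mm,
            a$min_in_mask_frac > 0, a$min_in_mask_frac <= 1,
            a$n_perm >= 1, a$cft_p > 0, a$cft_p < 1,
            a$base_alpha > 0, a$base_alpha < 1,
            a$min_roi_volume_mm3 > 0, a$connectivity %in% c(6L, 26L))
  stopifnot(config$cohort$n_participants >= 1)
  config$phases <- config$phases %||% phases()
  stopifnot(all(config$phases %in% phases()))
  class(config) <- "study_config"
  config
}

#' Read / write a study configuration as YAML
#' @param path YAML file path.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_study_config(cfg)
}

#' @rdname read_study_config
#' @param config a `study_config`.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[fearrsa %s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full simulated study
#'
#' Executes every stage for a simulated cohort: design generation and events
#' export, behavioral simulation and mixed-model analysis, BOLD synthesis,
#' LSS beta-series estimation, whole-mask RSA metrics, searchlight maps for
#' the three planted contrasts (acquisition CS+ > CS- cue generalization,
#' reversal change > no-change item stability, reversal - acquisition
#' context specificity), cluster-level FWE inference with Bonferroni alpha
#' families, volume-thresholded ROI extraction with overlap resolution,
#' ROI-level reinstatement and specificity-linkage mixed models, and a
#' recovery report comparing group-level signs against the planted ground
#' truth. Writes a manifest with seeds, config hash, and per-file checksums.
#'
#' @param config a `study_config` (see [default_study_config()]).
#' @param verbose log stage progress.
#' @return list with `manifest`, `report`, `behavior`, `cluster_results`,
#'   `rois`, `linkage`, `metrics`, and the output `dir`.
#' @export
run_study <- function(config = default_study_config(), verbose = TRUE) {
  config <- validate_study_config(config)
  dir <- config$outputs$dir
  for (d in c("", "events", "ratings", "maps", "tables", "volumes")) {
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  geometry <- volume_geometry(config$geometry$dim,
                              config$geometry$voxel_size_mm,
                              config$geometry$tr_s)
  n_p <- config$cohort$n_participants
  seed <- config$cohort$base_seed
  use_phases <- config$phases

  ## ---- stage 1-2: designs, events, behavior --------------------------------
  stage_log(verbose, "designs + behavior (%d participants)", n_p)
  spec0 <- assign_counterbalancing(0L, seed)
  designs0 <- build_all_phases(spec0, derive_seed(seed, 5L))
  ratings <- simulate_expectancy(
    designs0,
    behavior_params(participant_sd = config$behavior$participant_sd,
                    noise_sd = config$behavior$noise_sd,
                    seed = derive_seed(seed, 6L)),
    n_participants = n_p
  )
  utils::write.table(ratings, file.path(dir, "ratings", "ratings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  behavior <- suppressWarnings(analyze_expectancy(summarize_expectancy(ratings)))
  utils::write.csv(behavior$fixed,
                   file.path(dir, "tables", "behavior_fixed.csv"),
                   row.names = FALSE)
  utils::write.csv(behavior$posthoc,
                   file.path(dir, "tables", "behavior_posthoc.csv"),
                   row.names = FALSE)

  ## ---- stage 3-4: per-participant simulation, LSS, metrics -----------------
  stage_log(verbose, "synthesis + LSS + metrics")
  set.seed(derive_seed(seed, 77L))
  deltas <- stats::rnorm(n_p, 0, config$effects$delta_sd)
  parts <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    es <- participant_effect_spec(deltas[p], config$effects$coupling)
    parts[[p]] <- simulate_participant(p - 1L, derive_seed(seed, 100L + p),
                                       geometry, es, use_phases = use_phases)
    for (ph in use_phases) {
      d <- parts[[p]]$series[[ph]]$cue$meta
      attr(d, "phase") <- ph
      write_events(d, file.path(dir, "events",
                                sprintf("sub-%02d_%s_events.tsv", p, ph)))
      if (isTRUE(config$outputs$write_volumes)) {
        write_beta_series(
          parts[[p]]$series[[ph]]$cue,
          file.path(dir, "volumes", sprintf("sub-%02d_%s_cue_betas.nii.gz", p, ph)),
          file.path(dir, "volumes", sprintf("sub-%02d_%s_cue_betas.tsv", p, ph)))
      }
    }
  }
  metrics <- do.call(rbind, lapply(parts, function(x) x$metrics))
  utils::write.csv(metrics, file.path(dir, "tables", "metrics.csv"),
                   row.names = FALSE)

  ## ---- stage 5: searchlight + cluster inference ----------------------------
  stage_log(verbose, "searchlight maps")
  nbhd <- build_neighborhoods(geometry, config$analysis$radius_mm,
                              config$analysis$min_in_mask_frac)
  contrasts <- list()
  if ("acquisition" %in% use_phases) {
    contrasts$cue_generalization_acq <- lapply(parts, function(x) {
      run_searchlight(x$series$acquisition$cue, nbhd,
                      sl_cue_generalization_contrast(c("CS++", "CS+-"),
                                                     c("CS-+", "CS--")))
    })
  }
  if ("reversal" %in% use_phases) {
    contrasts$item_stability_rev <- lapply(parts, function(x) {
      run_searchlight(x$series$reversal$cue, nbhd,
                      sl_item_stability_contrast(c("CS-+", "CS+-"),
                                                 c("CS++", "CS--")))
    })
    if ("acquisition" %in% use_phases) {
      contrasts$context_specificity <- lapply(parts, function(x) {
        run_searchlight(list(x$series$reversal$context,
                             x$series$acquisition$context),
                        nbhd, sl_context_specificity_diff())
      })
    }
  }
  for (nm in names(contrasts)) {
    for (p in seq_len(n_p)) {
      write_volume(contrasts[[nm]][[p]]$values, geometry,
                   file.path(dir, "maps", sprintf("sub-%02d_%s.nii.gz", p, nm)))
    }
  }

  stage_log(verbose, "cluster-level FWE inference (%d perms)",
            config$analysis$n_perm)
  cluster_results <- list()
  roi_sets <- list()
  for (nm in names(contrasts)) {
    n_cmp <- config$analysis$comparisons[[nm]] %||% 1L
    alpha <- bonferroni_alpha(config$analysis$base_alpha, n_cmp)
    cf <- suppressWarnings(cluster_fwe(
      contrasts[[nm]], n_perm = config$analysis$n_perm,
      cft_p = config$analysis$cft_p, alpha = alpha,
      connectivity = config$analysis$connectivity,
      seed = derive_seed(seed, 30L, match(nm, names(contrasts)))
    ))
    cluster_results[[nm]] <- cf
    write_volume(cf$t_map, geometry,
                 file.path(dir, "maps", sprintf("group_t_%s.nii.gz", nm)))
    sig <- unlist(cf$cluster_voxels[cf$clusters$significant])
    if (length(sig)) {
      roi_sets[[nm]] <- extract_rois(
        sig, geometry, config$analysis$min_roi_volume_mm3,
        config$analysis$connectivity, source = nm)
    }
  }
  cluster_table <- do.call(rbind, lapply(names(cluster_results), function(nm) {
    tab <- cluster_results[[nm]]$clusters
    if (nrow(tab)) cbind(contrast = nm, tab) else NULL
  }))
  if (is.null(cluster_table)) {
    cluster_table <- data.frame(contrast = character(0))
  }
  utils::write.csv(cluster_table, file.path(dir, "tables", "clusters.csv"),
                   row.names = FALSE)

  rois <- if (length(roi_sets)) resolve_roi_overlaps(roi_sets) else NULL
  roi_table <- if (!is.null(rois) && length(rois$rois)) {
    do.call(rbind, lapply(rois$rois, function(r) {
      data.frame(name = r$name, n_voxels = r$n_voxels,
                 volume_mm3 = r$volume_mm3, source = r$source)
    }))
  } else data.frame(name = character(0))
  utils::write.csv(roi_table, file.path(dir, "tables", "rois.csv"),
                   row.names = FALSE)

  ## ---- stage 6: ROI / linkage mixed models ---------------------------------
  stage_log(verbose, "linkage mixed models")
  linkage <- NULL
  if (all(c("acquisition", "reversal", "test_old") %in% use_phases)) {
    roi_voxels <- if (!is.null(rois) && length(rois$rois)) {
      match(rois$rois[[1]]$voxels, mask_indices(geometry))
    } else {
      seq_len(sum(geometry$mask))  # fall back to the whole mask
    }
    linkage <- linkage_stage(parts, roi_voxels)
    utils::write.csv(linkage$reinstatement_lme$fixed,
                     file.path(dir, "tables", "reinstatement_lme.csv"),
                     row.names = FALSE)
    utils::write.csv(linkage$pair_fdr,
                     file.path(dir, "tables", "specificity_linkage.csv"),
                     row.names = FALSE)
  }

  ## ---- stage 7: recovery report + manifest ---------------------------------
  report <- recovery_report(metrics, linkage)
  utils::write.csv(report, file.path(dir, "tables", "report.csv"),
                   row.names = FALSE)

  manifest <- build_manifest(config, dir, seed)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  stage_log(verbose, "done: %s", dir)
  invisible(list(
    manifest = manifest, report = report, behavior = behavior,
    cluster_results = cluster_results, rois = rois, linkage = linkage,
    metrics = metrics, dir = dir
  ))
}

linkage_stage <- function(parts, roi_voxels) {
  rows <- list()
  link_rows <- list()
  for (p in seq_along(parts)) {
    ser <- parts[[p]]$series
    sub <- function(s) subset_voxels(s, roi_voxels)
    spec_diff <- context_specificity(build_rsm(sub(ser$reversal$context))) -
      context_specificity(build_rsm(sub(ser$acquisition$context)))
    for (src in c("acquisition", "reversal")) {
      rsm_x <- build_rsm(sub(ser[[src]]$cue), sub(ser$test_old$cue))
      for (mode in c("item", "generalized")) {
        re <- reinstatement(rsm_x, mode)
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, phase = src, cs_type = re$cs_type, mode = mode,
          value = re$value)
        keep <- re$cs_type %in% c("CS-+", "CS+-")
        if (src == "acquisition") {
          link_rows[[length(link_rows) + 1]] <- data.frame(
            participant = p, cs_type = re$cs_type[keep], mode = mode,
            specificity = spec_diff, reinstatement = re$value[keep])
        }
      }
    }
  }
  reinst <- do.call(rbind, rows)
  link <- do.call(rbind, link_rows)
  item_tab <- reinst[reinst$mode == "item", ]
  item_tab$value <- item_tab$value
  reinst_lme <- suppressWarnings(roi_phase_lme(
    data.frame(participant = item_tab$participant, value = item_tab$value,
               phase = item_tab$phase, cs_type = item_tab$cs_type)
  ))
  fit_mode <- function(mode) {
    suppressWarnings(specificity_reinstatement_lme(
      link[link$mode == mode, c("participant", "cs_type", "specificity",
                                "reinstatement")], mode))
  }
  li <- fit_mode("item")
  lg <- fit_mode("generalized")
  list(reinstatement_table = reinst, reinstatement_lme = reinst_lme,
       item = li, generalized = lg, pair_fdr = linkage_pair_fdr(li, lg))
}

recovery_report <- function(metrics, linkage) {
  pick <- function(metric, phase, conds) {
    sub <- metrics[metrics$metric == metric & metrics$phase == phase &
                     metrics$condition %in% conds, ]
    tapply(sub$value, sub$participant, mean)
  }
  vals <- c(
    cue_generalization_contrast = tryCatch(mean(
      pick("cue_generalization", "acquisition", c("CS++", "CS+-")) -
        pick("cue_generalization", "acquisition", c("CS-+", "CS--"))),
      error = function(e) NA_real_),
    item_stability_contrast = tryCatch(mean(
      pick("item_stability", "reversal", c("CS-+", "CS+-")) -
        pick("item_stability", "reversal", c("CS++", "CS--"))),
      error = function(e) NA_real_),
    context_specificity_diff = tryCatch(mean(
      pick("context_specificity", "reversal", "all") -
        pick("context_specificity", "acquisition", "all")),
      error = function(e) NA_real_),
    linkage_interaction = if (!is.null(linkage)) {
      linkage$generalized$interaction$estimate[1]
    } else NA_real_
  )
  data.frame(
    quantity = names(vals), value = unname(vals),
    planted_sign = "positive", recovered = unname(vals > 0)
  )
}

build_manifest <- function(config, dir, seed) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.yaml"]
  sums <- tools::md5sum(files)
  cfg_yaml <- yaml::as.yaml(unclass(config))
  list(
    package_version = as.character(utils::packageVersion("fearrsa")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    base_seed = seed,
    config_md5 = unname(tools::md5sum(
      local({ tf <- tempfile(); writeLines(cfg_yaml, tf); tf }))),
    files = lapply(seq_along(files), function(i) {
      list(path = sub(paste0("^", dir, "/?"), "", files[i]),
           md5 = unname(sums[i]))
    })
  )
}
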