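#' Experiment configuration
#'
#' Bundles every tunable of the simulated two-study experiment and its
#' analysis. Defaults are the study's stated conditions: 9 memories (3 per
#' condition) x 14 repetitions over 2 sessions, TR 3.5 s, 1.5 mm voxels,
#' hippocampus/vmPFC phantom ROIs at the printed mean sizes, 3 mm smoothing,
#' 10-fold outer / 5-fold inner cross-validation, C = 1, searchlight radius
#' 3 voxels, 1000 Dice permutations.
#'
#' @param n_subjects simulated subjects (default 10, the returning cohort).
#' @param grid_shape phantom grid (default c(40, 28, 28)).
#' @param roi_size_targets named ROI voxel-count targets
#'   (default HC 928, vmPFC 1169).
#' @param long_axis hippocampal long-axis grid axis (default 1).
#' @param design a [design_spec()].
#' @param amplitudes per-(ROI, condition) signal scale: scalar, matrix, or
#'   list with elements `study1`, `study2` of either.
#' @param support_frac support sparsity (default 0.4 of ROI voxels).
#' @param support_overlap cross-condition shared-support fraction or `NULL`.
#' @param timepoint_overlap fraction of each memory's support retained at
#'   study two (default 1: unchanged representations).
#' @param noise_sd,drift_slope noise SD and per-volume drift slope.
#' @param preproc a [preproc_config()].
#' @param radius_voxels searchlight radius (default 3).
#' @param k,inner_k,C outer folds, inner folds, SVM cost.
#' @param n_perm Dice permutations (default 1000).
#' @param contrast two condition names compared by paired tests and Dice
#'   maps (default remote vs recent).
#' @param map_rois ROIs whose information maps are overlap-tested
#'   (default "HC").
#' @param split_hc if `TRUE`, also decode anterior/posterior portions of
#'   the ROI named `HC` (35% long-axis split).
#' @param anterior_fraction long-axis anterior fraction (default 0.35).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 10L,
                              grid_shape = c(40L, 28L, 28L),
                              roi_size_targets = c(HC = 928, vmPFC = 1169),
                              voxel_size_mm = 1.5,
                              long_axis = 1L,
                              design = design_spec(),
                              amplitudes = 1,
                              support_frac = 0.4,
                              support_overlap = NULL,
                              timepoint_overlap = 1,
                              noise_sd = 1,
                              drift_slope = 0.05,
                              preproc = preproc_config(),
                              radius_voxels = 3,
                              k = 10L, inner_k = 5L, C = 1,
                              n_perm = 1000L,
                              contrast = c("remote", "recent"),
                              map_rois = "HC",
                              split_hc = FALSE,
                              anterior_fraction = 0.35) {
  structure(as.list(environment()), class = "experiment_config")
}

study_amplitudes <- function(config, study) {
  a <- config$amplitudes
  if (is.list(a) && !is.null(a[[paste0("study", study)]]))
    a[[paste0("study", study)]] else a
}

#' Simulate one subject's two-study experiment
#'
#' Builds the subject's phantom geometry, plants ground-truth patterns,
#' derives study two's truth from study one via `timepoint_overlap`, draws
#' an independent trial schedule per study, and synthesizes both BOLD
#' series. All randomness flows from `seed` through documented substreams.
#'
#' @param config an [experiment_config()].
#' @param seed integer subject seed.
#' @param n_studies how many studies to simulate (default 2).
#' @return list with `geometry`, `design`, and `studies`, each study a list
#'   of `truth`, `schedule`, `bold`.
#' @export
simulate_subject <- function(config, seed = 1L, n_studies = 2L) {
  geometry <- build_phantom_rois(config$grid_shape, config$roi_size_targets,
                                 seed = substream_seed(seed, "geom"),
                                 voxel_size_mm = config$voxel_size_mm,
                                 long_axis = config$long_axis)
  design <- config$design
  truth1 <- plant_patterns(geometry, design,
                           amplitudes = study_amplitudes(config, 1),
                           support_frac = config$support_frac,
                           support_overlap = config$support_overlap,
                           noise_sd = config$noise_sd,
                           drift_slope = config$drift_slope,
                           seed = substream_seed(seed, "truth", 1))
  studies <- vector("list", n_studies)
  for (st in seq_len(n_studies)) {
    truth <- if (st == 1L) truth1 else {
      tt <- ground_truth_at_timepoint(truth1, config$timepoint_overlap,
                                      seed = substream_seed(seed, "truth", st))
      tt$amplitudes <- expand_amplitudes(study_amplitudes(config, st),
                                         names(geometry$roi_masks),
                                         design$conditions)
      tt
    }
    schedule <- make_trial_schedule(design,
                                    seed = substream_seed(seed, "sched", st))
    bold <- synthesize_bold(geometry, truth, schedule, design)
    studies[[st]] <- list(truth = truth, schedule = schedule, bold = bold)
  }
  names(studies) <- paste0("study", seq_len(n_studies))
  list(geometry = geometry, design = design, studies = studies)
}

decoding_roi_masks <- function(config, geometry) {
  masks <- geometry$roi_masks
  if (isTRUE(config$split_hc) && "HC" %in% names(masks)) {
    sp <- split_long_axis(masks[["HC"]], config$anterior_fraction,
                          config$long_axis)
    masks$HC_ant <- sp$anterior
    masks$HC_post <- sp$posterior
  }
  masks
}

#' Decode one subject's study
#'
#' Preprocesses the study's BOLD series and runs the cross-validated
#' searchlight ECOC-SVM decoder once per (ROI, condition), each condition a
#' 3-memory classification problem. Returns the per-cell accuracies, the
#' full decoding results, and the per-condition information maps.
#'
#' @param geometry the subject's `phantom_geometry`.
#' @param study a study element from [simulate_subject()].
#' @param config an [experiment_config()].
#' @param seed integer seed (fold assignment).
#' @return list with `accuracy` (data.frame roi x condition), `results`
#'   (nested list), `maps` (per ROI per condition logical maps over ROI
#'   voxels), `roi_masks` used.
#' @export
decode_study <- function(geometry, study, config, seed = 1L) {
  masks <- decoding_roi_masks(config, geometry)
  patterns <- preprocess_subject(study$bold, study$schedule, masks,
                                 config$preproc)
  conds <- config$design$conditions
  rows <- list(); results <- list(); maps <- list()
  for (roi in names(masks)) {
    spheres <- enumerate_spheres(masks[[roi]], config$radius_voxels)
    results[[roi]] <- list(); maps[[roi]] <- list()
    for (cc in conds) {
      sel <- patterns[[roi]]$condition == cc
      ps <- subset_patterns(patterns[[roi]], sel)
      res <- suppressMessages(
        cross_validate(ps, spheres, k = config$k, C = config$C,
                       seed = substream_seed(seed, roi, cc),
                       inner_k = config$inner_k))
      results[[roi]][[cc]] <- res
      maps[[roi]][[cc]] <- build_information_map(res)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, condition = cc, accuracy = res$mean_accuracy,
        chance = res$chance, n_trials = res$n_trials,
        stringsAsFactors = FALSE)
    }
  }
  list(accuracy = do.call(rbind, rows), results = results, maps = maps,
       roi_masks = masks)
}

#' Run a full simulated experiment
#'
#' Simulates `n_subjects` x 2 studies, runs preprocessing, decoding and
#' information maps per ROI, and computes the group statistics: one-tailed
#' one-sample t vs chance per (study, ROI, condition); repeated-measures
#' ANOVA over conditions and the paired contrast per (study, ROI); the
#' study x contrast interaction per ROI; and Dice permutation tests of
#' information-map overlap (within-study contrast pair, and the same
#' condition across studies) for `map_rois`. No multiple-testing correction
#' is applied (threshold p < 0.05 throughout); the report counts the tests
#' run. The report regenerates bit-identically from the same master seed.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @param n_studies studies per subject (default 2).
#' @return an object of class `experiment_report`: `accuracy` (long
#'   data.frame), `vs_chance`, `condition_tests`, `interaction`,
#'   `dice_within`, `dice_across`, `n_tests`, `config`, `seed`.
#' @export
run_experiment <- function(config, seed = 1L, n_studies = 2L) {
  acc <- list(); maps <- list(); rois_used <- NULL
  for (s in seq_len(config$n_subjects)) {
    sub <- simulate_subject(config, seed = substream_seed(seed, "subject", s),
                            n_studies = n_studies)
    for (st in seq_len(n_studies)) {
      dec <- decode_study(sub$geometry, sub$studies[[st]], config,
                          seed = substream_seed(seed, "decode", s, st))
      a <- dec$accuracy
      a$subject <- s; a$study <- st
      acc[[length(acc) + 1L]] <- a
      for (roi in intersect(config$map_rois, names(dec$maps)))
        maps[[paste(s, st, roi, sep = ".")]] <- list(
          subject = s, study = st, roi = roi, maps = dec$maps[[roi]],
          roi_vox = sum(dec$roi_masks[[roi]]))
      rois_used <- names(dec$results)
    }
  }
  accuracy <- do.call(rbind, acc)
  conds <- config$design$conditions
  n_tests <- 0L

  cell <- function(st, roi, cc) {
    v <- accuracy$accuracy[accuracy$study == st & accuracy$roi == roi &
                             accuracy$condition == cc]
    v[order(accuracy$subject[accuracy$study == st & accuracy$roi == roi &
                               accuracy$condition == cc])]
  }

  vs_chance <- list(); condition_tests <- list(); interaction <- list()
  for (st in seq_len(n_studies)) {
    for (roi in rois_used) {
      for (cc in conds) {
        v <- cell(st, roi, cc)
        # chance = 1 / n memories per condition (a 3-way problem by default)
        chance <- 1 / config$design$n_memories_per_condition
        tt <- tryCatch(t_one_sample(v, chance, one_tailed = TRUE),
                       error = function(e) list(t = NA, df = length(v) - 1,
                                                p = NA))
        vs_chance[[length(vs_chance) + 1L]] <- data.frame(
          study = st, roi = roi, condition = cc, n = length(v),
          mean_accuracy = mean(v), t = tt$t, df = tt$df, p = tt$p,
          test = "one-sample t vs chance, one-tailed",
          stringsAsFactors = FALSE)
        n_tests <- n_tests + 1L
      }
      m <- vapply(conds, function(cc) cell(st, roi, cc),
                  numeric(config$n_subjects))
      an <- tryCatch(rm_anova_oneway(m), error = function(e)
        list(F = NA, df1 = NA, df2 = NA, p = NA))
      pt <- tryCatch(t_paired(cell(st, roi, config$contrast[1]),
                              cell(st, roi, config$contrast[2])),
                     error = function(e) list(t = NA, df = NA, p = NA))
      condition_tests[[length(condition_tests) + 1L]] <- data.frame(
        study = st, roi = roi, F = an$F, df1 = an$df1, df2 = an$df2,
        p_anova = an$p,
        contrast = paste(config$contrast, collapse = " - "),
        t_paired = pt$t, df_paired = pt$df, p_paired = pt$p,
        stringsAsFactors = FALSE)
      n_tests <- n_tests + 2L
    }
  }
  if (n_studies >= 2L) {
    for (roi in rois_used) {
      ia <- tryCatch(rm_anova_interaction_2x2(
        cell(1, roi, config$contrast[2]), cell(1, roi, config$contrast[1]),
        cell(2, roi, config$contrast[2]), cell(2, roi, config$contrast[1])),
        error = function(e) list(F = NA, df1 = NA, df2 = NA, p = NA))
      interaction[[length(interaction) + 1L]] <- data.frame(
        roi = roi, F = ia$F, df1 = ia$df1, df2 = ia$df2, p = ia$p,
        test = "study x condition interaction (2x2 RM)",
        stringsAsFactors = FALSE)
      n_tests <- n_tests + 1L
    }
  }

  dice_within <- list(); dice_across <- list()
  for (roi in config$map_rois) {
    for (st in seq_len(n_studies)) {
      keys <- paste(seq_len(config$n_subjects), st, roi, sep = ".")
      entries <- maps[keys]
      if (any(vapply(entries, is.null, TRUE))) next
      ma <- lapply(entries, function(e) e$maps[[config$contrast[1]]])
      mb <- lapply(entries, function(e) e$maps[[config$contrast[2]]])
      roi_full <- lapply(entries, function(e) rep(TRUE, e$roi_vox))
      dt <- tryCatch(permutation_overlap_test(
        ma, mb, roi_full, n_perm = config$n_perm,
        seed = substream_seed(seed, "dice", roi, st)),
        error = function(e) NULL)
      if (!is.null(dt))
        dice_within[[paste(roi, st, sep = ".")]] <- dt
      n_tests <- n_tests + 1L
    }
    if (n_studies >= 2L) {
      for (cc in conds) {
        e1 <- maps[paste(seq_len(config$n_subjects), 1, roi, sep = ".")]
        e2 <- maps[paste(seq_len(config$n_subjects), 2, roi, sep = ".")]
        if (any(vapply(e1, is.null, TRUE)) || any(vapply(e2, is.null, TRUE)))
          next
        dt <- tryCatch(permutation_overlap_test(
          lapply(e1, function(e) e$maps[[cc]]),
          lapply(e2, function(e) e$maps[[cc]]),
          lapply(e1, function(e) rep(TRUE, e$roi_vox)),
          n_perm = config$n_perm,
          seed = substream_seed(seed, "diceX", roi, cc)),
          error = function(e) NULL)
        if (!is.null(dt)) dice_across[[paste(roi, cc, sep = ".")]] <- dt
        n_tests <- n_tests + 1L
      }
    }
  }

  structure(list(accuracy = accuracy,
                 vs_chance = do.call(rbind, vs_chance),
                 condition_tests = do.call(rbind, condition_tests),
                 interaction = if (length(interaction))
                   do.call(rbind, interaction) else NULL,
                 dice_within = dice_within,
                 dice_across = dice_across,
                 n_tests = n_tests,
                 sphericity_correction = "none",
                 multiple_testing_correction = "none",
                 seed = as.integer(seed)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  cat(sprintf("  %d accuracy cells, %d statistical tests (no multiplicity correction)\n",
              nrow(x$accuracy), x$n_tests))
  agg <- stats::aggregate(accuracy ~ study + roi + condition, x$accuracy, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Serialise an experiment report to JSON
#'
#' @param report an `experiment_report`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_experiment_report <- function(report, path) {
  x <- list(accuracy = report$accuracy,
            vs_chance = report$vs_chance,
            condition_tests = report$condition_tests,
            interaction = report$interaction,
            dice_within = lapply(report$dice_within, unclass),
            dice_across = lapply(report$dice_across, unclass),
            n_tests = report$n_tests,
            sphericity_correction = report$sphericity_correction,
            multiple_testing_correction = report$multiple_testing_correction,
            seed = report$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Average accuracies across hemispheres
#'
#' Collapses ROI names differing only by a `_L` / `_R` suffix (e.g. `HC_L`,
#' `HC_R`) by averaging their accuracies within subject, study and
#' condition; testing then proceeds on the collapsed values.
#'
#' @param accuracy the long accuracy data.frame of an `experiment_report`.
#' @return the collapsed data.frame.
#' @export
collapse_hemispheres <- function(accuracy) {
  base <- sub("_[LR]$", "", accuracy$roi)
  stats::aggregate(accuracy ~ subject + study + roi + condition,
                   transform(accuracy, roi = base), mean)
}
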