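#' Pipeline run configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]:
#' task overrides, population parameters, toy geometry, explicit seeds,
#' the number of split-half permutations (default 5000), the uncorrected
#' thresholds for the overlap analysis (default 0.05, 0.01, 0.001), and
#' the output mode.
#'
#' @param overrides Named list overriding any of the defaults: `task`
#'   (list for [make_task_config()]), `population` (list for
#'   [population_params()]), `geometry` (a [toy_geometry()] object),
#'   `neural` (logical), `seed_sim`, `seed_split`, `n_permutations`,
#'   `thresholds`, `mode` (`"simulate"`, `"analyze"` or `"full"`),
#'   `out_dir`, `voxelwise` (logical).
#' @return An object of class `pit_run_config`.
#' @export
run_config <- function(overrides = list()) {
  defaults <- list(
    task = list(),
    population = list(),
    geometry = NULL,
    neural = TRUE,
    seed_sim = 1L,
    seed_split = 2L,
    n_permutations = 5000L,
    thresholds = c(0.05, 0.01, 0.001),
    mode = "full",
    out_dir = NULL,
    voxelwise = TRUE
  )
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop_pitrel("unknown run config key(s): ",
                  paste(unknown, collapse = ", "),
                  class = "pitrel_config_error")
    defaults[names(overrides)] <- overrides
  }
  cfg <- defaults
  cfg$mode <- match.arg(cfg$mode, c("full", "simulate", "analyze"))
  cfg$seed_sim <- assert_count(cfg$seed_sim, "seed_sim")
  cfg$seed_split <- assert_count(cfg$seed_split, "seed_split")
  cfg$n_permutations <- assert_count(cfg$n_permutations, "n_permutations",
                                     min = 1)
  if (any(cfg$thresholds <= 0 | cfg$thresholds >= 1))
    stop_pitrel("thresholds must lie strictly inside (0, 1)",
                class = "pitrel_validation_error")
  if (cfg$neural && is.null(cfg$geometry)) cfg$geometry <- toy_geometry()
  structure(cfg, class = "pit_run_config")
}

#' Per-subject, per-session PIT effect table
#'
#' Computes both behavioural PIT parameters for every subject and
#' session: the interference error-rate difference and the motivational
#' slope (fixed effect plus conditional mode from the Poisson mixed
#' model, or the unshrunken per-subject two-stage slope).
#'
#' @param trials Trial records covering one or two sessions.
#' @param method `"glmm"` (default) or `"two_stage"` for the motivational
#'   slope.
#' @return Data frame with columns `subject_id`, `session`,
#'   `interference_effect`, `motivational_slope`.
#' @export
effect_table <- function(trials, method = c("glmm", "two_stage")) {
  method <- match.arg(method)
  pit <- trials[trials$phase == "pit", ]
  out <- list()
  for (s in sort(unique(pit$session))) {
    d <- pit[pit$session == s, ]
    by_subj <- split(d, d$subject_id)
    inter <- vapply(by_subj, function(x)
      as.numeric(interference_effect(x, quiet = TRUE)), 0.0)
    slopes <- if (method == "glmm")
      subject_motivational_slopes(fit_motivational_glmm(d))
    else two_stage_motivational(d)
    ids <- names(by_subj)
    out[[as.character(s)]] <- data.frame(
      subject_id = ids, session = s,
      interference_effect = unname(inter[ids]),
      motivational_slope = unname(slopes[ids]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# effect function used inside the split-half permutation loop
motivational_half_effect <- function(d) {
  poisson_slope_one(d$cue_value, d$go_nogo, d$button_presses)
}

interference_half_effect <- function(d) {
  as.numeric(interference_effect(d, quiet = TRUE))
}

#' Behavioural reliability report block
#'
#' Produces the behavioural summary: per-session permutation split-half
#' reliability for the interference and motivational PIT effects,
#' between-session agreement ICC with its confidence interval and
#' companion Pearson correlation, a paired t-test of between-session
#' change, and the qualitative labels under both guideline schemes.
#'
#' The motivational effect entering the split-half permutations is the
#' fast per-subject Poisson slope (a full mixed-model fit per half per
#' permutation would be prohibitive); the test-retest row uses the
#' mixed-model conditional-mode slopes.
#'
#' @param trials Trial records for both sessions.
#' @param n_perm Number of split-half permutations.
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `pit_behavioural_report` with the summary data
#'   frame `table`, the per-measure `icc` objects, `t_tests`, and
#'   `split_half` objects.
#' @export
behavioural_report <- function(trials, n_perm = 5000, seed) {
  if (missing(seed)) stop_pitrel("seed must be provided explicitly")
  pit <- trials[trials$phase == "pit", ]
  sessions <- sort(unique(pit$session))
  measures <- c(interference = "interference_effect",
                motivational = "motivational_slope")
  sh <- list()
  k <- 0L
  for (m in names(measures)) {
    fn <- if (m == "interference") interference_half_effect
          else motivational_half_effect
    for (s in sessions) {
      k <- k + 1L
      sh[[paste(m, s, sep = "_T")]] <-
        split_half_reliability(pit[pit$session == s, ], fn,
                               n_perm = n_perm, seed = seed + k)
    }
  }
  eff <- effect_table(trials, method = "glmm")
  icc <- list(); tt <- list()
  if (length(sessions) == 2L) {
    for (m in names(measures)) {
      wide <- merge(
        eff[eff$session == sessions[1], c("subject_id", measures[[m]])],
        eff[eff$session == sessions[2], c("subject_id", measures[[m]])],
        by = "subject_id", suffixes = c("_1", "_2")
      )
      vals <- as.matrix(wide[, -1])
      icc[[m]] <- icc_agreement(vals)
      tt[[m]] <- paired_t_test(vals[, 1], vals[, 2])
    }
  }
  rows <- list()
  for (m in names(measures)) {
    for (s in sessions) {
      v <- sh[[paste(m, s, sep = "_T")]]$coefficient
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, statistic = paste0("split_half_T", s),
        value = v, ci_low = NA_real_, ci_high = NA_real_,
        pearson_r = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
        label_koo_li = classify_reliability(v, "koo_li"),
        label_cicchetti = classify_reliability(v, "cicchetti"),
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(icc[[m]])) {
      ic <- icc[[m]]; t1 <- tt[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, statistic = "test_retest",
        value = ic$icc, ci_low = ic$ci_low, ci_high = ic$ci_high,
        pearson_r = ic$pearson_r,
        t = t1$t_statistic, df = t1$df, p = t1$p_value,
        label_koo_li = classify_reliability(min(ic$icc, 1), "koo_li"),
        label_cicchetti = classify_reliability(min(ic$icc, 1), "cicchetti"),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(table = do.call(rbind, rows), split_half = sh,
                 icc = icc, t_tests = tt),
            class = "pit_behavioural_report")
}

# run first-level analyses for every subject-session and collect the
# quantities the neural report needs; streams subjects to bound memory
collect_neural <- function(trials, traits, population, geometry,
                           seed_neural, thresholds, voxelwise = TRUE) {
  subjects <- unique(traits$subject_id)
  rois <- names(geometry$masks)
  models <- c("interference", "motivational")
  set.seed(seed_neural)
  deviations <- sample_neural_deviations(population, subjects, geometry)
  blocks <- c("split_T1", "split_T2", "test_retest")

  roi_vals <- list()   # [[block]][[contrast]][[roi]] -> n x 2 matrix rows
  jac_rows <- list()
  betas_session <- list(`1` = list(), `2` = list())  # [[sess]][[contrast]]

  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    set.seed(seed_neural + i)
    per_session <- list()
    for (s in 1:2) {
      tr <- traits[traits$subject_id == sid & traits$session == s, ]
      pit <- trials[trials$subject_id == sid & trials$session == s &
                      trials$phase == "pit", ]
      sim <- simulate_neural_trials(pit, tr, population$neural, geometry,
                                    deviations)
      full <- list()
      for (m in models)
        full[[m]] <- estimate_first_level(sim$amplitudes,
                                          build_design(pit, m), geometry)
      halves <- split_half_neural(pit, sim$amplitudes, geometry)
      per_session[[s]] <- list(full = full, halves = halves)
    }
    # accumulate
    for (m in models) {
      contrasts <- names(per_session[[1]]$full[[m]]$contrasts)
      for (cn in contrasts) {
        pairs <- list(
          split_T1 = list(per_session[[1]]$halves$A[[m]],
                          per_session[[1]]$halves$B[[m]]),
          split_T2 = list(per_session[[2]]$halves$A[[m]],
                          per_session[[2]]$halves$B[[m]]),
          test_retest = list(per_session[[1]]$full[[m]],
                             per_session[[2]]$full[[m]])
        )
        for (bl in blocks) {
          fl1 <- pairs[[bl]][[1]]; fl2 <- pairs[[bl]][[2]]
          mv <- vapply(rois, function(r) c(
            roi_mean(fl1$contrasts[[cn]]$beta, geometry$masks[[r]]),
            roi_mean(fl2$contrasts[[cn]]$beta, geometry$masks[[r]])
          ), numeric(2))
          roi_vals[[bl]][[cn]] <-
            rbind(roi_vals[[bl]][[cn]],
                  matrix(mv, nrow = 1,
                         dimnames = list(sid, paste(
                           rep(rois, each = 2), c("m1", "m2"), sep = "."))))
          for (p_thr in thresholds) {
            j <- jaccard(
              threshold_map(fl1$contrasts[[cn]]$t, fl1$df, p_thr),
              threshold_map(fl2$contrasts[[cn]]$t, fl2$df, p_thr)
            )
            jac_rows[[length(jac_rows) + 1L]] <- data.frame(
              subject_id = sid, block = bl, contrast = cn,
              threshold = p_thr, jaccard = j$jaccard,
              n_union = j$n_union, stringsAsFactors = FALSE
            )
          }
        }
        if (voxelwise) {
          for (s in 1:2)
            betas_session[[s]][[cn]] <-
              rbind(betas_session[[s]][[cn]],
                    as.vector(per_session[[s]]$full[[m]]$contrasts[[cn]]$beta))
        }
      }
    }
  }
  vox <- NULL
  if (voxelwise) {
    vox <- list()
    for (cn in names(betas_session[[1]]))
      vox[[cn]] <- voxelwise_icc(betas_session[[1]][[cn]],
                                 betas_session[[2]][[cn]], geometry)
  }
  list(roi_values = roi_vals, jaccard = do.call(rbind, jac_rows),
       voxelwise = vox, rois = rois, blocks = blocks)
}

#' Neural reliability report block
#'
#' Summarizes the collected first-level results into the neural report:
#' one agreement ICC (with CI and labels) per ROI, contrast and block
#' (split-half per session, and test-retest), plus global Jaccard overlap
#' rows (the arithmetic mean over subjects of the individual-level
#' coefficients; subjects with both maps empty are excluded and counted).
#'
#' @param collected The structure produced by the neural stage of
#'   [run_pipeline()] (ROI mean values, per-subject Jaccard coefficients,
#'   optional voxel-wise ICC maps).
#' @param thresholds Uncorrected p thresholds for the global rows.
#' @return A list of class `pit_neural_report` with the summary data
#'   frame `table` and the voxel-wise ICC maps (if computed).
#' @export
neural_report <- function(collected, thresholds = c(0.05, 0.01, 0.001)) {
  rows <- list()
  rois <- collected$rois
  for (bl in names(collected$roi_values)) {
    for (cn in names(collected$roi_values[[bl]])) {
      mat <- collected$roi_values[[bl]][[cn]]
      for (r in rois) {
        vals <- mat[, paste(r, c("m1", "m2"), sep = "."), drop = FALSE]
        ic <- tryCatch(icc_agreement(vals), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          block = bl, contrast = cn, region = r, threshold = NA_real_,
          value = if (is.null(ic)) NA_real_ else ic$icc,
          ci_low = if (is.null(ic)) NA_real_ else ic$ci_low,
          ci_high = if (is.null(ic)) NA_real_ else ic$ci_high,
          n = nrow(vals),
          label_koo_li = if (is.null(ic)) NA_character_ else
            classify_reliability(min(ic$icc, 1), "koo_li"),
          label_cicchetti = if (is.null(ic)) NA_character_ else
            classify_reliability(min(ic$icc, 1), "cicchetti"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  jac <- collected$jaccard
  if (!is.null(jac)) {
    agg <- split(jac, list(jac$block, jac$contrast, jac$threshold),
                 drop = TRUE)
    for (g in agg) {
      valid <- is.finite(g$jaccard)
      rows[[length(rows) + 1L]] <- data.frame(
        block = g$block[1], contrast = g$contrast[1], region = "global",
        threshold = g$threshold[1],
        value = if (any(valid)) mean(g$jaccard[valid]) else NaN,
        ci_low = NA_real_, ci_high = NA_real_,
        n = sum(valid),
        label_koo_li = NA_character_, label_cicchetti = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, voxelwise = collected$voxelwise,
                 jaccard_by_subject = jac),
            class = "pit_neural_report")
}

#' Run the full reliability pipeline
#'
#' Simulates (or analyses) a two-session PIT study end to end: task
#' simulation, behavioural effect estimation per session and per split,
#' permutation split-half and test-retest statistics, neural first-level
#' estimation with split-half re-estimation, ROI and voxel-wise ICCs, and
#' Jaccard overlap at the configured thresholds. Every random draw
#' descends from the two seeds in the configuration, so a rerun with the
#' same configuration reproduces every report cell.
#'
#' @param config A [run_config()] object.
#' @param trials Optional pre-existing trial table (skips behavioural
#'   simulation; used for the real-data path).
#' @return An object of class `pit_report`: list with `behavioural`
#'   (a [behavioural_report()]), `neural` (a [neural_report()] or
#'   `NULL`), `trials`, `manifest`. When `config$out_dir` is set, CSV
#'   tables, the JSON manifest and any voxel-wise ICC maps are written
#'   there.
#' @export
run_pipeline <- function(config = run_config(), trials = NULL) {
  stopifnot(inherits(config, "pit_run_config"))
  task <- make_task_config(config$task)
  population <- do.call(population_params, config$population)

  traits <- NULL
  if (is.null(trials)) {
    study <- simulate_study(task, population, geometry = NULL,
                            seed = config$seed_sim)
    trials <- study$trials
    traits <- study$traits
    manifest <- study$manifest
  } else {
    manifest <- list(seed = config$seed_sim, source = "user-supplied trials")
  }
  manifest$seed_split <- config$seed_split
  manifest$n_permutations <- config$n_permutations
  manifest$thresholds <- config$thresholds

  if (config$mode == "simulate") {
    out <- structure(list(behavioural = NULL, neural = NULL,
                          trials = trials, manifest = manifest),
                     class = "pit_report")
    write_report(out, config)
    return(out)
  }

  message("pitrel: behavioural reliability (",
          config$n_permutations, " permutations)")
  behav <- behavioural_report(trials, n_perm = config$n_permutations,
                              seed = config$seed_split)

  neural <- NULL
  if (config$neural && !is.null(traits)) {
    message("pitrel: neural first-level + reliability")
    collected <- collect_neural(trials, traits, population,
                                config$geometry,
                                seed_neural = config$seed_sim + 1000003L,
                                thresholds = config$thresholds,
                                voxelwise = config$voxelwise)
    neural <- neural_report(collected, config$thresholds)
  }
  out <- structure(list(behavioural = behav, neural = neural,
                        trials = trials, manifest = manifest),
                   class = "pit_report")
  write_report(out, config)
  out
}

write_report <- function(report, config) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(report$trials, file.path(dir, "trials.csv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$behavioural))
    utils::write.csv(report$behavioural$table,
                     file.path(dir, "behavioural_report.csv"),
                     row.names = FALSE)
  if (!is.null(report$neural)) {
    utils::write.csv(report$neural$table,
                     file.path(dir, "neural_report.csv"), row.names = FALSE)
    if (!is.null(report$neural$voxelwise)) {
      for (cn in names(report$neural$voxelwise)) {
        v <- report$neural$voxelwise[[cn]]
        v[!is.finite(v)] <- 0
        write_volume(v, file.path(dir, paste0("icc_", cn, ".nii.gz")))
      }
    }
  }
  invisible(dir)
}

#' @export
print.pit_report <- function(x, ...) {
  cat("PIT reliability report\n")
  if (!is.null(x$behavioural)) {
    cat("\nBehavioural block:\n")
    print(x$behavioural$table, digits = 3)
  }
  if (!is.null(x$neural)) {
    cat("\nNeural block (first rows):\n")
    print(utils::head(x$neural$table, 12), digits = 3)
  }
  invisible(x)
}
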