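#' Draw subject- and session-level neural map deviations
#'
#' For every subject, signal component and ROI, draws a stable subject
#' deviation (correlated across the two sessions at the population
#' `rho_trait`) plus an independent session deviation. These deviations are
#' constant within an ROI, which makes them survive ROI averaging and
#' induces the between-subject variance that reliability statistics
#' measure. Consumes the current RNG stream.
#'
#' @param population A [population_params()] object.
#' @param subject_ids Character vector of subject identifiers.
#' @param geometry A [toy_geometry()] object (fixes the ROI set).
#'
#' @return A list, one element per signal component, each an array of
#'   dimension `n_subjects x n_rois x 2` (sessions) holding the total
#'   deviation (subject + session part) of the component amplitude.
#' @export
sample_neural_deviations <- function(population, subject_ids, geometry) {
  stopifnot(inherits(population, "pit_population"),
            inherits(geometry, "pit_geometry"))
  if (inherits(subject_ids, "data.frame"))
    subject_ids <- unique(subject_ids$subject_id)
  np <- population$neural
  rho <- population$rho_trait
  n <- length(subject_ids)
  rois <- names(geometry$masks)
  out <- list()
  for (comp in np$components) {
    s_sd <- np$sd_subject_map[[comp]]
    e_sd <- np$sd_session_map[[comp]]
    z1 <- matrix(stats::rnorm(n * length(rois)), n)
    z2 <- matrix(stats::rnorm(n * length(rois)), n)
    subj1 <- s_sd * z1
    subj2 <- s_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    dev <- array(0, c(n, length(rois), 2L),
                 dimnames = list(subject_ids, rois, c("1", "2")))
    dev[, , 1L] <- subj1 + e_sd * matrix(stats::rnorm(n * length(rois)), n)
    dev[, , 2L] <- subj2 + e_sd * matrix(stats::rnorm(n * length(rois)), n)
    out[[comp]] <- dev
  }
  out
}

# component regressor values for a set of transfer trials
neural_component_matrix <- function(pit_trials) {
  lp <- log(pit_trials$button_presses + 1)
  cbind(
    onset        = rep(1, nrow(pit_trials)),
    incongruent  = as.numeric(pit_trials$congruency == "incongruent"),
    congruent    = as.numeric(pit_trials$congruency == "congruent"),
    cs_value     = pit_trials$cue_value,
    log_presses  = lp,
    motivational = pit_trials$cue_value * lp
  )
}

# per-voxel amplitude field of each component for one subject-session
build_beta_field <- function(traits_row, neural_params, geometry,
                             deviations = NULL) {
  roi_lab <- roi_voxel_index(geometry)
  inside <- roi_lab > 0L
  n_comp <- length(neural_params$components)
  B <- matrix(0, n_comp, geometry$n_voxels,
              dimnames = list(neural_params$components, NULL))
  for (k in seq_len(n_comp)) {
    comp <- neural_params$components[k]
    amp <- neural_params$roi_amplitudes[[comp]]
    per_roi <- amp[names(geometry$masks)]
    per_roi[is.na(per_roi)] <- 0
    if (!is.null(deviations)) {
      dv <- deviations[[comp]][traits_row$subject_id, ,
                               as.character(traits_row$session)]
      per_roi <- per_roi + dv[names(geometry$masks)]
    }
    B[k, inside] <- per_roi[roi_lab[inside]]
  }
  B
}

#' Simulate trial-level voxel amplitudes for one subject-session
#'
#' The amplitude of trial `t` at voxel `j` is the sum over signal
#' components `k` of `x[t, k] * beta_field[k, j]` plus i.i.d. Gaussian
#' trial noise, where `x` holds the component regressor values realized in
#' the behavioural transfer trials (onset, congruency indicators, cue
#' value, log button presses, and the value-by-vigour interaction) and the
#' beta field is the group ROI amplitude plus the subject/session
#' deviations of [sample_neural_deviations()].
#'
#' @param pit_trials Transfer-phase trial records for one subject-session.
#' @param traits_row The matching row of the trait table.
#' @param neural_params A [neural_params()] object.
#' @param geometry A [toy_geometry()] object.
#' @param deviations Deviation list from [sample_neural_deviations()];
#'   `NULL` for a group-average subject.
#'
#' @return A list with `amplitudes` (trials-by-voxel matrix), `masks`
#'   (the geometry's ROI masks) and `geometry`. Consumes the RNG stream.
#' @export
simulate_neural_trials <- function(pit_trials, traits_row, neural_params,
                                   geometry, deviations = NULL) {
  stopifnot(inherits(geometry, "pit_geometry"),
            inherits(neural_params, "pit_neural_params"))
  if (!all(pit_trials$phase == "pit"))
    stop_pitrel("pit_trials must contain transfer-phase rows only")
  X <- neural_component_matrix(pit_trials)
  B <- build_beta_field(traits_row, neural_params, geometry, deviations)
  Y <- X %*% B
  if (neural_params$sd_trial_noise > 0)
    Y <- Y + matrix(stats::rnorm(length(Y), 0, neural_params$sd_trial_noise),
                    nrow(Y))
  list(amplitudes = Y, masks = geometry$masks, geometry = geometry)
}
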