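#' Label transfer trials as congruent, incongruent or neutral
#'
#' A trial is incongruent when the instrumental requirement conflicts with
#' the Pavlovian cue valence: collecting under a negative cue or rejecting
#' under a positive cue. It is congruent when they agree (collect under a
#' positive cue, reject under a negative cue), and neutral when the cue
#' value is zero (zero-valued cues belong to neither class).
#'
#' @param cue_value Integer cue value(s) in euros.
#' @param required_action Character vector, `"collect"` or `"reject"`.
#' @param cue_set Optional set of admissible cue values; values outside it
#'   are an error.
#'
#' @return Character vector in `{"congruent", "incongruent", "neutral"}`.
#' @examples
#' label_congruency(-2, "collect")  # "incongruent"
#' label_congruency(+1, "reject")   # "incongruent"
#' label_congruency(0, "collect")   # "neutral"
#' @export
label_congruency <- function(cue_value, required_action, cue_set = NULL) {
  if (!is.null(cue_set) && !all(cue_value %in% cue_set))
    stop_pitrel("cue value(s) outside the configured set: ",
                paste(unique(cue_value[!cue_value %in% cue_set]),
                      collapse = ", "),
                class = "pitrel_validation_error")
  if (!all(required_action %in% c("collect", "reject")))
    stop_pitrel("required_action must be 'collect' or 'reject'",
                class = "pitrel_validation_error")
  out <- rep("neutral", length(cue_value))
  collect <- required_action == "collect"
  out[(collect & cue_value < 0) | (!collect & cue_value > 0)] <- "incongruent"
  out[(collect & cue_value > 0) | (!collect & cue_value < 0)] <- "congruent"
  out
}

#' Interference PIT effect: incongruent minus congruent error rate
#'
#' Computes the error-rate difference `ER(incongruent) - ER(congruent)`
#' for one subject-session (or one half of it). The error rate of a class
#' is the share of trials with `response_correct == FALSE` among all
#' trials of that class (omitted responses count as errors upstream);
#' neutral trials are excluded.
#'
#' @param trials Trial records for a single subject-session or split half;
#'   rows from phases other than the transfer phase are ignored.
#' @param quiet Suppress the warning emitted when a class is empty.
#'
#' @return The difference as a single number in `[-1, 1]`, with attributes
#'   `n_incongruent` and `n_congruent`. When either class is empty the
#'   result is `NA` with attribute `reason` (never a silent 0).
#' @export
interference_effect <- function(trials, quiet = FALSE) {
  if ("phase" %in% names(trials))
    trials <- trials[trials$phase == "pit", ]
  inc <- trials$congruency == "incongruent"
  con <- trials$congruency == "congruent"
  n_inc <- sum(inc, na.rm = TRUE)
  n_con <- sum(con, na.rm = TRUE)
  if (n_inc == 0L || n_con == 0L) {
    if (!quiet)
      warning("interference_effect: empty ",
              if (n_inc == 0L) "incongruent" else "congruent",
              " class; returning NA", call. = FALSE)
    return(structure(NA_real_, n_incongruent = n_inc, n_congruent = n_con,
                     reason = "empty congruency class"))
  }
  er_inc <- sum(!trials$response_correct[inc]) / n_inc
  er_con <- sum(!trials$response_correct[con]) / n_con
  structure(er_inc - er_con, n_incongruent = n_inc, n_congruent = n_con)
}

#' Fit the motivational Poisson mixed model
#'
#' Fits the generalized linear mixed model of button-press vigour on the
#' monetary Pavlovian cue value:
#' `ButtonPress ~ PavlovianValue + InstrumentalResponse_GoNogo +
#' (1 + PavlovianValue | Participant_ID) + (1 | PavlovianCue) +
#' (1 | InstrumentalCue)`, Poisson family with log link, Laplace
#' approximation, via [lme4::glmer()]. The fixed `PavlovianValue` slope is
#' the group motivational PIT effect; per-subject slopes are obtained by
#' adding the conditional modes ([subject_motivational_slopes()]).
#'
#' @param trials Transfer-phase trial records for two or more subjects
#'   (other phases are dropped automatically).
#' @param centre_value Centre the cue value before fitting (default
#'   `FALSE`: values enter in euros, -2..+2).
#' @param optimizer Optimizer name passed to [lme4::glmerControl()]
#'   (default `"bobyqa"`).
#'
#' @return An object of class `pit_glmm`: a list with elements `fixed`
#'   (estimates and SEs for intercept, value slope and go/no-go effect),
#'   `varcomps` (`sd_int_subj`, `sd_slope_subj`, `corr_subj`,
#'   `sd_pav_cue`, `sd_instr_cue`), `conditional_modes` (per-subject
#'   intercept/slope deviations), `loglik`, `converged`, `method`, and
#'   `fit` (the underlying `merMod`).
#' @export
fit_motivational_glmm <- function(trials, centre_value = FALSE,
                                  optimizer = "bobyqa") {
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "pit", ]
  y <- trials$button_presses
  if (any(is.na(y)) || any(y < 0) || any(y != round(y)))
    stop_pitrel("button_presses must be non-negative integers",
                class = "pitrel_validation_error")
  if (length(unique(trials$subject_id)) < 2L)
    stop_pitrel("at least 2 subjects required",
                class = "pitrel_validation_error")
  if (length(unique(trials$cue_value)) < 2L)
    stop_pitrel("at least 2 distinct cue values required",
                class = "pitrel_validation_error")
  d <- data.frame(
    ButtonPress = as.integer(y),
    PavlovianValue = if (centre_value) trials$cue_value - mean(trials$cue_value)
                     else trials$cue_value,
    GoNogo = trials$go_nogo,
    Participant_ID = factor(trials$subject_id),
    PavlovianCue = factor(trials$pavlovian_cue_id),
    InstrumentalCue = factor(trials$instrumental_cue_id)
  )
  fit <- lme4::glmer(
    ButtonPress ~ PavlovianValue + GoNogo +
      (1 + PavlovianValue | Participant_ID) +
      (1 | PavlovianCue) + (1 | InstrumentalCue),
    data = d, family = stats::poisson(),
    control = lme4::glmerControl(optimizer = optimizer,
                                 calc.derivs = TRUE)
  )
  sf <- summary(fit)
  co <- sf$coefficients
  vc <- lme4::VarCorr(fit)
  subj_vc <- vc$Participant_ID
  sds <- attr(subj_vc, "stddev")
  corr <- attr(subj_vc, "correlation")
  cm <- lme4::ranef(fit)$Participant_ID
  messages <- fit@optinfo$conv$lme4$messages
  converged <- fit@optinfo$conv$opt == 0 && is.null(messages)
  if (!converged)
    warning("motivational GLMM did not converge cleanly: ",
            paste(unlist(messages), collapse = "; "), call. = FALSE)
  structure(list(
    fixed = data.frame(
      term = c("intercept", "slope_value", "slope_go"),
      estimate = unname(co[, "Estimate"]),
      se = unname(co[, "Std. Error"]),
      row.names = NULL
    ),
    varcomps = list(
      sd_int_subj = unname(sds["(Intercept)"]),
      sd_slope_subj = unname(sds["PavlovianValue"]),
      corr_subj = unname(corr["(Intercept)", "PavlovianValue"]),
      sd_pav_cue = unname(attr(vc$PavlovianCue, "stddev")),
      sd_instr_cue = unname(attr(vc$InstrumentalCue, "stddev"))
    ),
    conditional_modes = data.frame(
      subject_id = rownames(cm),
      intercept_dev = cm[["(Intercept)"]],
      slope_dev = cm[["PavlovianValue"]],
      row.names = NULL
    ),
    loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    method = "glmer Laplace, crossed random effects",
    centre_value = centre_value,
    fit = fit
  ), class = "pit_glmm")
}

#' Per-subject motivational slopes from the mixed-model fit
#'
#' Each subject's motivational PIT effect is the fixed cue-value slope
#' plus that subject's conditional-mode (BLUP-analogue) slope deviation.
#' The deviations are shrunken toward zero, so these values average the
#' fixed slope and have no more variance than independently fitted
#' per-subject slopes.
#'
#' @param fit A [fit_motivational_glmm()] result.
#' @return Named numeric vector of per-subject slopes (per-euro log-rate).
#' @export
subject_motivational_slopes <- function(fit) {
  stopifnot(inherits(fit, "pit_glmm"))
  b <- fit$fixed$estimate[fit$fixed$term == "slope_value"]
  stats::setNames(b + fit$conditional_modes$slope_dev,
                  fit$conditional_modes$subject_id)
}

# lean per-subject Poisson GLM slope; X = [1, value, go]
poisson_slope_one <- function(value, go, presses) {
  X <- cbind(1, value, go)
  if (length(unique(go)) < 2L) X <- X[, 1:2, drop = FALSE]
  if (length(unique(value)) < 2L) return(NA_real_)
  fit <- suppressWarnings(
    try(stats::glm.fit(X, presses, family = stats::poisson()),
        silent = TRUE)
  )
  if (inherits(fit, "try-error") || !fit$converged) return(NA_real_)
  b <- fit$coefficients[2]
  if (!is.finite(b)) NA_real_ else unname(b)
}

#' Two-stage per-subject motivational slopes
#'
#' Independent-oracle estimator for the motivational PIT effect: a
#' separate Poisson regression `ButtonPress ~ PavlovianValue + GoNogo` is
#' fitted per subject and the cue-value slope returned. Used as a
#' cross-check on the mixed model (and as a fast per-half effect function
#' inside the permutation split-half), not as the primary estimator:
#' unlike the conditional modes, these slopes are unshrunken.
#'
#' @param trials Transfer-phase trial records (one session or split) for
#'   one or more subjects.
#' @return Named numeric vector of per-subject slopes; a subject whose fit
#'   is singular or separable gets `NA` with a diagnostic attribute
#'   `n_failed`.
#' @export
two_stage_motivational <- function(trials) {
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "pit", ]
  by_subj <- split(trials, trials$subject_id)
  out <- vapply(by_subj, function(d)
    poisson_slope_one(d$cue_value, d$go_nogo, d$button_presses), 0.0)
  structure(out, n_failed = sum(is.na(out)))
}
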