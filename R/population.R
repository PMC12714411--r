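#' Population parameters for the generative PIT model
#'
#' Describes the latent between-subject distribution from which subject
#' traits are drawn, the crossed cue effects, and the generative model of
#' the toy neural data. Each behavioural trait is drawn per subject and per
#' session from a bivariate normal whose session-1/session-2 correlation is
#' `rho_trait`; setting `rho_trait = 1` yields perfectly stable traits (the
#' classical assumption that the true score does not change over time),
#' while values below 1 introduce genuine trait change between sessions.
#'
#' The behavioural traits are, per subject:
#' \describe{
#'   \item{alpha}{baseline error log-odds on congruent/neutral transfer
#'     trials (logit units).}
#'   \item{gamma}{additive shift of the error log-odds on incongruent
#'     trials; the latent interference PIT effect.}
#'   \item{b0}{Poisson log-rate intercept for button presses.}
#'   \item{b1}{per-euro log-rate slope of presses on the Pavlovian cue
#'     value; the latent motivational PIT effect.}
#' }
#' `b_go` (the collect-vs-reject log-rate effect) is a population constant,
#' and `sd_cue_pav` / `sd_cue_instr` are the SDs of the crossed random
#' intercepts attached to the individual Pavlovian and instrumental cue
#' stimuli.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param mu_alpha,sd_alpha Mean and SD of the baseline error logit.
#' @param mu_gamma,sd_gamma Mean and SD of the incongruency shift (logit).
#' @param mu_b0,sd_b0 Mean and SD of the Poisson log-rate intercept.
#' @param mu_b1,sd_b1 Mean and SD of the per-euro motivational slope.
#' @param b_go Collect-vs-reject effect on the log press rate.
#' @param sd_cue_pav,sd_cue_instr SDs of the crossed cue intercepts.
#' @param rho_trait Session 1 to session 2 correlation shared by all traits
#'   (in `[-1, 1]`), unless overridden per trait via `rho_by_trait`.
#' @param rho_by_trait Optional named list (names among `alpha`, `gamma`,
#'   `b0`, `b1`) of per-trait correlations.
#' @param neural A list of neural generative parameters as returned by
#'   [neural_params()].
#'
#' @return An object of class `pit_population`.
#' @seealso [sample_population()], [neural_params()]
#' @export
population_params <- function(n_subjects = 119,
                              mu_alpha = stats::qlogis(0.08), sd_alpha = 0.8,
                              mu_gamma = 1.0, sd_gamma = 1.0,
                              mu_b0 = 0.5, sd_b0 = 0.4,
                              mu_b1 = 0.2, sd_b1 = 0.1,
                              b_go = 1.5,
                              sd_cue_pav = 0.05, sd_cue_instr = 0.05,
                              rho_trait = 0.7,
                              rho_by_trait = NULL,
                              neural = neural_params()) {
  p <- list(
    n_subjects = assert_count(n_subjects, "n_subjects", min = 2),
    mu_alpha = mu_alpha, sd_alpha = sd_alpha,
    mu_gamma = mu_gamma, sd_gamma = sd_gamma,
    mu_b0 = mu_b0, sd_b0 = sd_b0,
    mu_b1 = mu_b1, sd_b1 = sd_b1,
    b_go = b_go,
    sd_cue_pav = sd_cue_pav, sd_cue_instr = sd_cue_instr,
    rho_trait = rho_trait,
    rho_by_trait = rho_by_trait,
    neural = neural
  )
  for (nm in c("sd_alpha", "sd_gamma", "sd_b0", "sd_b1",
               "sd_cue_pav", "sd_cue_instr"))
    assert_scalar_number(p[[nm]], nm, min = 0)
  assert_scalar_number(p$rho_trait, "rho_trait", min = -1, max = 1)
  if (!is.null(rho_by_trait)) {
    bad <- setdiff(names(rho_by_trait), c("alpha", "gamma", "b0", "b1"))
    if (length(bad))
      stop_pitrel("unknown trait name(s) in rho_by_trait: ",
                  paste(bad, collapse = ", "),
                  class = "pitrel_config_error")
    for (nm in names(rho_by_trait))
      assert_scalar_number(rho_by_trait[[nm]], paste0("rho_by_trait$", nm),
                           min = -1, max = 1)
  }
  structure(p, class = "pit_population")
}

#' Neural generative parameters
#'
#' Parameters of the toy voxel-level generative model. Each signal
#' component corresponds to a trial-level regressor of the first-level
#' models (the common trial onset, the incongruent and congruent condition
#' responses, the Pavlovian cue value, the log button presses, and their
#' interaction -- the motivational PIT effect). A component's group
#' amplitude is specified per region of interest; subject- and
#' session-level deviations are added on top, constant within a region, and
#' subject deviations are correlated across sessions at the population
#' `rho_trait`.
#'
#' Default amplitudes give strong, largely shared responses for the
#' incongruent and congruent conditions (so that their difference carries
#' much less between-subject signal than either constituent -- the regime in
#' which difference contrasts lose reliability), a value signal in the
#' ventral striatum, a motor signal in lateral prefrontal cortex, and a
#' weak value-by-vigour interaction.
#'
#' @param roi_amplitudes Named list mapping component name to a numeric
#'   vector of group amplitudes for the ROIs `amygdala`, `VS`, `lPFC`,
#'   `dmPFC` (in that order).
#' @param sd_subject_map Between-subject SD of the per-ROI component
#'   deviation; scalar or named per component.
#' @param sd_session_map Session-specific SD of the per-ROI component
#'   deviation; scalar or named per component.
#' @param sd_trial_noise SD of the i.i.d. per-trial, per-voxel noise.
#'
#' @return A list with class `pit_neural_params`.
#' @export
neural_params <- function(roi_amplitudes = NULL,
                          sd_subject_map = c(onset = 0.50, incongruent = 0.12,
                                             congruent = 0.12, cs_value = 0.05,
                                             log_presses = 0.10,
                                             motivational = 0.03),
                          sd_session_map = 0.08,
                          sd_trial_noise = 2.0) {
  components <- c("onset", "incongruent", "congruent",
                  "cs_value", "log_presses", "motivational")
  if (is.null(roi_amplitudes)) {
    roi_amplitudes <- list(
      onset        = c(amygdala = 0.8, VS = 1.0, lPFC = 1.0, dmPFC = 1.0),
      incongruent  = c(amygdala = 0.30, VS = 0.50, lPFC = 0.55, dmPFC = 0.60),
      congruent    = c(amygdala = 0.30, VS = 0.45, lPFC = 0.50, dmPFC = 0.55),
      cs_value     = c(amygdala = 0, VS = 0.15, lPFC = 0, dmPFC = 0),
      log_presses  = c(amygdala = 0, VS = 0, lPFC = 0.30, dmPFC = 0),
      motivational = c(amygdala = 0, VS = 0.08, lPFC = 0, dmPFC = 0.05)
    )
  }
  missing_comp <- setdiff(components, names(roi_amplitudes))
  if (length(missing_comp))
    stop_pitrel("roi_amplitudes missing component(s): ",
                paste(missing_comp, collapse = ", "),
                class = "pitrel_config_error")
  expand_sd <- function(x, name) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(x, length(components)), components)
    if (!all(components %in% names(x)))
      stop_pitrel(name, " must be a scalar or named per component",
                  class = "pitrel_config_error")
    x <- x[components]
    if (any(x < 0)) stop_pitrel(name, " must be non-negative",
                                class = "pitrel_validation_error")
    x
  }
  structure(list(
    components     = components,
    roi_amplitudes = roi_amplitudes[components],
    sd_subject_map = expand_sd(sd_subject_map, "sd_subject_map"),
    sd_session_map = expand_sd(sd_session_map, "sd_session_map"),
    sd_trial_noise = assert_scalar_number(sd_trial_noise, "sd_trial_noise",
                                          min = 0)
  ), class = "pit_neural_params")
}

#' Draw subject traits for two sessions
#'
#' Samples per-subject latent traits for sessions 1 and 2 from bivariate
#' normal distributions with the population means/SDs and cross-session
#' correlation `rho_trait` (per-trait overrides honoured), together with
#' the crossed Pavlovian- and instrumental-cue random intercepts shared by
#' all subjects. Fully deterministic given `seed`.
#'
#' @param params A [population_params()] object.
#' @param seed Integer seed (mandatory; there is no hidden RNG state).
#' @param cue_values Integer cue values used to label the Pavlovian cue
#'   intercepts (default -2..2).
#'
#' @return A data frame of class `pit_traits` with one row per subject and
#'   session (columns `subject_id`, `session`, `alpha`, `gamma`, `b0`,
#'   `b1`, `b_go`) and attribute `cue_effects`, a list with the named
#'   vectors `pav` (one intercept per cue value) and `instr` (one per
#'   instrumental shell stimulus).
#' @export
sample_population <- function(params, seed,
                              cue_values = c(-2L, -1L, 0L, 1L, 2L)) {
  stopifnot(inherits(params, "pit_population"))
  if (missing(seed)) stop_pitrel("seed must be provided explicitly")
  set.seed(seed)
  n <- params$n_subjects
  rho_for <- function(trait) {
    (params$rho_by_trait[[trait]] %||% params$rho_trait)
  }
  draw_pair <- function(mu, sd, rho) {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    s1 <- mu + sd * z1
    s2 <- mu + sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    cbind(s1, s2)
  }
  alpha <- draw_pair(params$mu_alpha, params$sd_alpha, rho_for("alpha"))
  gamma <- draw_pair(params$mu_gamma, params$sd_gamma, rho_for("gamma"))
  b0    <- draw_pair(params$mu_b0, params$sd_b0, rho_for("b0"))
  b1    <- draw_pair(params$mu_b1, params$sd_b1, rho_for("b1"))

  subject_id <- sprintf("S%03d", seq_len(n))
  traits <- data.frame(
    subject_id = rep(subject_id, each = 2L),
    session    = rep(c(1L, 2L), times = n),
    alpha      = as.vector(t(alpha)),
    gamma      = as.vector(t(gamma)),
    b0         = as.vector(t(b0)),
    b1         = as.vector(t(b1)),
    b_go       = params$b_go,
    stringsAsFactors = FALSE
  )
  shells <- c("good_shell_1", "good_shell_2", "bad_shell_1", "bad_shell_2")
  cue_effects <- list(
    pav   = stats::setNames(stats::rnorm(length(cue_values), 0,
                                         params$sd_cue_pav),
                            paste0("CS", cue_values)),
    instr = stats::setNames(stats::rnorm(length(shells), 0,
                                         params$sd_cue_instr), shells)
  )
  attr(traits, "cue_effects") <- cue_effects
  attr(traits, "seed") <- seed
  class(traits) <- c("pit_traits", "data.frame")
  traits
}
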