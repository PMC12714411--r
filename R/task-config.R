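#' Task configuration for the PIT paradigm
#'
#' Builds the configuration object describing the three-phase
#' Pavlovian-to-instrumental transfer (PIT) task: an instrumental training
#' phase with a performance-based stopping rule, a passive Pavlovian
#' conditioning phase, and a transfer (PIT) phase in which the conditioned
#' stimuli are shown in the background while the instrumental task is
#' performed under nominal extinction.
#'
#' Defaults follow the standard paradigm: instrumental training runs for at
#' least 60 trials and stops as soon as accuracy over the last 16 consecutive
#' trials reaches 80%, with a hard cap at 120 trials; Pavlovian conditioning
#' comprises 80 trials, 16 per conditioned stimulus, with monetary values
#' of -2, -1, 0, +1 and +2 euros; the transfer phase comprises 90 trials of
#' 3 s each, the conditioned stimulus leading the instrumental stimulus by
#' 0.6 s so that a 2.4-s response window remains.
#'
#' @param overrides Named list of configuration values to override. Unknown
#'   names are an error.
#'
#' @return An object of class `pit_task_config`: a named list with elements
#'   `n_instrumental_min`, `n_instrumental_max`, `criterion_accuracy`,
#'   `criterion_window`, `n_pavlovian_trials`, `n_per_cue`, `cue_values`,
#'   `n_pit_trials`, `trial_duration_s`, `cs_lead_s`, `response_window_s`,
#'   and `press_cap`.
#'
#' @examples
#' cfg <- make_task_config()
#' cfg$n_pit_trials  # 90
#' small <- make_task_config(list(n_pit_trials = 30, cue_values = c(-1, 0, 1),
#'                                n_per_cue = 10, n_pavlovian_trials = 30))
#' @export
make_task_config <- function(overrides = list()) {
  defaults <- list(
    n_instrumental_min = 60L,
    n_instrumental_max = 120L,
    criterion_accuracy = 0.80,
    criterion_window   = 16L,
    n_pavlovian_trials = 80L,
    n_per_cue          = 16L,
    cue_values         = c(-2L, -1L, 0L, 1L, 2L),
    n_pit_trials       = 90L,
    trial_duration_s   = 3.0,
    cs_lead_s          = 0.6,
    response_window_s  = 2.4,
    press_cap          = Inf
  )
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop_pitrel("task config overrides must be a named list",
                  class = "pitrel_config_error")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop_pitrel("unknown task config key(s): ",
                  paste(unknown, collapse = ", "),
                  class = "pitrel_config_error")
    defaults[names(overrides)] <- overrides
  }
  cfg <- defaults
  validate_task_config(cfg)
  structure(cfg, class = "pit_task_config")
}

validate_task_config <- function(cfg) {
  assert_count(cfg$n_instrumental_min, "n_instrumental_min", min = 1)
  assert_count(cfg$n_instrumental_max, "n_instrumental_max", min = 1)
  if (cfg$n_instrumental_min > cfg$n_instrumental_max)
    stop_pitrel("n_instrumental_min exceeds n_instrumental_max",
                class = "pitrel_validation_error")
  assert_scalar_number(cfg$criterion_accuracy, "criterion_accuracy", 0, 1)
  assert_count(cfg$criterion_window, "criterion_window", min = 1)
  assert_count(cfg$n_pavlovian_trials, "n_pavlovian_trials", min = 1)
  assert_count(cfg$n_per_cue, "n_per_cue", min = 1)
  assert_count(cfg$n_pit_trials, "n_pit_trials", min = 1)
  if (!is.numeric(cfg$cue_values) || anyDuplicated(cfg$cue_values) ||
      !all(is_wholenumber(cfg$cue_values)))
    stop_pitrel("cue_values must be distinct integers",
                class = "pitrel_validation_error")
  if (cfg$n_per_cue * length(cfg$cue_values) != cfg$n_pavlovian_trials)
    stop_pitrel("invariant violated: n_per_cue * |cue_values| must equal ",
                "n_pavlovian_trials (", cfg$n_per_cue, " * ",
                length(cfg$cue_values), " != ", cfg$n_pavlovian_trials, ")",
                class = "pitrel_validation_error")
  if (abs(cfg$cs_lead_s + cfg$response_window_s - cfg$trial_duration_s) > 1e-9)
    stop_pitrel("invariant violated: cs_lead_s + response_window_s must ",
                "equal trial_duration_s",
                class = "pitrel_validation_error")
  n_cells <- 2L * length(cfg$cue_values)
  if (cfg$n_pit_trials %% n_cells != 0L)
    stop_pitrel("invariant violated: n_pit_trials (", cfg$n_pit_trials,
                ") must be divisible by |cue_values| * 2 (", n_cells, ")",
                class = "pitrel_validation_error")
  invisible(cfg)
}

#' @export
print.pit_task_config <- function(x, ...) {
  cat("PIT task configuration\n")
  cat(sprintf("  instrumental: %d-%d trials, stop at %.0f%% over last %d\n",
              x$n_instrumental_min, x$n_instrumental_max,
              100 * x$criterion_accuracy, x$criterion_window))
  cat(sprintf("  pavlovian:    %d trials (%d per cue), values {%s}\n",
              x$n_pavlovian_trials, x$n_per_cue,
              paste(x$cue_values, collapse = ", ")))
  cat(sprintf("  transfer:     %d trials, %.1f s each (%.1f s response window)\n",
              x$n_pit_trials, x$trial_duration_s, x$response_window_s))
  invisible(x)
}
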