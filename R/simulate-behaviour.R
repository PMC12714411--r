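TRIAL_COLUMNS <- c("subject_id", "session", "phase", "trial_index",
                   "cue_value", "pavlovian_cue_id", "instrumental_cue_id",
                   "shell_type", "required_action", "go_nogo", "congruency",
                   "response_correct", "button_presses")

empty_trials <- function(n) {
  data.frame(
    subject_id = character(n), session = integer(n), phase = character(n),
    trial_index = integer(n), cue_value = rep(NA_integer_, n),
    pavlovian_cue_id = rep(NA_character_, n),
    instrumental_cue_id = rep(NA_character_, n),
    shell_type = rep(NA_character_, n),
    required_action = rep(NA_character_, n),
    go_nogo = rep(NA_integer_, n), congruency = rep(NA_character_, n),
    response_correct = rep(NA, n), button_presses = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
}

#' Simulate the instrumental training phase for one subject-session
#'
#' Training accuracy follows a saturating learning curve
#' `accuracy(t) = A - (A - 0.5) * exp(-t / tau)` starting at chance (0.5)
#' and rising toward the asymptote `A`. Each trial's correctness is a
#' Bernoulli draw at the current accuracy. The phase ends at the first
#' trial at or beyond the configured minimum (default 60) at which the
#' proportion correct over the trailing window (default the last 16
#' consecutive trials) reaches the criterion (default 80%), and never
#' exceeds the configured maximum (default 120 trials).
#'
#' @param traits_row One row of a [sample_population()] trait table.
#' @param config A [make_task_config()] object.
#' @param asymptote Learning-curve asymptote in `[0.5, 1]`; by default
#'   derived from the subject's baseline error logit as
#'   `1 - plogis(alpha)`, floored at chance.
#' @param tau Learning time constant in trials (default 16).
#'
#' @return A trial-record data frame (one row per training trial). Consumes
#'   the current RNG stream; seed upstream for determinism.
#' @export
simulate_instrumental_phase <- function(traits_row, config,
                                        asymptote = NULL, tau = 16) {
  stopifnot(inherits(config, "pit_task_config"))
  if (is.null(asymptote))
    asymptote <- max(0.5, 1 - stats::plogis(traits_row$alpha))
  assert_scalar_number(asymptote, "asymptote", min = 0.5, max = 1)
  n_min <- config$n_instrumental_min
  n_max <- config$n_instrumental_max
  w <- config$criterion_window
  correct <- logical(n_max)
  n_done <- n_max
  for (t in seq_len(n_max)) {
    acc <- asymptote - (asymptote - 0.5) * exp(-t / tau)
    correct[t] <- stats::runif(1) < acc
    if (t >= n_min && t >= w &&
        mean(correct[(t - w + 1L):t]) >= config$criterion_accuracy) {
      n_done <- t
      break
    }
  }
  shell <- sample(rep(c("good", "bad"), length.out = n_done))
  out <- empty_trials(n_done)
  out$subject_id <- traits_row$subject_id
  out$session <- traits_row$session
  out$phase <- "instrumental"
  out$trial_index <- seq_len(n_done)
  out$shell_type <- shell
  out$required_action <- ifelse(shell == "good", "collect", "reject")
  out$go_nogo <- as.integer(out$required_action == "collect")
  out$response_correct <- correct[seq_len(n_done)]
  out
}

#' Simulate the passive Pavlovian conditioning phase
#'
#' Emits the conditioning trials (default 80; 16 per conditioned stimulus)
#' in randomized order. The phase is passive viewing, so response fields
#' are `NA`.
#'
#' @inheritParams simulate_instrumental_phase
#' @return A trial-record data frame.
#' @export
simulate_pavlovian_phase <- function(traits_row, config) {
  stopifnot(inherits(config, "pit_task_config"))
  values <- sample(rep(config$cue_values, each = config$n_per_cue))
  out <- empty_trials(length(values))
  out$subject_id <- traits_row$subject_id
  out$session <- traits_row$session
  out$phase <- "pavlovian"
  out$trial_index <- seq_along(values)
  out$cue_value <- as.integer(values)
  out$pavlovian_cue_id <- paste0("CS", values)
  out
}

#' Simulate the transfer (PIT) phase for one subject-session
#'
#' Generates the transfer trials (default 90) with the ten cue-value by
#' required-action cells equally represented (9 trials each under the
#' default configuration) in randomized order. Trial congruency follows
#' [label_congruency()]. Correctness is Bernoulli with error log-odds
#' `alpha + gamma * 1[incongruent]`; button presses are Poisson with
#' log-rate `b0 + b1 * cue_value + b_go * go_nogo + u_pav + u_instr`,
#' where the `u` terms are the crossed cue intercepts drawn at the
#' population level.
#'
#' @inheritParams simulate_instrumental_phase
#' @param cue_effects List with named vectors `pav` and `instr` of crossed
#'   cue intercepts (as attached to the trait table by
#'   [sample_population()]); zero effects when omitted.
#'
#' @return A trial-record data frame with `n_pit_trials` rows.
#' @export
simulate_pit_phase <- function(traits_row, config, cue_effects = NULL) {
  stopifnot(inherits(config, "pit_task_config"))
  cells <- expand.grid(cue_value = config$cue_values,
                       required_action = c("collect", "reject"),
                       stringsAsFactors = FALSE)
  reps <- config$n_pit_trials / nrow(cells)
  idx <- sample(rep(seq_len(nrow(cells)), each = reps))
  cue_value <- cells$cue_value[idx]
  action <- cells$required_action[idx]
  n <- length(idx)

  shell_type <- ifelse(action == "collect", "good", "bad")
  exemplar <- sample(1:2, n, replace = TRUE)
  instrumental_cue_id <- paste0(shell_type, "_shell_", exemplar)
  pav_id <- paste0("CS", cue_value)

  u_pav <- u_instr <- numeric(n)
  if (!is.null(cue_effects)) {
    u_pav <- unname(cue_effects$pav[pav_id])
    u_pav[is.na(u_pav)] <- 0
    u_instr <- unname(cue_effects$instr[instrumental_cue_id])
    u_instr[is.na(u_instr)] <- 0
  }

  congruency <- label_congruency(cue_value, action, cue_set = config$cue_values)
  p_err <- stats::plogis(traits_row$alpha +
                           traits_row$gamma * (congruency == "incongruent"))
  go <- as.integer(action == "collect")
  lambda <- exp(traits_row$b0 + traits_row$b1 * cue_value +
                  traits_row$b_go * go + u_pav + u_instr)
  presses <- stats::rpois(n, lambda)
  if (is.finite(config$press_cap))
    presses <- pmin(presses, config$press_cap)

  out <- empty_trials(n)
  out$subject_id <- traits_row$subject_id
  out$session <- traits_row$session
  out$phase <- "pit"
  out$trial_index <- seq_len(n)
  out$cue_value <- as.integer(cue_value)
  out$pavlovian_cue_id <- pav_id
  out$instrumental_cue_id <- instrumental_cue_id
  out$shell_type <- shell_type
  out$required_action <- action
  out$go_nogo <- go
  out$congruency <- congruency
  out$response_correct <- stats::runif(n) >= p_err
  out$button_presses <- as.integer(presses)
  out
}

#' Simulate a complete two-session PIT study
#'
#' Runs all three task phases for every subject and both sessions, and
#' optionally generates toy neural trial data for the transfer phase. One
#' seed determines the entire dataset; the returned manifest records the
#' seed and all parameters so the dataset can be regenerated bit-identically.
#'
#' @param task_config A [make_task_config()] object.
#' @param population A [population_params()] object.
#' @param geometry Optional [toy_geometry()] object; when supplied, neural
#'   trial amplitudes are generated for every subject-session transfer
#'   phase (this stores `n_subjects * 2` trial-by-voxel matrices; for large
#'   studies generate per subject with [simulate_neural_trials()] instead).
#' @param seed Integer seed (mandatory).
#'
#' @return An object of class `pit_study`: a list with `trials` (the full
#'   long-format trial table), `traits`, `neural` (or `NULL`), and
#'   `manifest`.
#' @export
simulate_study <- function(task_config, population, geometry = NULL, seed) {
  stopifnot(inherits(task_config, "pit_task_config"),
            inherits(population, "pit_population"))
  if (missing(seed)) stop_pitrel("seed must be provided explicitly")
  traits <- sample_population(population, seed = seed,
                              cue_values = task_config$cue_values)
  cue_effects <- attr(traits, "cue_effects")

  rows <- vector("list", nrow(traits) * 3L)
  k <- 0L
  for (i in seq_len(nrow(traits))) {
    tr <- traits[i, ]
    rows[[k + 1L]] <- simulate_instrumental_phase(tr, task_config)
    rows[[k + 2L]] <- simulate_pavlovian_phase(tr, task_config)
    rows[[k + 3L]] <- simulate_pit_phase(tr, task_config, cue_effects)
    k <- k + 3L
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL

  neural <- NULL
  if (!is.null(geometry)) {
    dev <- sample_neural_deviations(population, traits, geometry)
    neural <- list(geometry = geometry, deviations = dev,
                   amplitudes = list())
    for (i in seq_len(nrow(traits))) {
      tr <- traits[i, ]
      key <- paste0(tr$subject_id, "_s", tr$session)
      pit <- trials[trials$subject_id == tr$subject_id &
                      trials$session == tr$session & trials$phase == "pit", ]
      neural$amplitudes[[key]] <-
        simulate_neural_trials(pit, tr, population$neural, geometry,
                               deviations = dev)$amplitudes
    }
  }

  manifest <- list(
    seed = seed,
    task_config = unclass(task_config),
    population = unclass(population[setdiff(names(population), "neural")]),
    neural_params = if (!is.null(geometry)) unclass(population$neural),
    geometry = if (!is.null(geometry)) geometry_summary(geometry),
    n_subjects = population$n_subjects,
    package_version = as.character(utils::packageVersion("pitrel"))
  )
  structure(list(trials = trials, traits = traits, neural = neural,
                 manifest = manifest),
            class = "pit_study")
}

#' Read and write long-format trial tables
#'
#' Trial tables are exchanged as plain CSV with one header row and the
#' fixed column set documented in [simulate_study()] (`subject_id`,
#' `session`, `phase`, `trial_index`, `cue_value`, `pavlovian_cue_id`,
#' `instrumental_cue_id`, `shell_type`, `required_action`, `go_nogo`,
#' `congruency`, `response_correct`, `button_presses`).
#'
#' @param trials A trial-record data frame.
#' @param path File path.
#' @return `read_trials()` returns the trial data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop_pitrel("trial table missing column(s): ",
                paste(missing_cols, collapse = ", "))
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(subject_id = "character"))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop_pitrel("trial file missing column(s): ",
                paste(missing_cols, collapse = ", "))
  trials$response_correct <- as.logical(trials$response_correct)
  trials[, TRIAL_COLUMNS]
}
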