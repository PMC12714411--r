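# shared fixtures, all generated in code

tiny_config <- function(...) make_task_config(list(...))

tiny_geometry <- function() toy_geometry(c(12L, 12L, 6L), c(3L, 3L, 3L))

# one subject-session trait row built directly (no sampling)
fixed_traits_row <- function(subject_id = "S001", session = 1L,
                             alpha = qlogis(0.1), gamma = 1,
                             b0 = 0.5, b1 = 0.2, b_go = 1.5) {
  data.frame(subject_id = subject_id, session = session, alpha = alpha,
             gamma = gamma, b0 = b0, b1 = b1, b_go = b_go,
             stringsAsFactors = FALSE)
}

# population with all between-subject SDs zero (degenerate)
degenerate_population <- function(n_subjects = 10, ...) {
  population_params(n_subjects = n_subjects,
                    sd_alpha = 0, sd_gamma = 0, sd_b0 = 0, sd_b1 = 0,
                    sd_cue_pav = 0, sd_cue_instr = 0, ...)
}

# hand-built transfer trials with known congruency/error structure
hand_trials <- function(congruency, correct, subject_id = "S001",
                        session = 1L) {
  n <- length(congruency)
  data.frame(
    subject_id = subject_id, session = session, phase = "pit",
    trial_index = seq_len(n),
    cue_value = ifelse(congruency == "neutral", 0L,
                       ifelse(congruency == "incongruent", -1L, 1L)),
    pavlovian_cue_id = "CS0", instrumental_cue_id = "good_shell_1",
    shell_type = "good", required_action = "collect", go_nogo = 1L,
    congruency = congruency, response_correct = correct,
    button_presses = 0L, stringsAsFactors = FALSE
  )
}

# Monte-Carlo oracle for the classical-test-theory reliability of the
# interference effect: true-score variance of plogis(alpha+gamma)-plogis(alpha)
# across subjects, and binomial error variance of the full-length estimate
# (n_inc incongruent and n_con congruent trials), computed directly from the
# trait distribution -- independent of the split-half machinery.
ctt_interference_reliability <- function(mu_alpha, sd_alpha, mu_gamma,
                                         sd_gamma, rho = 1,
                                         n_inc = 36, n_con = 36,
                                         n_mc = 2e5, seed = 999) {
  set.seed(seed)
  alpha <- rnorm(n_mc, mu_alpha, sd_alpha)
  gamma <- rnorm(n_mc, mu_gamma, sd_gamma)
  p_con <- plogis(alpha)
  p_inc <- plogis(alpha + gamma)
  true_effect <- p_inc - p_con
  sigma_T2 <- var(true_effect)
  sigma_e2 <- mean(p_inc * (1 - p_inc)) / n_inc +
    mean(p_con * (1 - p_con)) / n_con
  list(R = sigma_T2 / (sigma_T2 + sigma_e2),
       sigma_T2 = sigma_T2, sigma_e2 = sigma_e2)
}

# simulate only the transfer phase for n subjects (both sessions optional)
simulate_pit_only <- function(population, config = make_task_config(),
                              seed = 1, sessions = 1L) {
  traits <- sample_population(population, seed = seed,
                              cue_values = config$cue_values)
  cue_effects <- attr(traits, "cue_effects")
  keep <- traits$session %in% sessions
  rows <- lapply(which(keep), function(i)
    simulate_pit_phase(traits[i, ], config, cue_effects))
  list(trials = do.call(rbind, rows), traits = traits[keep, ])
}
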