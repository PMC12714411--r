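test_that("congruency labelling follows cue valence and required action", {
  expect_identical(label_congruency(-2L, "collect"), "incongruent")
  expect_identical(label_congruency(-1L, "collect"), "incongruent")
  expect_identical(label_congruency(1L, "reject"), "incongruent")
  expect_identical(label_congruency(2L, "collect"), "congruent")
  expect_identical(label_congruency(-2L, "reject"), "congruent")
  expect_identical(label_congruency(0L, "collect"), "neutral")
  expect_identical(label_congruency(0L, "reject"), "neutral")
  expect_error(label_congruency(3L, "collect", cue_set = -2:2),
               class = "pitrel_validation_error")
  expect_error(label_congruency(1L, "approach"),
               class = "pitrel_validation_error")
})

test_that("interference effect is the incongruent minus congruent error rate", {
  d <- hand_trials(rep(c("incongruent", "congruent"), each = 4),
                   c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(as.numeric(interference_effect(d)), 0.50 - 0.25)

  all_correct <- hand_trials(rep(c("incongruent", "congruent"), 3), rep(TRUE, 6))
  expect_equal(as.numeric(interference_effect(all_correct)), 0)

  balanced <- hand_trials(rep(c("incongruent", "congruent"), each = 4),
                          rep(c(TRUE, FALSE), 4))
  expect_equal(as.numeric(interference_effect(balanced)), 0)

  # antisymmetry: swapping the class labels flips the sign exactly
  swapped <- d
  swapped$congruency <- ifelse(d$congruency == "incongruent",
                               "congruent", "incongruent")
  expect_equal(as.numeric(interference_effect(swapped)),
               -as.numeric(interference_effect(d)))

  # neutral trials never enter
  with_neutral <- rbind(d, hand_trials(rep("neutral", 10), rep(FALSE, 10)))
  expect_equal(as.numeric(interference_effect(with_neutral)), 0.25)

  only_inc <- hand_trials(rep("incongruent", 4), rep(TRUE, 4))
  expect_warning(res <- interference_effect(only_inc), "empty")
  expect_true(is.na(res))
  expect_identical(attr(res, "reason"), "empty congruency class")
})

test_that("two-stage slopes solve the noise-free subject exactly", {
  # perfectly log-linear counts: slope recovered to machine-level precision
  v <- rep(-2:2, each = 6)
  go <- rep(c(0, 1), 15)
  y <- exp(0.4 + 0.25 * v + 0.8 * go)
  expect_equal(unname(poisson_slope_one(v, go, y)), 0.25, tolerance = 1e-7)
  # constant presses give a zero slope
  expect_equal(unname(poisson_slope_one(v, go, rep(3, 30))), 0,
               tolerance = 1e-8)
})

test_that("GLMM degenerates to pooled Poisson regression without random effects", {
  pop <- degenerate_population(n_subjects = 25)
  sim <- simulate_pit_only(pop, seed = 41, sessions = 1L)
  fit <- suppressWarnings(fit_motivational_glmm(sim$trials))
  pooled <- glm(button_presses ~ cue_value + go_nogo, poisson(),
                data = sim$trials)
  slope_glmm <- fit$fixed$estimate[fit$fixed$term == "slope_value"]
  expect_lt(abs(slope_glmm - coef(pooled)[["cue_value"]]), 1e-3)
})

test_that("GLMM recovers the generating motivational slope", {
  pop <- population_params(n_subjects = 40, mu_b1 = 0.2)
  sim <- simulate_pit_only(pop, seed = 42, sessions = 1L)
  fit <- fit_motivational_glmm(sim$trials)
  slope <- fit$fixed$estimate[fit$fixed$term == "slope_value"]
  expect_lt(abs(slope - 0.2), 0.05)
  expect_true(fit$converged)
  expect_true(all(c("sd_int_subj", "sd_slope_subj", "corr_subj")
                  %in% names(fit$varcomps)))
  # conditional modes are centred
  cm <- fit$conditional_modes$slope_dev
  expect_lt(abs(mean(cm)), 0.02 * max(sd(cm), 1e-6))
})

test_that("mixed-model and two-stage subject slopes agree up to shrinkage", {
  pop <- population_params(n_subjects = 60, mu_b1 = 0.2, sd_b1 = 0.12)
  sim <- simulate_pit_only(pop, seed = 43, sessions = 1L)
  fit <- fit_motivational_glmm(sim$trials)
  glmm_slopes <- subject_motivational_slopes(fit)
  ts_slopes <- two_stage_motivational(sim$trials)
  common <- intersect(names(glmm_slopes), names(ts_slopes))
  keep <- common[is.finite(ts_slopes[common])]
  expect_gt(cor(glmm_slopes[keep], ts_slopes[keep], method = "spearman"), 0.9)
  # shrinkage: conditional-mode slopes vary no more than unshrunken ones
  expect_lte(var(glmm_slopes[keep]), var(ts_slopes[keep]))
  # slopes correlate with the generating subject traits
  truth <- sim$traits$b1[match(keep, sim$traits$subject_id)]
  expect_gt(cor(glmm_slopes[keep], truth), 0.7)
  # mean of subject slopes is the fixed slope
  b <- fit$fixed$estimate[fit$fixed$term == "slope_value"]
  expect_lt(abs(mean(glmm_slopes) - b),
            0.02 * max(fit$varcomps$sd_slope_subj, 1e-6))
})

test_that("permuting subject labels destroys the subject slope variance", {
  pop <- population_params(n_subjects = 30, sd_b1 = 0.15)
  sim <- simulate_pit_only(pop, seed = 44, sessions = 1L)
  fit <- fit_motivational_glmm(sim$trials)
  perm <- sim$trials
  set.seed(45)
  perm$subject_id <- sample(perm$subject_id)
  fit_perm <- suppressWarnings(fit_motivational_glmm(perm))
  expect_lt(fit_perm$varcomps$sd_slope_subj,
            0.5 * fit$varcomps$sd_slope_subj)
})

test_that("GLMM input validation rejects malformed data", {
  pop <- degenerate_population(4)
  sim <- simulate_pit_only(pop, seed = 46, sessions = 1L)
  bad <- sim$trials
  bad$button_presses <- bad$button_presses + 0.5
  expect_error(fit_motivational_glmm(bad), class = "pitrel_validation_error")
  one <- sim$trials[sim$trials$subject_id == "S001", ]
  expect_error(fit_motivational_glmm(one), class = "pitrel_validation_error")
})
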