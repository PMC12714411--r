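test_that("stratified splitting partitions every stratum near-evenly", {
  cfg <- make_task_config()
  set.seed(51)
  pit <- simulate_pit_phase(fixed_traits_row(), cfg)
  set.seed(52)
  halves <- split_trials(pit)
  expect_identical(sort(c(halves$idx_A, halves$idx_B)), seq_len(90L))
  expect_length(intersect(halves$idx_A, halves$idx_B), 0L)
  # each 9-trial cell splits 5/4 or 4/5
  cell_A <- table(halves$A$cue_value, halves$A$required_action)
  expect_true(all(cell_A %in% c(4L, 5L)))
  # determinism under a fixed seed
  set.seed(52)
  again <- split_trials(pit)
  expect_identical(halves$idx_A, again$idx_A)
  # a thin stratum is an error naming the stratum
  thin <- pit[!(pit$cue_value == 2 & pit$required_action == "reject") |
                pit$trial_index == pit$trial_index[
                  pit$cue_value == 2 & pit$required_action == "reject"][1], ]
  expect_error(split_trials(thin), "2", class = "pitrel_split_error")
})

test_that("Spearman-Brown correction has its fixed points and monotonicity", {
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(0.5), 2 * 0.5 / 1.5)
  r <- seq(-0.95, 1, by = 0.05)
  sb <- spearman_brown(r)
  expect_true(all(diff(sb) > 0))            # strictly increasing
  expect_true(all(sb[r >= 0] >= r[r >= 0])) # at or above identity
  expect_error(spearman_brown(-1), class = "pitrel_validation_error")
})

test_that("split-half coefficient is the Fisher-z mean and respects bounds", {
  pop <- population_params(n_subjects = 12)
  sim <- simulate_pit_only(pop, seed = 53, sessions = 1L)
  sh <- split_half_reliability(sim$trials, interference_effect,
                               n_perm = 60, seed = 54)
  expect_equal(sh$coefficient,
               tanh(mean(atanh(sh$per_perm_r_sb))), tolerance = 1e-10)
  expect_gte(sh$coefficient, min(sh$per_perm_r_sb))
  expect_lte(sh$coefficient, max(sh$per_perm_r_sb))
  expect_identical(sh$n_permutations, 60L)
  # determinism
  sh2 <- split_half_reliability(sim$trials, interference_effect,
                                n_perm = 60, seed = 54)
  expect_identical(sh$per_perm_r, sh2$per_perm_r)
})

test_that("deterministic subject-level effects give perfect reliability", {
  pop <- population_params(n_subjects = 10)
  sim <- simulate_pit_only(pop, seed = 55, sessions = 1L)
  # effect depends on the subject only, not on which trials land in a half
  effect_fn <- function(d) as.numeric(sub("S", "", d$subject_id[1]))^0.5
  sh <- split_half_reliability(sim$trials, effect_fn, n_perm = 20, seed = 56)
  expect_gt(sh$coefficient, 1 - 1e-6)
  expect_identical(sh$n_clipped, 20L)
})

test_that("no between-subject variance yields a near-zero coefficient", {
  pop <- degenerate_population(n_subjects = 150, mu_gamma = 1)
  sim <- simulate_pit_only(pop, seed = 57, sessions = 1L)
  sh <- split_half_reliability(sim$trials,
                               function(d) as.numeric(interference_effect(d, quiet = TRUE)),
                               n_perm = 100, seed = 58)
  expect_lt(abs(sh$coefficient), 0.25)
})

test_that("split-half recovers the classical-test-theory reliability", {
  # scaled-down recovery check (one regime); the acceptance suite covers three
  pop <- population_params(n_subjects = 200, mu_alpha = qlogis(0.12),
                           sd_alpha = 0.7, mu_gamma = 1.2, sd_gamma = 1.1)
  oracle <- ctt_interference_reliability(qlogis(0.12), 0.7, 1.2, 1.1)
  sim <- simulate_pit_only(pop, seed = 59, sessions = 1L)
  sh <- split_half_reliability(sim$trials,
                               function(d) as.numeric(interference_effect(d, quiet = TRUE)),
                               n_perm = 200, seed = 60)
  expect_lt(abs(sh$coefficient - oracle$R), 0.06)
})

test_that("agreement ICC has the documented limiting behaviour", {
  x <- c(1, 2, 3, 4, 5)
  ident <- icc_agreement(cbind(x, x))
  expect_equal(ident$icc, 1)
  # constant shift: Pearson stays 1, absolute agreement is penalized
  shifted1 <- icc_agreement(cbind(x, x + 0.5))
  shifted2 <- icc_agreement(cbind(x, x + 1.5))
  expect_equal(shifted1$pearson_r, 1)
  expect_lt(shifted1$icc, 1)
  expect_lt(shifted2$icc, shifted1$icc)
  # degenerate and undersized inputs
  expect_error(icc_agreement(cbind(c(2, 2), c(2, 2))),
               class = "pitrel_degenerate_error")
  expect_error(icc_agreement(cbind(1, 2)), class = "pitrel_validation_error")
  # listwise deletion is counted
  with_na <- icc_agreement(cbind(c(x, NA), c(x, 1)))
  expect_identical(with_na$n_dropped, 1L)
  expect_identical(with_na$n, 5L)
})

test_that("agreement ICC matches a first-principles ANOVA computation", {
  brute_force_icc <- function(x) {
    n <- nrow(x); k <- ncol(x)
    grand <- mean(x)
    row_m <- rowMeans(x); col_m <- colMeans(x)
    SSR <- k * sum((row_m - grand)^2)
    SSC <- n * sum((col_m - grand)^2)
    SST <- sum((x - grand)^2)
    MSE <- (SST - SSR - SSC) / ((n - 1) * (k - 1))
    MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
    (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  }
  # the worked 4x2 example
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 2))
  expect_equal(icc_agreement(m)$icc, brute_force_icc(m), tolerance = 1e-10)
  set.seed(61)
  for (i in 1:20) {
    x <- matrix(rnorm(10), 5, 2)
    expect_equal(icc_agreement(x)$icc, brute_force_icc(x), tolerance = 1e-8)
  }
})

test_that("paired t-test handles regular and degenerate differences", {
  x <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  same <- paired_t_test(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  div <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(is.infinite(div$t_statistic) && div$t_statistic > 0)
  expect_equal(div$mean_difference, 1)
  # df convention: n - 1
  set.seed(62)
  a <- rnorm(119); b <- rnorm(119)
  expect_identical(paired_t_test(a, b)$df, 118L)
  ref <- t.test(a, b, paired = TRUE)
  ours <- paired_t_test(a, b)
  expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("guideline classification respects both schemes and bin edges", {
  expect_identical(classify_reliability(0.53, "koo_li"), "moderate")
  expect_identical(classify_reliability(0.29, "koo_li"), "poor")
  expect_identical(classify_reliability(0.92, "koo_li"), "excellent")
  expect_identical(classify_reliability(0.75, "koo_li"), "good")
  expect_identical(classify_reliability(0.75, "cicchetti"), "excellent")
  expect_identical(classify_reliability(0.45, "cicchetti"), "fair")
  expect_identical(classify_reliability(-0.2, "koo_li"), "poor")
  expect_error(classify_reliability(0.5, "bogus"))
  expect_error(classify_reliability(1.2, "koo_li"),
               class = "pitrel_validation_error")
})
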