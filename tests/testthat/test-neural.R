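test_that("toy geometry yields disjoint nonempty ROI boxes", {
  geo <- toy_geometry()
  expect_identical(names(geo$masks), c("amygdala", "VS", "lPFC", "dmPFC"))
  counts <- vapply(geo$masks, sum, 0L)
  expect_true(all(counts == 64L))
  expect_true(all(Reduce(`+`, geo$masks) <= 1L))
  expect_error(
    toy_geometry(roi_origins = list(amygdala = c(1, 1, 1), VS = c(2, 2, 2),
                                    lPFC = c(10, 10, 1), dmPFC = c(10, 1, 1))),
    "overlap", class = "pitrel_geometry_error")
  expect_error(toy_geometry(dim = c(6, 6, 4), roi_dim = 8),
               class = "pitrel_geometry_error")
})

test_that("interference design is a balanced indicator matrix", {
  cfg <- make_task_config()
  set.seed(71)
  pit <- simulate_pit_phase(fixed_traits_row(), cfg)
  des <- build_design(pit, "interference")
  expect_identical(dim(des$X), c(90L, 10L))
  expect_true(all(colSums(des$X) == 9))
  expect_true(all(rowSums(des$X) == 1))
  expect_false(des$orthogonalized)
  # absent cell is dropped with a warning and recorded
  sub <- pit[!(pit$cue_value == 2 & pit$required_action == "reject"), ]
  expect_warning(des2 <- build_design(sub, "interference"), "dropped")
  expect_identical(des2$dropped_cells, "cs_p2_reject")
  expect_identical(ncol(des2$X), 9L)
})

test_that("motivational design centres unorthogonalized modulators", {
  cfg <- make_task_config()
  set.seed(72)
  pit <- simulate_pit_phase(fixed_traits_row(), cfg)
  des <- build_design(pit, "motivational")
  expect_identical(colnames(des$X),
                   c("onset", "motivational", "cs_value", "log_presses"))
  expect_true(all(abs(colMeans(des$X[, -1])) < 1e-10))
  expect_false(des$orthogonalized)
  # constant presses: log-presses column vanishes after centring
  flat <- pit
  flat$button_presses <- 5L
  expect_warning(des3 <- build_design(flat, "motivational"), "constant")
  expect_true(all(abs(des3$X[, "log_presses"]) < 1e-12))
})

test_that("contrast weights encode the congruency definition", {
  cfg <- make_task_config()
  set.seed(73)
  pit <- simulate_pit_phase(fixed_traits_row(), cfg)
  des <- build_design(pit, "interference")
  cw <- design_contrasts(des)
  inc_cols <- c("cs_m1_collect", "cs_m2_collect", "cs_p1_reject", "cs_p2_reject")
  cng_cols <- c("cs_p1_collect", "cs_p2_collect", "cs_m1_reject", "cs_m2_reject")
  expect_equal(sum(cw$incongruent[inc_cols]), 1)
  expect_true(all(cw$incongruent[setdiff(names(cw$incongruent), inc_cols)] == 0))
  expect_equal(sum(cw$congruent[cng_cols]), 1)
  expect_equal(sum(cw$incongruent_vs_congruent), 0)
})

test_that("first-level OLS recovers noise-free fields and scales linearly", {
  geo <- tiny_geometry()
  cfg <- make_task_config()
  np <- neural_params(sd_trial_noise = 0)
  tr <- fixed_traits_row()
  set.seed(74)
  pit <- simulate_pit_phase(tr, cfg)
  # silence components that vary within a design cell
  np$roi_amplitudes$cs_value[] <- 0
  np$roi_amplitudes$log_presses[] <- 0
  np$roi_amplitudes$motivational[] <- 0
  sim <- simulate_neural_trials(pit, tr, np, geo)
  fl <- estimate_first_level(sim$amplitudes, build_design(pit, "interference"),
                             geo)
  v <- which(geo$masks$VS)[1]
  expect_equal(fl$contrasts$incongruent$beta[v],
               np$roi_amplitudes$onset[["VS"]] +
                 np$roi_amplitudes$incongruent[["VS"]], tolerance = 1e-8)
  expect_equal(fl$contrasts$congruent$beta[v],
               np$roi_amplitudes$onset[["VS"]] +
                 np$roi_amplitudes$congruent[["VS"]], tolerance = 1e-8)
  # contrast algebra holds exactly at every voxel
  expect_equal(fl$contrasts$incongruent_vs_congruent$beta,
               fl$contrasts$incongruent$beta - fl$contrasts$congruent$beta,
               tolerance = 1e-12)
  expect_identical(fl$df, 90L - 10L)
  # doubling amplitudes doubles betas exactly
  fl2 <- estimate_first_level(2 * sim$amplitudes,
                              build_design(pit, "interference"), geo)
  expect_equal(fl2$contrasts$incongruent$beta,
               2 * fl$contrasts$incongruent$beta, tolerance = 1e-10)
})

test_that("split-half re-estimation reproduces noise-free maps and splits deterministically", {
  geo <- tiny_geometry()
  cfg <- make_task_config()
  np <- neural_params(sd_trial_noise = 0)
  np$roi_amplitudes$cs_value[] <- 0
  np$roi_amplitudes$log_presses[] <- 0
  np$roi_amplitudes$motivational[] <- 0
  tr <- fixed_traits_row()
  set.seed(75)
  pit <- simulate_pit_phase(tr, cfg)
  sim <- simulate_neural_trials(pit, tr, np, geo)
  set.seed(76)
  sh <- split_half_neural(pit, sim$amplitudes, geo, model = "interference")
  expect_equal(sh$A$interference$contrasts$incongruent$beta,
               sh$B$interference$contrasts$incongruent$beta,
               tolerance = 1e-8)
  set.seed(76)
  sh2 <- split_half_neural(pit, sim$amplitudes, geo, model = "interference")
  expect_identical(sh$idx_A, sh2$idx_A)
})

test_that("ROI means are unweighted and reject bad input", {
  geo <- tiny_geometry()
  const <- array(3.5, geo$dim)
  expect_equal(roi_mean(const, geo$masks$VS), 3.5)
  two <- array(0, c(2, 2, 1))
  msk <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  two[1, 1, 1] <- 1; two[2, 1, 1] <- 3
  expect_equal(roi_mean(two, msk), 2)
  bad <- const; bad[which(geo$masks$VS)[1]] <- NaN
  expect_error(roi_mean(bad, geo$masks$VS), "non-finite")
  expect_error(roi_mean(const, array(FALSE, geo$dim)),
               class = "pitrel_geometry_error")
  expect_error(roi_mean(const, array(TRUE, c(2, 2, 2))),
               class = "pitrel_geometry_error")
})

test_that("voxel-wise ICC agrees with the scalar ICC and calibrates at null", {
  set.seed(77)
  A <- matrix(rnorm(20 * 30), 20)
  B <- A + matrix(rnorm(20 * 30, sd = 0.7), 20)
  vw <- voxelwise_icc(A, B)
  for (j in c(1, 7, 30))
    expect_equal(vw[j], icc_agreement(cbind(A[, j], B[, j]))$icc,
                 tolerance = 1e-8)
  # duplicated maps: ICC 1 everywhere
  dup <- voxelwise_icc(A, A)
  expect_true(all(abs(dup - 1) < 1e-10))
  # independent noise: mean ICC near 0
  set.seed(78)
  nullA <- matrix(rnorm(100 * 500), 100)
  nullB <- matrix(rnorm(100 * 500), 100)
  vw0 <- voxelwise_icc(nullA, nullB)
  expect_lt(abs(mean(vw0)), 0.05)
  # constant voxel marked degenerate
  A2 <- A; A2[, 3] <- 1
  B2 <- B; B2[, 3] <- 1
  vw2 <- voxelwise_icc(A2, B2)
  expect_true(is.nan(vw2[3]))
  expect_identical(attr(vw2, "n_degenerate"), 1L)
})

test_that("planted signal raises voxel-wise ICC inside its ROI", {
  geo <- tiny_geometry()
  set.seed(79)
  n <- 40
  subj_amp <- rnorm(n, 1, 0.8)               # stable subject trait
  vs_idx <- which(geo$masks$VS)
  make_maps <- function() {
    m <- matrix(rnorm(n * geo$n_voxels, sd = 0.5), n)
    m[, vs_idx] <- m[, vs_idx] + subj_amp
    m
  }
  vw <- voxelwise_icc(make_maps(), make_maps(), geo)
  inside <- mean(vw[geo$masks$VS])
  outside <- mean(vw[!Reduce(`|`, geo$masks)], na.rm = TRUE)
  expect_gt(inside, outside + 0.3)
})

test_that("thresholding nests across p levels and handles edge cases", {
  set.seed(80)
  tmap <- array(rnorm(12 * 12 * 6, sd = 2), c(12, 12, 6))
  m001 <- threshold_map(tmap, df = 80, p_threshold = 0.001)
  m01 <- threshold_map(tmap, df = 80, p_threshold = 0.01)
  m05 <- threshold_map(tmap, df = 80, p_threshold = 0.05)
  expect_true(all(m01[m001]))   # p<.001 subset of p<.01
  expect_true(all(m05[m01]))    # p<.01 subset of p<.05
  expect_true(all(threshold_map(tmap, 80, 1)))
  expect_false(any(threshold_map(array(0, dim(tmap)), 80, 0.01)))
  pos <- threshold_map(tmap, 80, 0.05, tail = "positive")
  expect_true(all(tmap[pos] > 0))
})

test_that("Jaccard overlap satisfies its defining identities", {
  a <- array(FALSE, c(4, 4, 2)); b <- a
  a[1:2, 1, 1] <- TRUE            # |A| = 2
  expect_equal(jaccard(a, a)$jaccard, 1)
  b[3:4, 4, 2] <- TRUE            # disjoint
  expect_equal(jaccard(a, b)$jaccard, 0)
  # hand-counted case: |A∩B| = 2, |A∪B| = 6
  a2 <- array(FALSE, c(4, 4, 2)); b2 <- a2
  a2[1:4, 1, 1] <- TRUE           # A = {1,2,3,4}
  b2[3:4, 1, 1] <- TRUE; b2[1:2, 2, 1] <- TRUE  # B = {3,4,5,6}
  j <- jaccard(a2, b2)
  expect_equal(j$jaccard, 1 / 3)
  expect_identical(j$n_intersection, 2L)
  expect_identical(j$n_union, 6L)
  # symmetry
  expect_equal(jaccard(b2, a2)$jaccard, j$jaccard)
  # both empty: undefined, flagged
  e <- array(FALSE, c(4, 4, 2))
  je <- jaccard(e, e)
  expect_true(is.nan(je$jaccard))
  expect_true(je$both_empty)
  expect_error(jaccard(a, array(FALSE, c(2, 2, 2))),
               class = "pitrel_geometry_error")
})

test_that("NIfTI volumes round-trip through disk", {
  set.seed(81)
  vol <- array(rnorm(10 * 10 * 5), c(10, 10, 5))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(dim(back), dim(vol))
  expect_equal(as.vector(back), as.vector(vol), tolerance = 1e-6)
  mask <- array(runif(10 * 10 * 5) > 0.5, c(10, 10, 5))
  mpath <- tempfile(fileext = ".nii.gz")
  write_volume(mask, mpath)
  mback <- read_volume(mpath)
  expect_identical(array(as.logical(round(mback)), dim(mask)), mask)
  # geometry mismatch across a set is an error listing the offender
  p2 <- tempfile(fileext = ".nii.gz")
  write_volume(array(0, c(4, 4, 4)), p2)
  expect_error(read_volume_set(c(path, p2)), "mismatch",
               class = "pitrel_geometry_error")
  unlink(c(path, mpath, p2))
})
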