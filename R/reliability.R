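#' Stratified random split of one subject-session's trials
#'
#' Partitions the trials into two halves, stratified by design cell
#' (default: cue value by required action) so that every condition is
#' represented in both halves. Within a stratum the trials are divided as
#' evenly as possible; when a stratum has an odd count the extra trial
#' goes to a uniformly random half. Every trial appears in exactly one
#' half. Consumes the RNG stream; seed upstream for determinism.
#'
#' @param trials Trial records for a single subject-session.
#' @param stratify_by Column names defining the strata.
#'
#' @return A list with data frames `A` and `B` and the integer index
#'   vectors `idx_A` and `idx_B` into `trials`.
#' @export
split_trials <- function(trials, stratify_by = c("cue_value",
                                                 "required_action")) {
  strata <- interaction(trials[stratify_by], drop = TRUE, lex.order = TRUE)
  idx_by_stratum <- split(seq_len(nrow(trials)), strata)
  sizes <- lengths(idx_by_stratum)
  if (any(sizes < 2L))
    stop_pitrel("stratum with fewer than 2 trials: ",
                paste(names(sizes)[sizes < 2L], collapse = ", "),
                class = "pitrel_split_error")
  idx_A <- integer(0)
  for (s in idx_by_stratum) {
    n_s <- length(s)
    take <- n_s %/% 2L
    if (n_s %% 2L == 1L && stats::runif(1) < 0.5) take <- take + 1L
    idx_A <- c(idx_A, s[sample.int(n_s, take)])
  }
  idx_A <- sort(idx_A)
  idx_B <- setdiff(seq_len(nrow(trials)), idx_A)
  list(A = trials[idx_A, , drop = FALSE], B = trials[idx_B, , drop = FALSE],
       idx_A = idx_A, idx_B = idx_B)
}

#' Spearman-Brown correction of a split-half correlation
#'
#' Corrects a half-length correlation for the reduced number of items:
#' `2 r / (1 + r)`. Strictly increasing on `(-1, 1]`, at or above the
#' identity on `[0, 1]`, with fixed points 0 and 1.
#'
#' @param r Correlation(s) in `(-1, 1]`.
#' @return Corrected correlation(s).
#' @examples
#' spearman_brown(0.5)  # 0.6667
#' @export
spearman_brown <- function(r) {
  if (any(!is.na(r) & (r <= -1 | r > 1)))
    stop_pitrel("spearman_brown is undefined at r <= -1 (and r > 1)",
                class = "pitrel_validation_error")
  2 * r / (1 + r)
}

#' Permutation split-half reliability
#'
#' For each of `n_perm` permutations, every subject's trials are randomly
#' split into stratified halves, the effect of interest is computed per
#' subject in each half, and the Pearson correlation across subjects
#' between halves is Spearman-Brown corrected. The corrected coefficients
#' are Fisher-z transformed, averaged, and transformed back; the
#' back-transformed mean is the reported split-half reliability.
#'
#' @param trials Transfer-phase trial records for all subjects of one
#'   session (or any single time point).
#' @param effect_fn Function mapping one subject's half of trials to a
#'   scalar effect (e.g. [interference_effect()] or a per-subject
#'   motivational slope). Subjects for which either half returns `NA` are
#'   dropped for that permutation (counted in the diagnostics).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed (mandatory).
#' @param stratify_by Stratification columns for [split_trials()].
#'
#' @return An object of class `pit_splithalf`: list with `coefficient`
#'   (tanh of the mean Fisher z), `mean_z`, `per_perm_r`,
#'   `per_perm_r_sb`, `n_permutations`, `n_subjects_used` (per
#'   permutation), `n_clipped`, and `seed`.
#' @export
split_half_reliability <- function(trials, effect_fn, n_perm = 5000, seed,
                                   stratify_by = c("cue_value",
                                                   "required_action")) {
  if (missing(seed)) stop_pitrel("seed must be provided explicitly")
  n_perm <- assert_count(n_perm, "n_perm", min = 1)
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "pit", ]
  by_subj <- split(trials, trials$subject_id)
  if (length(by_subj) < 3L)
    stop_pitrel("split-half reliability needs at least 3 subjects",
                class = "pitrel_validation_error")
  # precompute per-subject stratum index lists once
  prep <- lapply(by_subj, function(d) {
    strata <- interaction(d[stratify_by], drop = TRUE, lex.order = TRUE)
    idx <- split(seq_len(nrow(d)), strata)
    if (any(lengths(idx) < 2L))
      stop_pitrel("stratum with fewer than 2 trials for subject ",
                  d$subject_id[1], class = "pitrel_split_error")
    list(d = d, idx = idx, n = nrow(d))
  })
  set.seed(seed)
  ns <- length(prep)
  per_r <- numeric(n_perm)
  n_used <- integer(n_perm)
  eA <- eB <- numeric(ns)
  for (p in seq_len(n_perm)) {
    for (i in seq_len(ns)) {
      pr <- prep[[i]]
      in_A <- logical(pr$n)
      for (s in pr$idx) {
        n_s <- length(s)
        take <- n_s %/% 2L
        if (n_s %% 2L == 1L && stats::runif(1) < 0.5) take <- take + 1L
        in_A[s[sample.int(n_s, take)]] <- TRUE
      }
      eA[i] <- effect_fn(pr$d[in_A, , drop = FALSE])
      eB[i] <- effect_fn(pr$d[!in_A, , drop = FALSE])
    }
    keep <- is.finite(eA) & is.finite(eB)
    n_used[p] <- sum(keep)
    per_r[p] <- if (sum(keep) >= 3L) stats::cor(eA[keep], eB[keep])
                else NA_real_
  }
  if (all(is.na(per_r)))
    stop_pitrel("effect function produced no usable estimates in any ",
                "permutation", class = "pitrel_validation_error")
  clip <- 1 - 1e-12
  n_clipped_raw <- sum(abs(per_r) >= 1, na.rm = TRUE)
  r_c <- pmin(pmax(per_r, -clip), clip)
  r_sb <- spearman_brown(r_c)
  fz <- fisher_z_clip(r_sb)
  mean_z <- mean(fz$z, na.rm = TRUE)
  structure(list(
    coefficient = tanh(mean_z),
    mean_z = mean_z,
    per_perm_r = per_r,
    per_perm_r_sb = r_sb,
    n_permutations = n_perm,
    n_subjects_used = n_used,
    n_subjects = ns,
    n_clipped = n_clipped_raw + fz$n_clipped,
    seed = seed
  ), class = "pit_splithalf")
}

#' @export
print.pit_splithalf <- function(x, ...) {
  cat(sprintf(
    "Permutation split-half reliability: %.3f\n  (%d permutations, %d subjects, Spearman-Brown corrected, Fisher-z mean)\n",
    x$coefficient, x$n_permutations, x$n_subjects))
  invisible(x)
}

#' Absolute-agreement intraclass correlation (single measurement, two-way)
#'
#' Computes ICC(A,1): the single-measurement, absolute-agreement, two-way
#' model intraclass correlation between sessions, from the two-way ANOVA
#' mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`,
#' with the 95% confidence interval of McGraw and Wong's F-based
#' approximation. Absolute agreement penalizes systematic between-session
#' shifts, so the companion Pearson correlation (insensitive to such
#' shifts) is reported alongside. Under McGraw and Wong the
#' single-measurement agreement point estimate is identical for the
#' two-way random and two-way mixed models; the label states the model
#' explicitly. Negative estimates are reported as computed, not truncated.
#'
#' @param values Numeric matrix or data frame, subjects in rows and the
#'   `k >= 2` sessions (or split halves) in columns. Rows with missing
#'   cells are dropped listwise (count reported).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return An object of class `pit_icc`: list with `icc`, `ci_low`,
#'   `ci_high`, `mean_squares` (`MSR`, `MSC`, `MSE`), `n`, `k`,
#'   `model_label`, `pearson_r` (for `k = 2`), and `n_dropped`.
#' @export
icc_agreement <- function(values, conf_level = 0.95) {
  x <- as.matrix(values)
  if (!is.numeric(x) || ncol(x) < 2L)
    stop_pitrel("values must be a numeric matrix with >= 2 columns",
                class = "pitrel_validation_error")
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L)
    stop_pitrel("at least 2 complete subjects required",
                class = "pitrel_validation_error")
  if (all(abs(x - mean(x)) < 1e-14))
    stop_pitrel("zero total variance: ICC undefined",
                class = "pitrel_degenerate_error")
  long <- data.frame(
    y = as.vector(x),
    subj = factor(rep(seq_len(n), times = k)),
    meas = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subj + meas, data = long))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  alpha <- 1 - conf_level
  if (abs(1 - icc) < 1e-12) {
    ci <- c(icc, icc)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(
      n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
      n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    )
  }
  structure(list(
    icc = unname(icc),
    ci_low = unname(min(ci)), ci_high = unname(max(ci)),
    mean_squares = list(MSR = unname(MSR), MSC = unname(MSC),
                        MSE = unname(MSE)),
    n = n, k = k,
    model_label = "single-measurement, absolute-agreement, two-way",
    pearson_r = if (k == 2L) stats::cor(x[, 1], x[, 2]) else NA_real_,
    n_dropped = n_dropped
  ), class = "pit_icc")
}

#' @export
print.pit_icc <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f  [%.3f, %.3f]  (n = %d, k = %d)\n",
              x$model_label, x$icc, x$ci_low, x$ci_high, x$n, x$k))
  if (x$k == 2L) cat(sprintf("  Pearson r between sessions: %.3f\n",
                             x$pearson_r))
  invisible(x)
}

#' Paired t-test for between-session change
#'
#' Classical paired t on the session differences with a two-sided p-value.
#' Zero-variance differences with a nonzero mean yield an infinite t
#' (reported as such, p = 0); all-identical sessions give t = 0, p = 1.
#'
#' @param session1,session2 Equal-length numeric vectors.
#' @return A list of class `pit_change_test` with `t_statistic`, `df`
#'   (`n - 1`), `p_value` and `mean_difference`.
#' @export
paired_t_test <- function(session1, session2) {
  if (length(session1) != length(session2))
    stop_pitrel("sessions must have equal length",
                class = "pitrel_validation_error")
  keep <- is.finite(session1) & is.finite(session2)
  d <- session1[keep] - session2[keep]
  n <- length(d)
  if (n < 2L)
    stop_pitrel("at least 2 complete pairs required",
                class = "pitrel_validation_error")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t_stat <- m / (s / sqrt(n))
  }
  p <- if (is.infinite(t_stat)) 0 else
    2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  structure(list(t_statistic = t_stat, df = n - 1L, p_value = p,
                 mean_difference = m),
            class = "pit_change_test")
}

#' Classify a reliability coefficient
#'
#' Maps a coefficient to a qualitative label under either of the two
#' standard guideline schemes:
#' \describe{
#'   \item{`koo_li`}{poor < 0.5, moderate 0.5-0.75, good 0.75-0.9,
#'     excellent >= 0.9.}
#'   \item{`cicchetti`}{poor < 0.4, fair 0.4-0.6, good 0.6-0.75,
#'     excellent >= 0.75.}
#' }
#' Bin edges are inclusive for the higher category (0.75 is "good" under
#' `koo_li`, "excellent" under `cicchetti`).
#'
#' @param value Coefficient(s), at most 1 (negative values allowed and
#'   classified into the lowest bin).
#' @param scheme `"koo_li"` or `"cicchetti"`.
#' @return Character vector of labels.
#' @examples
#' classify_reliability(0.53, "koo_li")   # "moderate"
#' classify_reliability(0.92, "koo_li")   # "excellent"
#' @export
classify_reliability <- function(value, scheme = c("koo_li", "cicchetti")) {
  scheme <- match.arg(scheme)
  if (any(value > 1, na.rm = TRUE))
    stop_pitrel("reliability coefficients cannot exceed 1",
                class = "pitrel_validation_error")
  cuts <- switch(scheme,
    koo_li = list(breaks = c(0.5, 0.75, 0.9),
                  labels = c("poor", "moderate", "good", "excellent")),
    cicchetti = list(breaks = c(0.4, 0.6, 0.75),
                     labels = c("poor", "fair", "good", "excellent"))
  )
  idx <- findInterval(value, cuts$breaks) + 1L
  out <- cuts$labels[idx]
  out[is.na(value)] <- NA_character_
  out
}
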