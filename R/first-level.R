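as_volume <- function(v, geometry) array(v, geometry$dim)

# Moore-Penrose pseudoinverse via SVD (used only for rank-deficient designs)
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Per-voxel ordinary least squares with contrasts
#'
#' Fits the trial-amplitude linear model at every voxel: for amplitude
#' matrix `Y` (trials by voxels) and design `X`, computes OLS betas,
#' contrast estimates, their standard errors from the per-voxel residual
#' variance with `df = n_trials - rank(X)`, and t statistics
#' `t = beta / SE`. A rank-deficient design is handled by the
#' pseudoinverse with a warning and the correspondingly reduced df.
#'
#' @param amplitudes Trials-by-voxels numeric matrix.
#' @param design A [build_design()] object (rows must match trials).
#' @param geometry A [toy_geometry()] object.
#' @param contrasts Named list of weight vectors; defaults to
#'   [design_contrasts()] of the design.
#'
#' @return An object of class `pit_first_level`: list with `model`,
#'   `contrasts` (per contrast: 3-D `beta`, `se`, `t` arrays), `df`,
#'   `rank`, `masks` and `geometry`.
#' @export
estimate_first_level <- function(amplitudes, design, geometry,
                                 contrasts = NULL) {
  stopifnot(inherits(design, "pit_design"),
            inherits(geometry, "pit_geometry"))
  Y <- as.matrix(amplitudes)
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop_pitrel("amplitude rows (", nrow(Y), ") do not match design rows (",
                nrow(X), ")")
  if (ncol(Y) != geometry$n_voxels)
    stop_pitrel("amplitude columns do not match geometry voxel count")
  if (is.null(contrasts)) contrasts <- design_contrasts(design)

  qrX <- qr(X)
  rank <- qrX$rank
  n <- nrow(X)
  df <- n - rank
  if (df < 1L) stop_pitrel("no residual degrees of freedom")
  if (rank < ncol(X)) {
    warning("rank-deficient design (rank ", rank, " < ", ncol(X),
            " columns); using pseudoinverse", call. = FALSE)
    XtX_inv <- pinv(crossprod(X))
    B <- XtX_inv %*% crossprod(X, Y)
  } else {
    XtX_inv <- chol2inv(chol(crossprod(X)))
    B <- qr.coef(qrX, Y)
  }
  resid <- Y - X %*% B
  sigma2 <- colSums(resid^2) / df

  out <- list()
  for (nm in names(contrasts)) {
    w <- contrasts[[nm]]
    if (length(w) != ncol(X))
      stop_pitrel("contrast '", nm, "' has wrong length")
    beta_c <- drop(crossprod(w, B))
    var_scale <- drop(crossprod(w, XtX_inv %*% w))
    se_c <- sqrt(sigma2 * var_scale)
    t_c <- ifelse(se_c > 0, beta_c / se_c, NaN)
    out[[nm]] <- list(beta = as_volume(beta_c, geometry),
                      se = as_volume(se_c, geometry),
                      t = as_volume(t_c, geometry))
  }
  structure(list(model = design$model, contrasts = out, df = df,
                 rank = rank, masks = geometry$masks, geometry = geometry),
            class = "pit_first_level")
}

#' Split-half re-estimation of first-level maps
#'
#' Randomly splits the transfer trials of one subject-session into
#' stratified halves (by cue value and required action), then re-estimates
#' the first-level model independently on each half with the same
#' contrasts. Consumes the RNG stream; seed upstream for determinism.
#'
#' @param pit_trials Transfer-phase trial records for one subject-session.
#' @param amplitudes The matching trials-by-voxels amplitude matrix.
#' @param geometry A [toy_geometry()] object.
#' @param model `"interference"` or `"motivational"` (or both).
#'
#' @return A list with `A` and `B` (each a named list of
#'   `pit_first_level` objects, one per model) plus `idx_A`, `idx_B`.
#' @export
split_half_neural <- function(pit_trials, amplitudes, geometry,
                              model = c("interference", "motivational")) {
  model <- match.arg(model, several.ok = TRUE)
  halves <- split_trials(pit_trials)
  fit_half <- function(d, idx) {
    fits <- list()
    for (m in model)
      fits[[m]] <- estimate_first_level(amplitudes[idx, , drop = FALSE],
                                        build_design(d, m), geometry)
    fits
  }
  list(A = fit_half(halves$A, halves$idx_A),
       B = fit_half(halves$B, halves$idx_B),
       idx_A = halves$idx_A, idx_B = halves$idx_B)
}

#' Unweighted mean of a map over an ROI mask
#'
#' @param map 3-D numeric array.
#' @param mask Logical array of the same shape, nonempty.
#' @return The unweighted arithmetic mean of `map` over the mask voxels.
#'   A non-finite voxel inside the mask is an error (no silent NaN
#'   propagation).
#' @export
roi_mean <- function(map, mask) {
  if (!identical(dim(map), dim(mask)))
    stop_pitrel("map and mask geometries differ",
                class = "pitrel_geometry_error")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop_pitrel("empty ROI mask",
                              class = "pitrel_geometry_error")
  vals <- map[mask]
  if (any(!is.finite(vals)))
    stop_pitrel("non-finite values inside the ROI mask")
  mean(vals)
}

#' ROI intraclass correlation
#'
#' Convenience wrapper: applies [icc_agreement()] to a subjects-by-2
#' matrix of ROI mean betas (two sessions, or two split halves).
#'
#' @param values Subjects-by-2 numeric matrix.
#' @param ... Passed to [icc_agreement()].
#' @return A `pit_icc` object.
#' @export
roi_icc <- function(values, ...) icc_agreement(values, ...)

#' Voxel-wise intraclass correlation map
#'
#' Computes the absolute-agreement single-measurement ICC independently at
#' every voxel from two subjects-by-voxels beta matrices (sessions or
#' split halves). Voxels that are constant across all subjects and both
#' measurements are undefined and stored as `NaN` (count in attribute
#' `n_degenerate`).
#'
#' @param maps_A,maps_B Subjects-by-voxels matrices (or lists of 3-D
#'   arrays, one per subject) with identical geometry.
#' @param geometry Optional [toy_geometry()]; when given the result is
#'   returned as a 3-D array, otherwise as a vector.
#' @return ICC values per voxel with attribute `n_degenerate`.
#' @export
voxelwise_icc <- function(maps_A, maps_B, geometry = NULL) {
  to_mat <- function(m) {
    if (is.list(m)) do.call(rbind, lapply(m, as.vector)) else as.matrix(m)
  }
  A <- to_mat(maps_A); B <- to_mat(maps_B)
  if (!all(dim(A) == dim(B)))
    stop_pitrel("map sets have different dimensions",
                class = "pitrel_geometry_error")
  n <- nrow(A)
  if (n < 3L) stop_pitrel("at least 3 subjects required",
                          class = "pitrel_validation_error")
  k <- 2
  cmA <- colMeans(A); cmB <- colMeans(B)
  grand <- (cmA + cmB) / 2
  rowm <- (A + B) / 2
  SSR <- k * colSums(sweep(rowm, 2, grand)^2)
  SSC <- n * ((cmA - grand)^2 + (cmB - grand)^2)
  SST <- colSums(sweep(A, 2, grand)^2) + colSums(sweep(B, 2, grand)^2)
  SSE <- pmax(SST - SSR - SSC, 0)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  icc <- (MSR - MSE) / denom
  degenerate <- SST < 1e-20 | abs(denom) < 1e-20
  icc[degenerate] <- NaN
  out <- if (!is.null(geometry)) as_volume(icc, geometry) else icc
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Threshold a t map at an uncorrected p level
#'
#' Includes a voxel when its t statistic exceeds the Student-t critical
#' value for the requested uncorrected p threshold (default two-sided on
#' `|t|`; `tail = "positive"` thresholds the upper tail only).
#' `p_threshold = 1` degenerately includes every voxel.
#'
#' @param t_map 3-D array of t statistics.
#' @param df Residual degrees of freedom (at least 1).
#' @param p_threshold Uncorrected p threshold in `(0, 1]`.
#' @param tail `"two.sided"` or `"positive"`.
#' @return Logical array; `NA`/`NaN` t values are excluded.
#' @export
threshold_map <- function(t_map, df, p_threshold = 0.01,
                          tail = c("two.sided", "positive")) {
  tail <- match.arg(tail)
  assert_scalar_number(p_threshold, "p_threshold", min = 0, max = 1)
  if (p_threshold <= 0) stop_pitrel("p_threshold must be positive")
  assert_scalar_number(df, "df", min = 1)
  if (p_threshold >= 1) {
    out <- array(TRUE, dim(t_map))
    return(out)
  }
  if (tail == "two.sided") {
    crit <- stats::qt(1 - p_threshold / 2, df)
    out <- abs(t_map) > crit
  } else {
    crit <- stats::qt(1 - p_threshold, df)
    out <- t_map > crit
  }
  out[is.na(out)] <- FALSE
  out
}

#' Jaccard overlap of two binary maps
#'
#' `|A intersect B| / |A union B|`: the share of supra-threshold voxels
#' common to both maps, 1 for perfect overlap, 0 for disjoint maps. When
#' both masks are empty the coefficient is undefined and reported as
#' `NaN` with `both_empty = TRUE` (excluded from group summaries rather
#' than scored as 0 or 1).
#'
#' @param mask_A,mask_B Logical arrays of identical shape.
#' @return A list of class `pit_overlap` with `jaccard`, `n_A`, `n_B`,
#'   `n_intersection`, `n_union`, and `both_empty`.
#' @export
jaccard <- function(mask_A, mask_B) {
  if (!identical(dim(mask_A), dim(mask_B)))
    stop_pitrel("mask geometries differ", class = "pitrel_geometry_error")
  a <- as.logical(mask_A); b <- as.logical(mask_B)
  n_int <- sum(a & b)
  n_uni <- sum(a | b)
  structure(list(
    jaccard = if (n_uni > 0) n_int / n_uni else NaN,
    n_A = sum(a), n_B = sum(b),
    n_intersection = n_int, n_union = n_uni,
    both_empty = n_uni == 0
  ), class = "pit_overlap")
}
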