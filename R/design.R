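cue_label <- function(v) {
  ifelse(v < 0, paste0("cs_m", abs(v)), paste0("cs_p", v))
}

#' Build a first-level design matrix from transfer trials
#'
#' Two trial-amplitude models are available:
#' \describe{
#'   \item{interference}{10 indicator regressors, one per cue value by
#'     instrumental condition (collect/reject) cell. Rows sum to 1 across
#'     the indicators. Cells absent from the data are dropped with a
#'     warning and recorded.}
#'   \item{motivational}{one onset regressor covering every monetary
#'     transfer trial plus three parametric modulators -- the interaction
#'     of cue value with log button presses (the motivational PIT
#'     effect), the cue value alone, and the log presses alone. Presses
#'     are transformed as `log(presses + 1)` (zero presses occur).
#'     Modulators are mean-centred and deliberately NOT orthogonalized,
#'     so each keeps its own interpretation.}
#' }
#'
#' @param trials Transfer-phase trial records for one subject-session (or
#'   one split half).
#' @param model `"interference"` or `"motivational"`.
#'
#' @return An object of class `pit_design`: list with the matrix `X`,
#'   `model`, `columns`, `cells` (interference only), `dropped_cells`,
#'   and `orthogonalized = FALSE`.
#' @export
build_design <- function(trials, model = c("interference", "motivational")) {
  model <- match.arg(model)
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "pit", ]
  n <- nrow(trials)
  if (n == 0L) stop_pitrel("no transfer trials supplied")
  if (model == "interference") {
    cue_values <- sort(unique(trials$cue_value))
    cells <- expand.grid(cue_value = cue_values,
                         required_action = c("collect", "reject"),
                         stringsAsFactors = FALSE)
    cells$column <- paste(cue_label(cells$cue_value), cells$required_action,
                          sep = "_")
    X <- matrix(0, n, nrow(cells), dimnames = list(NULL, cells$column))
    for (j in seq_len(nrow(cells))) {
      X[trials$cue_value == cells$cue_value[j] &
          trials$required_action == cells$required_action[j], j] <- 1
    }
    present <- colSums(X) > 0
    dropped <- cells$column[!present]
    if (length(dropped)) {
      warning("design cell(s) absent from the data, dropped: ",
              paste(dropped, collapse = ", "), call. = FALSE)
      X <- X[, present, drop = FALSE]
      cells <- cells[present, , drop = FALSE]
    }
    out <- list(X = X, model = model, columns = colnames(X),
                cells = cells, dropped_cells = dropped,
                orthogonalized = FALSE)
  } else {
    lp <- log(trials$button_presses + 1)
    v <- trials$cue_value
    mods <- cbind(motivational = v * lp, cs_value = v, log_presses = lp)
    mods <- sweep(mods, 2, colMeans(mods))
    X <- cbind(onset = rep(1, n), mods)
    degenerate <- colnames(mods)[apply(mods, 2, function(c) all(abs(c) < 1e-12))]
    if (length(degenerate))
      warning("constant parametric modulator(s) (zero after centring): ",
              paste(degenerate, collapse = ", "),
              "; design is rank deficient", call. = FALSE)
    out <- list(X = X, model = model, columns = colnames(X),
                cells = NULL, dropped_cells = character(0),
                orthogonalized = FALSE)
  }
  structure(out, class = "pit_design")
}

#' Contrast weights for a first-level design
#'
#' For the interference model: `incongruent` and `congruent` are the
#' unweighted means of their four constituent cue-by-action cells
#' (collect under negative cues / reject under positive cues, and the
#' reverse), and `incongruent_vs_congruent` is their difference (weights
#' sum to zero). For the motivational model the four contrasts
#' (`monetary_onset`, `motivational_pit`, `cs_value`, `log_presses`) each
#' select one design column.
#'
#' @param design A [build_design()] object.
#' @return Named list of weight vectors over the design columns.
#' @export
design_contrasts <- function(design) {
  stopifnot(inherits(design, "pit_design"))
  p <- length(design$columns)
  zero <- stats::setNames(numeric(p), design$columns)
  if (design$model == "interference") {
    cells <- design$cells
    lab <- label_congruency(cells$cue_value, cells$required_action)
    inc <- zero; cng <- zero
    inc_cols <- cells$column[lab == "incongruent"]
    cng_cols <- cells$column[lab == "congruent"]
    if (!length(inc_cols) || !length(cng_cols))
      stop_pitrel("design lacks incongruent or congruent cells")
    inc[inc_cols] <- 1 / length(inc_cols)
    cng[cng_cols] <- 1 / length(cng_cols)
    list(incongruent = inc, congruent = cng,
         incongruent_vs_congruent = inc - cng)
  } else {
    one_col <- function(nm) { w <- zero; w[nm] <- 1; w }
    list(monetary_onset = one_col("onset"),
         motivational_pit = one_col("motivational"),
         cs_value = one_col("cs_value"),
         log_presses = one_col("log_presses"))
  }
}
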