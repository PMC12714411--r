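# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pitrel <- function(..., class = "pitrel_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_pitrel(name, " must be a single finite number",
                class = "pitrel_validation_error")
  if (x < min || x > max)
    stop_pitrel(name, " must lie in [", min, ", ", max, "], got ", x,
                class = "pitrel_validation_error")
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name, min = min)
  if (x != round(x))
    stop_pitrel(name, " must be an integer, got ", x,
                class = "pitrel_validation_error")
  invisible(as.integer(x))
}

# Fisher z with clipping at |r| = 1 - 1e-12; returns z and the clip count
fisher_z_clip <- function(r, clip = 1 - 1e-12) {
  n_clipped <- sum(abs(r) >= 1, na.rm = TRUE)
  r <- pmin(pmax(r, -clip), clip)
  list(z = atanh(r), n_clipped = n_clipped)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}
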