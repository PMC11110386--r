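#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
run_seeded <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fn()
}

#' Percentage rounded to the nearest integer, NA on an empty denominator.
#' @noRd
round_pct <- function(num, den) {
  out <- rep(NA_real_, length(num))
  d <- rep_len(den, length(num))
  ok <- d > 0
  out[ok] <- round(100 * num[ok] / d[ok])
  out
}

#' Classed configuration/format errors so callers can distinguish them.
#' @noRd
abort_config <- function(msg) {
  stop(structure(class = c("emaphase_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @noRd
abort_format <- function(msg) {
  stop(structure(class = c("emaphase_format_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
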