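# Dynamic complexity: fluctuation measure F times distribution measure D
# over backward overlapping windows, and the one-tailed z flag for
# significant instability.

check_window <- function(window, s_min, s_max) {
  if (s_max - s_min <= 0) abort_config("degenerate scale: s_max must exceed s_min")
  if (anyNA(window)) abort_format("window contains missing values; impute first")
  if (length(window) < 2) abort_format("window needs at least 2 values")
  if (any(window < s_min | window > s_max)) {
    abort_format("window values must lie within the scale bounds")
  }
  invisible(window)
}

#' Fluctuation measure F
#'
#' Splits the window into maximal monotone segments at direction
#' reversals (plateau points extend the current segment). For segment k
#' with amplitude `a_k = |end - start|` and duration `d_k` intervals,
#' `F = sum(a_k / d_k) / (R * (m - 1))` with `R = s_max - s_min`, so a
#' constant window scores 0 and maximal point-to-point alternation over
#' the full scale scores 1.
#'
#' @param window Numeric vector of `m >= 2` complete values in
#'   `[s_min, s_max]`.
#' @param s_min,s_max Theoretical scale bounds (defaults 0 and 5).
#' @return F in `[0, 1]`.
#' @export
fluctuation_F <- function(window, s_min = 0, s_max = 5) {
  check_window(window, s_min, s_max)
  m <- length(window)
  d <- diff(window)
  total <- 0
  start <- 1L
  dir <- 0
  for (i in seq_along(d)) {
    s <- sign(d[i])
    if (s != 0 && dir != 0 && s != dir) {
      total <- total + abs(window[i] - window[start]) / (i - start)
      start <- i
      dir <- s
    } else if (s != 0 && dir == 0) {
      dir <- s
    }
  }
  if (m > start) total <- total + abs(window[m] - window[start]) / (m - start)
  total / ((s_max - s_min) * (m - 1))
}

#' Distribution measure D
#'
#' Uniformity of the window's values over the scale range: the sorted
#' values are compared pair-by-pair against the ideal uniform positions
#' `I_i = s_min + (i - 1) R / (m - 1)`, and each pairwise span that falls
#' short of its ideal span contributes its deficit:
#' `D = 1 - sum_{i<j} max(0, (I_j - I_i) - (y_j - y_i)) / sum_{i<j} (I_j - I_i)`.
#' A constant window scores 0; values exactly at the ideal positions score
#' 1. D is invariant to within-window reordering.
#'
#' @inheritParams fluctuation_F
#' @return D in `[0, 1]`.
#' @export
distribution_D <- function(window, s_min = 0, s_max = 5) {
  check_window(window, s_min, s_max)
  m <- length(window)
  y <- sort(window)
  ideal <- s_min + (seq_len(m) - 1) * (s_max - s_min) / (m - 1)
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)  # row i < col j
  di <- ideal[ut[, 2]] - ideal[ut[, 1]]
  dy <- y[ut[, 2]] - y[ut[, 1]]
  1 - sum(pmax(0, di - dy)) / sum(di)
}

#' Windowed dynamic complexity of one item
#'
#' `DC_t = F * D` on the backward window of `width` days ending at day t,
#' for `t = width .. N`; the window shifts one day at a time without
#' changing width. The series must be complete (impute first, see
#' [impute_local_level()]).
#'
#' @param series Complete numeric series on the `[s_min, s_max]` scale.
#' @param width Window width in days (default 7, one weekly routine).
#' @param s_min,s_max Theoretical scale bounds.
#' @param item_name Label carried into the trace.
#' @return A tibble (`complexity_trace`): `item`, `day` (window end),
#'   `F`, `D`, `DC`. Empty when the series is shorter than `width`.
#' @export
dynamic_complexity <- function(series, width = 7, s_min = 0, s_max = 5,
                               item_name = "series") {
  if (anyNA(series)) abort_format("series contains missing values; impute first")
  n <- length(series)
  if (n < width) {
    out <- tibble(item = character(0), day = integer(0),
                  F = numeric(0), D = numeric(0), DC = numeric(0))
  } else {
    days <- width:n
    Fv <- vapply(days, function(t) {
      fluctuation_F(series[(t - width + 1):t], s_min, s_max)
    }, numeric(1))
    Dv <- vapply(days, function(t) {
      distribution_D(series[(t - width + 1):t], s_min, s_max)
    }, numeric(1))
    out <- tibble(item = item_name, day = as.integer(days),
                  F = Fv, D = Dv, DC = Fv * Dv)
  }
  attr(out, "width") <- width
  attr(out, "scale") <- c(s_min, s_max)
  class(out) <- unique(c("complexity_trace", class(out)))
  out
}

#' Flag windows with significant instability
#'
#' One-tailed z rule on the dynamic complexity timeline: a window is
#' flagged when its DC value strictly exceeds
#' `mean(DC) + qnorm(1 - alpha) * sd(DC)` (sample SD, n-1 denominator).
#' The threshold is self-referential to the trace, so a zero-variance
#' trace yields no flags, and adding a constant to every DC value leaves
#' the flags unchanged.
#'
#' @param trace A `complexity_trace` from [dynamic_complexity()].
#' @param alpha One-tailed significance level (default 0.05).
#' @return The trace with `threshold` and `flagged` columns added.
#' @export
flag_instability <- function(trace, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort_config("alpha must lie in (0, 1)")
  if (!nrow(trace)) {
    trace$threshold <- numeric(0)
    trace$flagged <- logical(0)
    return(trace)
  }
  s <- stats::sd(trace$DC)
  thr <- mean(trace$DC) + stats::qnorm(1 - alpha) * s
  trace$threshold <- thr
  trace$flagged <- if (is.finite(s) && s > 0) trace$DC > thr else FALSE
  trace
}
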