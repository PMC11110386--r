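#' Impute an ordinal series with a local-level state-space smoother
#'
#' Fits a Gaussian local-level (random walk plus observation noise)
#' structural model by maximum likelihood and replaces missing values with
#' the smoothed posterior mean of the level, clamped to the instrument
#' scale. Observed values are returned untouched, so the operation is
#' idempotent on a complete series. Imputed values are left continuous:
#' downstream dynamic complexity accepts ordinal or continuous input.
#'
#' @param series Numeric vector on the `[s_min, s_max]` scale, NA = missing.
#' @param s_min,s_max Theoretical scale bounds (defaults 0 and 5).
#' @return Numeric vector of the same length with no missing values.
#' @export
impute_local_level <- function(series, s_min = 0, s_max = 5) {
  x <- as.numeric(series)
  obs <- !is.na(x)
  if (!any(obs)) abort_format("cannot impute an all-missing series")
  if (sum(obs) < 10) abort_format("need at least 10 observed points to fit the model")
  if (!any(!obs)) return(x)
  vals <- x[obs]
  if (stats::sd(vals) == 0) {
    # degenerate state space: zero variance, smoothed level is the constant
    x[!obs] <- vals[1]
    return(x)
  }
  # optim occasionally reports line-search trouble on near-degenerate
  # series; the fitted variances are still usable, so only hard errors
  # trigger the fallback
  fit <- tryCatch(suppressWarnings(stats::StructTS(stats::ts(x), type = "level")),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    sm <- as.numeric(stats::tsSmooth(fit)[, 1])
  } else {
    # ML fit failed to converge on this series; fall back to the smoothed
    # limit of the local-level model as observation noise vanishes, i.e.
    # interpolation between neighbouring observations
    sm <- stats::approx(which(obs), x[obs], xout = seq_along(x), rule = 2)$y
  }
  x[!obs] <- clamp(sm[!obs], s_min, s_max)
  x
}
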