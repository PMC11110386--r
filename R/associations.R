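# Exact 2x2 association screens between day-level factors and behaviors,
# contemporaneous and lag-1, over the full timeline and per phase.

#' Exact test on a 2x2 table
#'
#' Two-sided Fisher exact test using the point-probability rule over the
#' hypergeometric distribution, the conditional maximum-likelihood odds
#' ratio under the noncentral hypergeometric, and the exact 95% CI by test
#' inversion (the conventions of `stats::fisher.test`). Degenerate margins
#' (an all-zero row or column) are untestable: p = 1 and no odds ratio.
#'
#' @param tab A 2x2 matrix of nonnegative integer counts.
#' @return A list with `p`, `odds_ratio`, `ci` (length-2), `testable`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort_format("table must be 2x2")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    abort_format("counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, odds_ratio = NA_real_, ci = c(NA_real_, NA_real_),
                testable = FALSE))
  }
  ft <- stats::fisher.test(tab, conf.int = TRUE, conf.level = 0.95)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate),
       ci = unname(ft$conf.int), testable = TRUE)
}

#' Cross-tabulate a factor against a behavior, contemporaneous or lag-1
#'
#' Lag 0 pairs `(factor_t, behavior_t)`; lag 1 pairs
#' `(factor_t, behavior_(t+1))`, asking whether the factor on one day is
#' associated with the behavior on the next. Pairs whose behavior day is
#' missing are dropped (the factor side is records-derived and observed
#' every day); lagged pairs are formed on calendar days, never
#' interpolated.
#'
#' @param factor_series Binary 0/1 vector.
#' @param behavior_series Binary 0/1 vector (NA = missing diary day).
#' @param lag 0 or 1.
#' @return A 2x2 matrix, rows factor (1, 0), columns behavior (1, 0).
#' @export
crosstab_lagged <- function(factor_series, behavior_series, lag = 0) {
  if (length(factor_series) != length(behavior_series)) {
    abort_format("series must have equal length")
  }
  if (!lag %in% c(0, 1)) abort_config("lag must be 0 or 1")
  n <- length(factor_series)
  if (lag == 1) {
    if (n < 2) abort_format("no lagged pairs available")
    f <- factor_series[-n]
    b <- behavior_series[-1]
  } else {
    f <- factor_series
    b <- behavior_series
  }
  keep <- !is.na(f) & !is.na(b)
  if (!any(keep)) abort_format("empty overlap: no complete pairs")
  f <- f[keep]
  b <- b[keep]
  matrix(c(sum(f == 1 & b == 1), sum(f == 1 & b == 0),
           sum(f == 0 & b == 1), sum(f == 0 & b == 0)),
         nrow = 2, byrow = TRUE,
         dimnames = list(factor = c("1", "0"), behavior = c("1", "0")))
}

#' Exact association screen: factors x behaviors x lags x scopes
#'
#' Runs [fisher_exact_2x2()] on every factor-behavior pair at lag 0 and
#' lag 1, over the full timeline and (when a segmentation is supplied)
#' within every phase, so a k-phase case emits
#' `n_factors * 2 * 2` full-timeline tests plus `n_factors * 2 * k * 2`
#' per-phase tests. Significance is evaluated at `p < alpha`
#' (default 0.01, the multiplicity rule for this many repeated bivariate
#' tests); scopes too degenerate to test are emitted as untestable and
#' never significant.
#'
#' @param themes A [theme_matrix()].
#' @param diary An [ema_diary()] on the same timeline.
#' @param segmentation Optional `ema_segmentation` for per-phase tests.
#' @param alpha Significance threshold (default 0.01).
#' @return A tibble: `factor`, `behavior`, `lag`, `scope`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `ci_low`, `ci_high`, `p`, `significant`,
#'   `testable`.
#' @export
assoc_screen <- function(themes, diary, segmentation = NULL, alpha = 0.01) {
  if (nrow(themes) != nrow(diary)) {
    abort_format("themes and diary must cover the same timeline")
  }
  facs <- setdiff(names(themes), "day")
  scopes <- list(full = seq_len(nrow(diary)))
  if (!is.null(segmentation)) {
    for (i in seq_len(nrow(segmentation))) {
      scopes[[sprintf("phase_%d", segmentation$phase[i])]] <-
        segmentation$start[i]:segmentation$end[i]
    }
  }
  rows <- vector("list", length(scopes) * length(facs) * 4L)
  k <- 0L
  for (sc in names(scopes)) {
    span <- scopes[[sc]]
    for (f in facs) {
      for (beh in diary_behaviors()) {
        for (lag in 0:1) {
          k <- k + 1L
          tab <- tryCatch(
            crosstab_lagged(themes[[f]][span], diary[[beh]][span], lag),
            error = function(e) NULL
          )
          if (is.null(tab)) {
            res <- list(p = NA_real_, odds_ratio = NA_real_,
                        ci = c(NA_real_, NA_real_), testable = FALSE)
            tab <- matrix(NA_integer_, 2, 2)
          } else {
            res <- fisher_exact_2x2(tab)
          }
          rows[[k]] <- tibble(
            factor = f, behavior = beh, lag = lag, scope = sc,
            a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
            odds_ratio = res$odds_ratio,
            ci_low = res$ci[1], ci_high = res$ci[2], p = res$p,
            significant = isTRUE(res$testable) &
              !is.na(res$p) & res$p < alpha,
            testable = res$testable
          )
        }
      }
    }
  }
  bind_rows(rows)
}
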