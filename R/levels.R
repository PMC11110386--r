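# Level detection by recursive partitioning on the time index, the two
# configurable change-point suppression rules, phase construction, and
# attractor/salience labelling.

#' Detect mean-level changes in a daily incident series
#'
#' Greedy recursive binary splitting on the time index (CART-style level
#' detection): within each segment, the accepted split minimises the
#' within-child sum of squares among the candidates that satisfy the
#' acceptance constraints -- both children span at least `min_len`
#' calendar days and the two child means differ by at least `min_change`
#' (absolute, on the 0-1 incident-proportion scale). Recursion continues
#' on accepted children and stops when a segment has no valid candidate,
#' so an invalid split can never mask a valid one deeper in the segment.
#' The change criterion is the pruning rule; no cross-validation is
#' involved, so the result is deterministic. Missing days are excluded
#' from segment means and sums of squares (the denominator is the number
#' of observed days in the segment), but count towards segment duration.
#'
#' @param series Numeric vector (binary incident series; NA = missing day).
#' @param min_len Minimum phase duration in days (default 7, one weekly
#'   routine).
#' @param min_change Minimum absolute change in segment mean (default
#'   0.25, i.e. 25 percentage points of incident proportion).
#' @param series_name Label carried into the change-point table.
#' @return A list of class `level_detection` with `segments`
#'   (`start`, `end`, `n_obs`, `mean`) and `changepoints`
#'   (`day`, `series`, `delta`, `direction`, `mean_before`, `mean_after`;
#'   `day` is the first day of the new segment).
#' @export
detect_levels <- function(series, min_len = 7, min_change = 0.25,
                          series_name = "series") {
  if (min_len < 1 || min_change < 0) abort_config("invalid detection thresholds")
  n <- length(series)
  obs <- !is.na(series)
  x <- as.numeric(series)
  x[!obs] <- 0
  cx <- c(0, cumsum(x))
  cq <- c(0, cumsum(x^2))
  cn <- c(0, cumsum(obs))

  boundaries <- integer(0)
  recurse <- function(l, r) {
    if (r - l + 1 < 2 * min_len) return(invisible())
    s <- (l + min_len - 1):(r - min_len)
    n1 <- cn[s + 1] - cn[l]
    n2 <- cn[r + 1] - cn[s + 1]
    S1 <- cx[s + 1] - cx[l]
    S2 <- cx[r + 1] - cx[s + 1]
    Q1 <- cq[s + 1] - cq[l]
    Q2 <- cq[r + 1] - cq[s + 1]
    ok <- n1 > 0 & n2 > 0
    valid <- ok
    valid[ok] <- abs(S2 / n2 - S1 / n1)[ok] >= min_change - 1e-12
    if (!any(valid)) return(invisible())
    sse <- rep(Inf, length(s))
    sse[valid] <- (Q1 - S1^2 / n1)[valid] + (Q2 - S2^2 / n2)[valid]
    # ties (within numerical tolerance) resolved towards the earliest split
    best <- which(sse <= min(sse) + 1e-9)[1]
    sb <- s[best]
    boundaries <<- c(boundaries, sb)
    recurse(l, sb)
    recurse(sb + 1, r)
  }
  recurse(1, n)

  build_level_detection(series, sort(boundaries), series_name,
                        list(min_len = min_len, min_change = min_change))
}

# Rebuild a level_detection object from a set of segment-final days.
build_level_detection <- function(series, boundaries, series_name, params) {
  n <- length(series)
  starts <- c(1L, as.integer(boundaries) + 1L)
  ends <- c(as.integer(boundaries), n)
  n_obs <- vapply(seq_along(starts),
                  function(i) sum(!is.na(series[starts[i]:ends[i]])), integer(1))
  means <- vapply(seq_along(starts),
                  function(i) mean(series[starts[i]:ends[i]], na.rm = TRUE),
                  numeric(1))
  k <- length(starts)
  cps <- if (k > 1) {
    delta <- means[-1] - means[-k]
    tibble(
      day = starts[-1],
      series = series_name,
      delta = delta,
      direction = ifelse(delta > 0, "increase", "decrease"),
      mean_before = means[-k],
      mean_after = means[-1]
    )
  } else {
    tibble(day = integer(0), series = character(0), delta = numeric(0),
           direction = character(0), mean_before = numeric(0),
           mean_after = numeric(0))
  }
  structure(list(
    series_name = series_name,
    segments = tibble(start = starts, end = ends, n_obs = n_obs, mean = means),
    changepoints = cps,
    params = params,
    n_days = n
  ), class = "level_detection")
}

#' Apply the automatic change-point suppression rules
#'
#' Two configurable rules replace the manual exclusions a rater would make
#' on visual inspection: (a) a change-point is suppressed when the mean of
#' the segment it opens differs by less than `min_change` from the mean of
#' its merged surrounding segments (the new level is redundant relative to
#' its context); (b) a change-point is suppressed when more than
#' `missing_frac` of the following `min_len` days are missing (the new
#' level is supported by too little data). Suppressions are applied in day
#' order, segments re-merged after each, and every decision is logged in
#' the `"log"` attribute.
#'
#' @param ld A `level_detection` from [detect_levels()].
#' @param series The series `ld` was computed on.
#' @param min_change,min_len Defaults taken from `ld`.
#' @param missing_frac Missingness fraction above which rule (b) fires.
#' @return A rebuilt `level_detection`; suppression messages in
#'   `attr(, "log")`.
#' @export
suppress_changepoints <- function(ld, series,
                                  min_change = ld$params$min_change,
                                  min_len = ld$params$min_len,
                                  missing_frac = 0.4) {
  n <- length(series)
  bounds <- ld$changepoints$day - 1L  # segment-final days
  log <- character(0)
  i <- 1L
  while (i <= length(bounds)) {
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    j <- i + 1L  # segment opened by this change-point
    t <- starts[j]
    drop <- FALSE
    tail_idx <- t:min(t + min_len - 1L, n)
    na_frac <- mean(is.na(series[tail_idx]))
    if (na_frac > missing_frac) {
      drop <- TRUE
      log <- c(log, sprintf(
        "%s: change-point at day %d suppressed (%.0f%% of the following %d days missing)",
        ld$series_name, t, 100 * na_frac, min_len))
    }
    if (!drop && j < length(starts)) {
      mB <- mean(series[starts[j]:ends[j]], na.rm = TRUE)
      region <- c(series[starts[j - 1]:ends[j - 1]],
                  series[starts[j + 1]:ends[j + 1]])
      mR <- mean(region, na.rm = TRUE)
      if (is.finite(mB) && is.finite(mR) && abs(mB - mR) < min_change) {
        drop <- TRUE
        log <- c(log, sprintf(
          "%s: change-point at day %d suppressed (segment mean %.2f within %.2f of merged surroundings %.2f)",
          ld$series_name, t, mB, min_change, mR))
      }
    }
    if (drop) bounds <- bounds[-i] else i <- i + 1L
  }
  out <- build_level_detection(series, bounds, ld$series_name, ld$params)
  attr(out, "log") <- log
  out
}

#' Pair change-points of two behavior series into transitions
#'
#' Same-direction change-points of the two series lying within `proximity`
#' days of each other are merged into one transition. The marked day is
#' chosen by policy: when one change dominates (its absolute delta is at
#' least `dominance_ratio` times the other's) the dominant change's day is
#' marked; otherwise increases are marked at the earlier day and decreases
#' at the later day, so the high-frequency phase spans both change days.
#' Ambiguous overlaps are resolved greedily by smallest day gap (logged).
#' Unpaired change-points become single-series transitions at their own
#' day.
#'
#' @param cp_a,cp_b `level_detection` objects or change-point tibbles with
#'   columns `day`, `series`, `delta`, `direction`.
#' @param proximity Maximum day gap for pairing (default 14).
#' @param dominance_ratio Delta ratio at or above which one change
#'   dominates (default 2).
#' @return A tibble with one row per transition: `marked_day`,
#'   `direction`, `series`, `day_1`, `delta_1`, `series_1`, `day_2`,
#'   `delta_2`, `series_2`, `dominant`, `gap`. Pairing notes in
#'   `attr(, "log")`.
#' @export
pair_changepoints <- function(cp_a, cp_b, proximity = 14, dominance_ratio = 2) {
  as_cp <- function(x) {
    if (inherits(x, "level_detection")) x$changepoints else as_tibble(x)
  }
  a <- as_cp(cp_a)
  b <- as_cp(cp_b)
  log <- character(0)

  pairs <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  if (nrow(pairs)) {
    pairs$gap <- abs(a$day[pairs$i] - b$day[pairs$j])
    pairs <- pairs[a$direction[pairs$i] == b$direction[pairs$j] &
                     pairs$gap <= proximity, , drop = FALSE]
    pairs <- pairs[order(pairs$gap, pmin(a$day[pairs$i], b$day[pairs$j])), ,
                   drop = FALSE]
  }
  used_a <- rep(FALSE, nrow(a))
  used_b <- rep(FALSE, nrow(b))
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (used_a[i] || used_b[j]) {
      log <- c(log, sprintf(
        "pair (%s day %d, %s day %d) skipped: a member already paired at a smaller gap",
        a$series[i], a$day[i], b$series[j], b$day[j]))
      next
    }
    used_a[i] <- TRUE
    used_b[j] <- TRUE
    p <- a[i, ]; q <- b[j, ]
    dominant <- NA_character_
    if (abs(p$delta) >= dominance_ratio * abs(q$delta)) {
      marked <- p$day; dominant <- p$series
    } else if (abs(q$delta) >= dominance_ratio * abs(p$delta)) {
      marked <- q$day; dominant <- q$series
    } else if (p$direction == "increase") {
      marked <- min(p$day, q$day)
    } else {
      marked <- max(p$day, q$day)
    }
    rows[[length(rows) + 1]] <- tibble(
      marked_day = as.integer(marked), direction = p$direction,
      series = paste(sort(c(p$series, q$series)), collapse = "+"),
      day_1 = p$day, delta_1 = p$delta, series_1 = p$series,
      day_2 = q$day, delta_2 = q$delta, series_2 = q$series,
      dominant = dominant, gap = abs(p$day - q$day)
    )
  }
  singles <- bind_rows(
    if (any(!used_a)) a[!used_a, , drop = FALSE],
    if (any(!used_b)) b[!used_b, , drop = FALSE]
  )
  for (r in seq_len(nrow(singles))) {
    p <- singles[r, ]
    rows[[length(rows) + 1]] <- tibble(
      marked_day = as.integer(p$day), direction = p$direction,
      series = p$series,
      day_1 = p$day, delta_1 = p$delta, series_1 = p$series,
      day_2 = NA_integer_, delta_2 = NA_real_, series_2 = NA_character_,
      dominant = NA_character_, gap = NA_integer_
    )
  }
  out <- if (length(rows)) {
    out <- bind_rows(rows)
    out[order(out$marked_day), , drop = FALSE]
  } else {
    tibble(marked_day = integer(0), direction = character(0),
           series = character(0), day_1 = integer(0), delta_1 = numeric(0),
           series_1 = character(0), day_2 = integer(0), delta_2 = numeric(0),
           series_2 = character(0), dominant = character(0), gap = integer(0))
  }
  attr(out, "log") <- log
  out
}

#' Build the phase segmentation from marked transitions
#'
#' Transitions partition the timeline into phases. A change-point day (as
#' reported by [detect_levels()]) is the first day of the new segment, so
#' every marked transition day opens a new phase directly: for paired
#' decreases the marking policy already chose the later day, letting the
#' high-frequency phase span both change days. Phase means are incident
#' proportions over observed days.
#'
#' @param diary An [ema_diary()].
#' @param transitions Output of [pair_changepoints()] (may have 0 rows).
#' @return A tibble of class `ema_segmentation`: `phase`, `start`, `end`,
#'   `n_days`, `n_completed`, `aggression_mean`, `self_injury_mean`, and
#'   `transition_day` (the Table-2-style transition point opening the
#'   phase; NA for phase 1).
#' @export
build_segmentation <- function(diary, transitions) {
  n <- nrow(diary)
  tday <- integer(0)
  if (nrow(transitions)) {
    tday <- sort(unique(transitions$marked_day[transitions$marked_day > 1 &
                                                 transitions$marked_day <= n]))
  }
  starts <- c(1L, tday)
  ends <- c(tday - 1L, n)
  phase_mean <- function(col, i) {
    mean(diary[[col]][starts[i]:ends[i]], na.rm = TRUE)
  }
  seg <- tibble(
    phase = seq_along(starts),
    start = starts,
    end = ends,
    n_days = ends - starts + 1L,
    n_completed = vapply(seq_along(starts), function(i) {
      sum(!is.na(diary$aggression[starts[i]:ends[i]]))
    }, integer(1)),
    aggression_mean = vapply(seq_along(starts), function(i) {
      phase_mean("aggression", i)
    }, numeric(1)),
    self_injury_mean = vapply(seq_along(starts), function(i) {
      phase_mean("self_injury", i)
    }, numeric(1)),
    transition_day = c(NA_integer_, tday)
  )
  class(seg) <- unique(c("ema_segmentation", class(seg)))
  seg
}

#' Label phase means as low / average / high
#'
#' A phase mean is `"high"` when it exceeds the mean of the phase means by
#' more than one standard deviation (sample SD, n-1 denominator), `"low"`
#' when it falls more than one SD below, and `"average"` otherwise.
#' Identical phase means (zero SD) are all `"average"`.
#'
#' @param means Numeric vector of phase means for one behavior.
#' @return Character vector of labels.
#' @export
label_levels <- function(means) {
  m <- mean(means)
  s <- stats::sd(means)
  if (!is.finite(s) || s == 0) return(rep("average", length(means)))
  ifelse(means > m + s, "high", ifelse(means < m - s, "low", "average"))
}

#' Label the attractor state of each phase
#'
#' Applies [label_levels()] per behavior and combines the two labels into
#' an attractor-state tag; the distinct observed (aggression, self-injury)
#' label pairs are the case's attractor states.
#'
#' @param segmentation An `ema_segmentation` from [build_segmentation()].
#' @return The segmentation with `aggression_label`, `self_injury_label`
#'   and `state` columns added.
#' @export
label_attractors <- function(segmentation) {
  seg <- segmentation
  seg$aggression_label <- label_levels(seg$aggression_mean)
  seg$self_injury_label <- label_levels(seg$self_injury_mean)
  seg$state <- paste0("agg:", seg$aggression_label,
                      "/si:", seg$self_injury_label)
  seg
}

#' Per-phase salience of risk- and protective factors
#'
#' A factor is salient in a phase when its phase-mean frequency deviates
#' by more than one SD from the factor's full-timeline mean, where the SD
#' is taken across the factor's phase means (sample SD, n-1 denominator)
#' -- the same spread measure the attractor-labeling rule uses. For a
#' binary daily series the raw daily SD is of order sqrt(p(1-p)) and
#' would leave rare factors unable to ever be salient, so the phase-level
#' spread is the operative one. Deviations upward are tagged `"often"`,
#' downward `"few"`. A constant factor series is never salient.
#'
#' @param segmentation An `ema_segmentation`.
#' @param themes A [theme_matrix()] over the full timeline.
#' @return A tibble: `phase`, `factor`, `phase_mean`, `overall_mean`,
#'   `phase_sd`, `salient`, `direction`.
#' @export
salience_summary <- function(segmentation, themes) {
  facs <- setdiff(names(themes), c("day"))
  rows <- lapply(facs, function(f) {
    x <- themes[[f]]
    mu <- mean(x)
    pm <- vapply(seq_len(nrow(segmentation)), function(i) {
      mean(x[segmentation$start[i]:segmentation$end[i]])
    }, numeric(1))
    s <- stats::sd(pm)
    if (!is.finite(s)) s <- 0
    salient <- s > 0 & (pm > mu + s | pm < mu - s)
    tibble(
      phase = segmentation$phase, factor = f, phase_mean = pm,
      overall_mean = mu, phase_sd = s, salient = salient,
      direction = ifelse(!salient, NA_character_,
                         ifelse(pm > mu, "often", "few"))
    )
  })
  bind_rows(rows)
}
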