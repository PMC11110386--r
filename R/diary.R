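# Data model and CSV I/O for the day-level diary, the day x factor theme
# matrix, and the extraordinary-event log.

#' Canonical diary column sets
#'
#' The diary instrument has two yes/no behavior items and seven six-point
#' (0-5) slider items, all self-reported once per day.
#'
#' @name diary-columns
#' @keywords internal
NULL

diary_items <- function() {
  c("happy", "scared", "sad", "angry",
    "urge_selfinjury", "death_thoughts", "urge_aggression")
}

diary_behaviors <- function() {
  c("aggression", "self_injury")
}

diary_selfreport_cols <- function() c(diary_behaviors(), diary_items())

#' Default risk- and protective factor set
#'
#' The 11 staff-hypothesized risk- and protective factors used throughout
#' the pipeline.
#'
#' @return Character vector of 11 factor names.
#' @export
default_factors <- function() {
  c("reliving_trauma", "hallucinating", "negative_affect", "medical_care",
    "compliments", "freedom_restricting_measures", "pain", "sickness",
    "psychological_therapy", "familial_tensions", "positive_interactions")
}

validate_diary <- function(df) {
  problems <- character(0)
  line <- function(i) i + 1L  # header occupies line 1 in the CSV
  need <- c("day", diary_selfreport_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    return(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  day <- df$day
  if (anyNA(day) || !all(day == round(day))) {
    problems <- c(problems, "column 'day' must be complete integers")
  } else if (length(day) && !identical(as.integer(day), seq_len(nrow(df)))) {
    bad <- which(as.integer(day) != seq_len(nrow(df)))
    problems <- c(problems, sprintf(
      "day indices must be contiguous 1..N; first violation at line %d", line(bad[1])))
  }
  for (col in diary_behaviors()) {
    v <- df[[col]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad)) problems <- c(problems, sprintf(
      "column '%s' must be 0/1/blank; bad value at line(s) %s",
      col, paste(line(bad), collapse = ", ")))
  }
  for (col in diary_items()) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 5))
    if (length(bad)) problems <- c(problems, sprintf(
      "column '%s' must lie in [0,5]; bad value at line(s) %s",
      col, paste(line(bad), collapse = ", ")))
  }
  # diary entries are all-or-none per day on the self-report side
  sr <- as.matrix(df[diary_selfreport_cols()])
  n_na <- rowSums(is.na(sr))
  partial <- which(n_na > 0 & n_na < ncol(sr))
  if (length(partial)) problems <- c(problems, sprintf(
    "days must be fully observed or fully missing; partial line(s) %s",
    paste(line(partial), collapse = ", ")))
  problems
}

#' Construct a day-level EMA diary
#'
#' A diary is a tibble with one row per calendar day: a `day` index
#' (contiguous, starting at 1), optionally a `date`, two binary behavior
#' columns (`aggression`, `self_injury`) and seven ordinal 0-5 items.
#' A day is either fully observed or fully missing on the self-report side.
#'
#' @param data A data frame with the canonical diary columns.
#' @return A tibble of class `ema_diary`.
#' @export
ema_diary <- function(data) {
  df <- as_tibble(data)
  problems <- validate_diary(df)
  if (length(problems)) abort_format(paste(problems, collapse = "\n"))
  df$day <- as.integer(df$day)
  class(df) <- unique(c("ema_diary", class(df)))
  df
}

#' Read / write a diary CSV
#'
#' Blank cells are missing values. Malformed files are rejected with the
#' offending CSV line numbers in the error message. `write_diary_csv()`
#' followed by `read_diary_csv()` is the identity.
#'
#' @param path Path to a CSV file with columns
#'   `day,date,aggression,self_injury,happy,scared,sad,angry,urge_selfinjury,death_thoughts,urge_aggression`
#'   (`date` optional).
#' @return `read_diary_csv()` returns an [ema_diary()] tibble.
#' @export
read_diary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  ema_diary(df)
}

#' @rdname read_diary_csv
#' @param diary An [ema_diary()] object.
#' @export
write_diary_csv <- function(diary, path) {
  utils::write.csv(as.data.frame(diary), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a day x factor theme matrix
#'
#' Binary day-level codes for the hypothesized risk- and protective
#' factors, derived from coded care records; one row per day, factors are
#' assumed observed (coded present/absent) every day.
#'
#' @param data Data frame with a `day` column plus one 0/1 column per factor.
#' @return A tibble of class `theme_matrix`.
#' @export
theme_matrix <- function(data) {
  df <- as_tibble(data)
  if (!"day" %in% names(df)) abort_format("theme matrix needs a 'day' column")
  facs <- setdiff(names(df), "day")
  if (!length(facs)) abort_format("theme matrix needs at least one factor column")
  if (anyDuplicated(facs)) abort_format("factor names must be unique")
  if (!identical(as.integer(df$day), seq_len(nrow(df)))) {
    abort_format("theme matrix day indices must be contiguous 1..N")
  }
  for (f in facs) {
    if (anyNA(df[[f]]) || !all(df[[f]] %in% c(0, 1))) {
      abort_format(sprintf("factor '%s' must be binary 0/1 with no blanks", f))
    }
  }
  df$day <- as.integer(df$day)
  class(df) <- unique(c("theme_matrix", class(df)))
  df
}

#' @rdname theme_matrix
#' @param path Path to a CSV with a `day` column plus one binary column per factor.
#' @export
read_theme_csv <- function(path) {
  theme_matrix(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname theme_matrix
#' @param themes A `theme_matrix` object.
#' @export
write_theme_csv <- function(themes, path) {
  utils::write.csv(as.data.frame(themes), path, row.names = FALSE)
  invisible(path)
}

#' Construct an extraordinary-event log
#'
#' Dated extraordinary events (positive or negative valence) identified
#' from the care records.
#'
#' @param data Data frame with columns `day`, `valence`
#'   (`"positive"`/`"negative"`) and `label`.
#' @param n_days Optional timeline length to validate days against.
#' @return A tibble of class `event_log`.
#' @export
event_log <- function(data, n_days = NULL) {
  df <- as_tibble(data)
  need <- c("day", "valence", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_format(sprintf(
    "event log missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(df) && !all(df$valence %in% c("positive", "negative"))) {
    abort_format("event valence must be 'positive' or 'negative'")
  }
  if (!is.null(n_days) && nrow(df) && any(df$day < 1 | df$day > n_days)) {
    abort_format("event days must lie within the timeline")
  }
  df$day <- as.integer(df$day)
  class(df) <- unique(c("event_log", class(df)))
  df
}

#' @rdname event_log
#' @param path Path to a CSV with columns `day,valence,label`.
#' @export
read_event_csv <- function(path, n_days = NULL) {
  event_log(utils::read.csv(path, stringsAsFactors = FALSE), n_days = n_days)
}

#' @rdname event_log
#' @param events An `event_log` object.
#' @export
write_event_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Diary completion and incident summary
#'
#' Counts completed diary days and, per behavior, the number and percentage
#' of incident days. Behavior percentages use completed diary days as the
#' denominator (an incident can only be self-reported on a completed day);
#' all percentages are rounded to the nearest integer.
#'
#' @param diary An [ema_diary()] object.
#' @return A list with `n_days`, `n_completed`, `pct_completed` and a
#'   `behaviors` tibble (`behavior`, `n_incident`, `pct_incident`).
#' @export
completion_summary <- function(diary) {
  n_days <- nrow(diary)
  completed <- !is.na(diary$aggression)  # days are all-or-none missing
  n_completed <- sum(completed)
  if (n_completed == 0) {
    warning("no completed diary days; percentages are undefined")
  }
  behaviors <- tibble(
    behavior = diary_behaviors(),
    n_incident = vapply(diary_behaviors(),
                        function(b) sum(diary[[b]] == 1, na.rm = TRUE), integer(1)),
    pct_incident = NA_real_
  )
  behaviors$pct_incident <- round_pct(behaviors$n_incident, n_completed)
  list(
    n_days = n_days,
    n_completed = n_completed,
    pct_completed = round_pct(n_completed, n_days),
    behaviors = behaviors
  )
}

#' Self/informant agreement test for a binary behavior
#'
#' Pearson chi-square test with Yates continuity correction on the 2x2
#' cross-classification of daily self-ratings against informant (records)
#' ratings of the same behavior. Days with a missing rating on either side
#' are excluded pairwise.
#'
#' @param self_series,informant_series Binary 0/1 vectors (NA allowed).
#' @return A list with `chi2`, `p`, `n` and the 2x2 `table`
#'   (self x informant).
#' @export
agreement_chi2 <- function(self_series, informant_series) {
  if (length(self_series) != length(informant_series)) {
    abort_format("series must have equal length")
  }
  keep <- !is.na(self_series) & !is.na(informant_series)
  tab <- table(
    self = factor(self_series[keep], levels = c(1, 0)),
    informant = factor(informant_series[keep], levels = c(1, 0))
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort_format("degenerate margin (a rating never varies); no test performed")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, n = sum(keep), table = tab)
}
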