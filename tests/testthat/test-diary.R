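make_small_diary <- function() {
  ema_diary(tibble::tibble(
    day = 1:3, aggression = c(0, 1, NA), self_injury = c(1, 0, NA),
    happy = c(3, 2, NA), scared = c(1, 1, NA), sad = c(2, 0, NA),
    angry = c(0, 1, NA), urge_selfinjury = c(4, 0, NA),
    death_thoughts = c(0, 0, NA), urge_aggression = c(1, 3, NA)
  ))
}

test_that("diary CSV round-trips to identity, including missing days", {
  path <- withr::local_tempfile(fileext = ".csv")
  small <- make_small_diary()
  write_diary_csv(small, path)
  expect_equal(as.data.frame(read_diary_csv(path)), as.data.frame(small))

  case <- generate_case(generator_config(seed = 21L))
  write_diary_csv(case$diary, path)
  back <- read_diary_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(case$diary))
})

test_that("malformed diary files are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(make_small_diary())
  df$happy[2] <- 7  # line 3 of the CSV
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_diary_csv(path), "line(s) 3", fixed = TRUE)

  df <- as.data.frame(make_small_diary())
  df$day <- c(1, 3, 4)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_diary_csv(path), "contiguous")

  df <- as.data.frame(make_small_diary())
  df$urge_selfinjury[1] <- NA  # partial day
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_diary_csv(path), "fully observed or fully missing")
})

test_that("completion summary reproduces the reported percentage arithmetic", {
  n <- 560
  completed <- 494
  diary <- ema_diary(tibble::tibble(
    day = 1:n,
    aggression = c(rep(1, 65), rep(0, completed - 65), rep(NA, n - completed)),
    self_injury = c(rep(1, 247), rep(0, completed - 247), rep(NA, n - completed)),
    happy = c(rep(3, completed), rep(NA, n - completed)),
    scared = c(rep(1, completed), rep(NA, n - completed)),
    sad = c(rep(1, completed), rep(NA, n - completed)),
    angry = c(rep(1, completed), rep(NA, n - completed)),
    urge_selfinjury = c(rep(1, completed), rep(NA, n - completed)),
    death_thoughts = c(rep(1, completed), rep(NA, n - completed)),
    urge_aggression = c(rep(1, completed), rep(NA, n - completed))
  ))
  s <- completion_summary(diary)
  expect_equal(s$n_completed, 494)
  expect_equal(s$pct_completed, 88)
  expect_equal(s$behaviors$pct_incident,
               c(13, 50))  # 65/494 and 247/494, completed-day denominator

  # invariant to row order (summary uses counts, not positions)
  shuffled <- diary[sample(n), ]
  shuffled$day <- 1:n
  s2 <- completion_summary(ema_diary(shuffled))
  expect_equal(s2$behaviors$n_incident, s$behaviors$n_incident)
  expect_equal(s2$pct_completed, s$pct_completed)

  empty <- apply_missingness(diary, 1, seed = 1)
  expect_warning(s3 <- completion_summary(empty), "undefined")
  expect_equal(s3$pct_completed, 0)
  expect_true(all(is.na(s3$behaviors$pct_incident)))
})

test_that("self/informant agreement chi-square matches the Yates closed form", {
  sr <- series_from_table(40, 10, 5, 45)
  res <- agreement_chi2(sr$self, sr$informant)
  expect_equal(res$chi2, oracle_yates_chi2(40, 10, 5, 45), tolerance = 1e-10)
  expect_equal(res$chi2, 46.707, tolerance = 1e-3)

  # independence: continuity-corrected statistic collapses to 0, p = 1
  sr <- series_from_table(25, 25, 25, 25)
  res <- agreement_chi2(sr$self, sr$informant)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  # perfect agreement on a diagonal table
  sr <- series_from_table(30, 0, 0, 30)
  expect_lt(agreement_chi2(sr$self, sr$informant)$p, 0.001)

  # symmetric in argument order (table transposes)
  sr <- series_from_table(12, 7, 3, 20)
  r1 <- agreement_chi2(sr$self, sr$informant)
  r2 <- agreement_chi2(sr$informant, sr$self)
  expect_equal(r1$chi2, r2$chi2)
  expect_equal(r1$p, r2$p)

  # degenerate margin: no test
  expect_error(agreement_chi2(rep(0, 20), rep(c(0, 1), 10)),
               class = "emaphase_format_error")

  # missing self-ratings excluded pairwise
  sr <- series_from_table(10, 5, 5, 10)
  self_na <- c(sr$self, NA, NA)
  inf_pad <- c(sr$informant, 1, 0)
  expect_equal(agreement_chi2(self_na, inf_pad)$n, 30)
})

test_that("theme and event CSVs validate and round-trip", {
  case <- generate_case(generator_config(n_days = 60L, phases = tibble::tibble(
    start = 1L, p_aggression = 0.2, p_selfinjury = 0.4),
    instability_windows = default_instability_windows()[0, ],
    event_days = tibble::tibble(day = c(10L, 40L),
                                valence = c("positive", "negative"),
                                label = c("a", "b")), seed = 8L))
  tdir <- withr::local_tempdir()
  paths <- write_case_csv(case, tdir)
  expect_equal(as.data.frame(read_theme_csv(paths[["themes"]])),
               as.data.frame(case$themes))
  expect_equal(as.data.frame(read_event_csv(paths[["events"]])),
               as.data.frame(case$events))
  expect_error(event_log(tibble::tibble(day = 1, valence = "meh", label = "x")),
               class = "emaphase_format_error")
  expect_error(theme_matrix(tibble::tibble(day = 1:2, f = c(0, 2))),
               class = "emaphase_format_error")
})
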