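test_that("level detection handles degenerate and textbook step inputs", {
  flat <- detect_levels(rep(0, 100))
  expect_equal(nrow(flat$segments), 1)
  expect_equal(flat$segments$mean, 0)
  expect_equal(nrow(flat$changepoints), 0)

  step <- detect_levels(c(rep(0, 40), rep(1, 40)))
  expect_equal(step$changepoints$day, 41)
  expect_equal(step$segments$mean, c(0, 1))
  expect_equal(step$changepoints$direction, "increase")

  # a single incident in the second half moves the child mean only 0.025:
  # below the 25-point change criterion, so no split survives
  weak <- detect_levels(c(rep(0, 40), rep(0, 39), 1))
  expect_equal(nrow(weak$changepoints), 0)

  short <- detect_levels(rep(c(0, 1), 6), min_len = 7)
  expect_equal(nrow(short$segments), 1)
})

test_that("level detection equals exhaustive split search on random series", {
  set.seed(515)
  for (rep_i in 1:40) {
    n <- sample(20:60, 1)
    k <- sample(1:3, 1)
    starts <- sort(sample(2:(n - 1), k))
    p <- runif(k + 1)
    idx <- findInterval(seq_len(n), c(1, starts))
    x <- rbinom(n, 1, p[idx])
    if (rep_i %% 4 == 0) x[sample(n, ceiling(n * 0.1))] <- NA
    ld <- detect_levels(x, min_len = 5, min_change = 0.2)
    expect_equal(ld$changepoints$day,
                 oracle_detect_levels(x, min_len = 5, min_change = 0.2))
  }
})

test_that("segment means reproduce incident proportions and recompose the series mean", {
  set.seed(99)
  x <- rbinom(200, 1, rep(c(0.1, 0.7), each = 100))
  x[sample(200, 24)] <- NA
  ld <- detect_levels(x)
  for (i in seq_len(nrow(ld$segments))) {
    span <- ld$segments$start[i]:ld$segments$end[i]
    expect_equal(ld$segments$mean[i], mean(x[span], na.rm = TRUE))
    expect_equal(ld$segments$n_obs[i], sum(!is.na(x[span])))
  }
  expect_equal(sum(ld$segments$mean * ld$segments$n_obs) / sum(ld$segments$n_obs),
               mean(x, na.rm = TRUE))
})

test_that("suppression rules drop data-poor and context-redundant change-points", {
  # rule (b): the week after the split is mostly missing
  x <- c(rep(0, 40), rep(1, 40))
  x[41:46] <- NA  # 6 of the 7 following days missing
  ld <- detect_levels(x)
  if (nrow(ld$changepoints)) {
    out <- suppress_changepoints(ld, x)
    expect_equal(nrow(out$changepoints), 0)
    expect_match(attr(out, "log"), "missing", all = FALSE)
  }

  # rule (a): a middle segment whose level matches its merged surroundings
  # survives only on the raw split, not after suppression
  y <- c(rep(0, 30), rep(c(1, 0), 15), rep(0.45, 0), rep(1, 30))
  ld2 <- detect_levels(y, min_len = 7, min_change = 0.25)
  out2 <- suppress_changepoints(ld2, y)
  # whatever remains, every surviving middle segment differs from its
  # merged surroundings by at least min_change
  seg <- out2$segments
  if (nrow(seg) > 2) {
    for (j in 2:(nrow(seg) - 1)) {
      mB <- mean(y[seg$start[j]:seg$end[j]], na.rm = TRUE)
      mR <- mean(y[c(seg$start[j - 1]:seg$end[j - 1],
                     seg$start[j + 1]:seg$end[j + 1])], na.rm = TRUE)
      expect_gte(abs(mB - mR), 0.25)
    }
  }
  expect_true(nrow(out2$segments) <= nrow(ld2$segments))
})

test_that("attractor labels follow the phase-means +/- 1 SD rule", {
  printed <- c(8, 30, 0, 6, 41, 11, 3, 26, 6, 13, 13)  # aggression phase means, %
  labels <- label_levels(printed)
  expect_equal(labels[printed == 41], "high")
  expect_equal(labels[printed == 30], "high")
  expect_equal(labels[printed == 0], "low")
  expect_equal(labels[printed == 3], "average")
  expect_equal(labels[printed == 26], "average")

  expect_equal(label_levels(rep(0.3, 5)), rep("average", 5))
  # with two phases the deviation equals the SD exactly, never exceeds it
  expect_equal(label_levels(c(0.1, 0.9)), c("average", "average"))
})

test_that("salience compares phase means to the full-timeline mean +/- 1 SD of phase means", {
  n <- 150
  # factor frequent in phase 1 (0.6), rare afterwards (0.04, 0.06)
  hot <- c(rep(c(1, 1, 1, 0, 0), 10), rep(0, 48), 1, 1, rep(0, 47), 1, 1, 1)
  # factor common in phases 1-2 (0.9), dropping away in phase 3 (0.2)
  cold <- c(rep(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0), 10), rep(c(1, 0, 0, 0, 0), 10))
  themes <- theme_matrix(tibble::tibble(day = 1:n, f_hot = hot,
                                        f_cold = cold, f_flat = rep(0L, n)))
  diary <- ema_diary(tibble::tibble(
    day = 1:n, aggression = 0L, self_injury = 0L, happy = 3L, scared = 1L,
    sad = 1L, angry = 1L, urge_selfinjury = 1L, death_thoughts = 0L,
    urge_aggression = 1L))
  seg <- build_segmentation(
    diary,
    tibble::tibble(marked_day = c(51L, 101L),
                   direction = c("increase", "increase")))
  sal <- salience_summary(seg, themes)
  h <- sal[sal$factor == "f_hot", ]
  # phase means 0.6 / 0.04 / 0.06, overall 0.2333, sd(phase means) 0.3177
  expect_equal(h$phase_mean, c(0.6, 0.04, 0.06))
  expect_equal(h$salient, c(TRUE, FALSE, FALSE))
  expect_equal(h$direction[1], "often")
  co <- sal[sal$factor == "f_cold", ]
  # phase means 0.9 / 0.9 / 0.2, overall 0.667: only the drop is salient
  expect_equal(co$salient, c(FALSE, FALSE, TRUE))
  expect_equal(co$direction[3], "few")
  expect_false(any(sal[sal$factor == "f_flat", ]$salient))
})
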