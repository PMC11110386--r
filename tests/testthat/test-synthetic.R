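test_that("degenerate incident probabilities produce degenerate series", {
  cfg <- generator_config(
    n_days = 100L,
    phases = tibble::tibble(start = 1L, p_aggression = 0, p_selfinjury = 0.5),
    instability_windows = tibble::tibble(start = integer(0), end = integer(0),
                                         noise_multiplier = numeric(0),
                                         alternation_prob = numeric(0)),
    event_days = tibble::tibble(day = integer(0), valence = character(0),
                                label = character(0)),
    missing_rate = 0, seed = 11L
  )
  case <- generate_case(cfg)
  expect_equal(nrow(case$diary), 100L)
  expect_true(all(case$diary$aggression == 0))
  expect_false(anyNA(case$diary))
  expect_length(case$truth$transition_days, 0)
})

test_that("generation is deterministic under a fixed seed and leaves the RNG alone", {
  before <- runif(1)
  set.seed(99)
  expected_next <- runif(1)
  set.seed(99)
  c1 <- generate_case(generator_config(n_days = 60L, phases = tibble::tibble(
    start = 1L, p_aggression = 0.2, p_selfinjury = 0.4), seed = 5L,
    instability_windows = default_instability_windows()[0, ],
    event_days = default_event_days()[0, ]))
  after <- runif(1)
  c2 <- generate_case(generator_config(n_days = 60L, phases = tibble::tibble(
    start = 1L, p_aggression = 0.2, p_selfinjury = 0.4), seed = 5L,
    instability_windows = default_instability_windows()[0, ],
    event_days = default_event_days()[0, ]))
  expect_identical(c1$diary, c2$diary)
  expect_identical(c1$themes, c2$themes)
  expect_equal(after, expected_next)  # caller's RNG stream restored
})

test_that("per-phase incident proportions match the configured probabilities", {
  p <- c(0.1, 0.8)
  props <- vapply(1:500, function(s) {
    cfg <- generator_config(
      n_days = 400L,
      phases = tibble::tibble(start = c(1L, 201L), p_aggression = 0.1,
                              p_selfinjury = p),
      instability_windows = default_instability_windows()[0, ],
      event_days = default_event_days()[0, ],
      missing_rate = 0, seed = s
    )
    d <- generate_case(cfg)$diary
    c(mean(d$self_injury[1:200]), mean(d$self_injury[201:400]))
  }, numeric(2))
  grand <- rowMeans(props)
  se3 <- 3 * sqrt(p * (1 - p) / (500 * 200))
  expect_true(all(abs(grand - p) < se3))
})

test_that("missingness is day-level, all-or-none, and binomially calibrated", {
  cfg0 <- generator_config(n_days = 80L, phases = tibble::tibble(
    start = 1L, p_aggression = 0.2, p_selfinjury = 0.4),
    instability_windows = default_instability_windows()[0, ],
    event_days = default_event_days()[0, ], missing_rate = 0, seed = 3L)
  diary <- generate_case(cfg0)$diary
  expect_identical(apply_missingness(diary, 0, seed = 1), diary)
  all_masked <- apply_missingness(diary, 1, seed = 1)
  expect_true(all(is.na(all_masked$aggression)))
  expect_true(all(is.na(all_masked$happy)))

  counts <- vapply(1:500, function(s) {
    masked <- apply_missingness(diary, 0.12, seed = s)
    # all-or-none per day
    sr <- as.matrix(masked[, c("aggression", "self_injury", "happy")])
    stopifnot(all(rowSums(is.na(sr)) %in% c(0, 3)))
    sum(is.na(masked$aggression))
  }, numeric(1))
  n <- 80
  expect_lt(abs(mean(counts) - n * 0.12), 3 * sqrt(n * 0.12 * 0.88))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(phases = tibble::tibble(
    start = 2L, p_aggression = 0.1, p_selfinjury = 0.1)),
    class = "emaphase_config_error")
  expect_error(generator_config(phases = tibble::tibble(
    start = c(1L, 5L), p_aggression = 0.1, p_selfinjury = 0.1)),
    class = "emaphase_config_error")  # phase shorter than 7 days
  expect_error(generator_config(phases = tibble::tibble(
    start = 1L, p_aggression = 1.2, p_selfinjury = 0.1)),
    class = "emaphase_config_error")
  expect_error(generator_config(missing_rate = -0.1),
               class = "emaphase_config_error")
  expect_error(generator_config(instability_windows = tibble::tibble(
    start = 10L, end = 1000L, noise_multiplier = 2, alternation_prob = 0.5)),
    class = "emaphase_config_error")
})

test_that("planted destabilization windows are flagged; quiet stretches mostly are not", {
  hits <- logical(60)
  false_rates <- numeric(60)
  for (i in seq_len(60)) {
    case <- generate_case(recovery_config(3000 + i))
    flagged <- unlist(lapply(c("urge_aggression", "urge_selfinjury"),
                             function(it) {
      imp <- impute_local_level(case$diary[[it]])
      tr <- flag_instability(dynamic_complexity(imp, item_name = it))
      tr$day[tr$flagged]
    }))
    hits[i] <- any(flagged >= 160 & flagged <= 171)
    outside <- flagged[flagged < 150 | flagged > 185]
    false_rates[i] <- length(unique(outside)) / (224 - 7 + 1)
  }
  expect_gte(mean(hits), 0.8)
  # the self-referential threshold keeps the outside-window flag rate at or
  # below the nominal one-tailed mass
  expect_lte(mean(false_rates), 0.05)
})
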