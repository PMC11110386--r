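# Synthetic single-case generator. Emits a diary, theme matrix and event
# log with the same statistical structure the pipeline assumes, plus the
# ground truth (transition days, instability windows, event days) needed
# to validate every downstream stage.

default_phases <- function() {
  # piecewise-constant incident probabilities; the default timeline mirrors
  # the 11 observed phases of the motivating case (560 days)
  tibble(
    start        = c(1L, 57L, 92L, 147L, 234L, 286L, 413L, 446L, 467L, 484L, 500L),
    p_aggression = c(.08, .30, .00, .06, .41, .11, .03, .26, .06, .13, .13),
    p_selfinjury = c(.30, .87, .78, .43, .80, .50, .06, .58, .13, .67, .21)
  )
}

default_item_params <- function() {
  # latent-Gaussian item model: baseline level, additive lift on days the
  # driving behavior occurs, and noise SD, all on the 0-5 scale
  tibble(
    item = diary_items(),
    baseline      = c(3.2, 1.4, 1.8, 1.2, 1.3, 0.8, 0.9),
    behavior_lift = c(-1.0, 0.8, 1.0, 1.5, 2.0, 1.0, 2.0),
    noise_sd      = rep(0.9, 7),
    driver = c("any", "any", "any", "aggression",
               "self_injury", "self_injury", "aggression")
  )
}

default_instability_windows <- function() {
  # destabilization episodes around the transitions that showed significant
  # instability, plus one unstable week without a transition
  t_inst <- c(57L, 92L, 413L, 446L, 467L, 484L)
  tibble(
    start = c(t_inst - 8L, 360L),
    end = c(t_inst + 2L, 368L),
    noise_multiplier = 2,
    alternation_prob = 0.5
  )
}

default_event_days <- function() {
  # extraordinary events in the week prior to event-linked transitions
  # (placed 3 days before the transition point) plus two events that were
  # not followed by a transition
  tibble(
    day = c(54L, 218L, 410L, 464L, 481L, 483L, 497L, 350L, 367L),
    valence = c("negative", "negative", "positive", "positive", "negative",
                "positive", "negative", "positive", "negative"),
    label = c("fear for an escapee", "first covid lockdown", "finishes tattoo",
              "starts relationship", "ends relationship", "release of own cd",
              "traumatic experience", "starts tattoo", "fight in the family")
  )
}

default_theme_rates <- function() {
  stats::setNames(
    c(0.06, 0.04, 0.35, 0.20, 0.15, 0.15, 0.15, 0.08, 0.12, 0.05, 0.30),
    default_factors()
  )
}

#' Configuration for the synthetic single-case generator
#'
#' The defaults emulate the motivating case: a 560-day timeline with the
#' 11 observed phases as piecewise-constant incident probabilities, ~12%
#' day-level MCAR missingness, behavior-coupled 0-5 items, planted
#' destabilization windows around instability-linked transitions, and an
#' extraordinary-event log.
#'
#' @param n_days Timeline length in days.
#' @param phases Tibble with `start` (strictly increasing, first = 1, each
#'   phase at least 7 days), `p_aggression`, `p_selfinjury` in `[0,1]`.
#' @param items Tibble with per-item `baseline`, `behavior_lift`,
#'   `noise_sd` (all on the 0-5 scale) and `driver`
#'   (`"aggression"`, `"self_injury"` or `"any"`).
#' @param instability_windows Tibble with `start`, `end`,
#'   `noise_multiplier` (>= 1) and `alternation_prob` in `[0,1]`.
#' @param event_days Tibble with `day`, `valence`, `label`.
#' @param theme_base_rates Named vector of Bernoulli day rates per factor.
#' @param missing_rate Day-level MCAR missingness probability.
#' @param start_date Calendar date of day 1.
#' @param seed Integer seed; one seeded generator drives all randomness.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_days = 560L,
                             phases = default_phases(),
                             items = default_item_params(),
                             instability_windows = default_instability_windows(),
                             event_days = default_event_days(),
                             theme_base_rates = default_theme_rates(),
                             missing_rate = 0.12,
                             start_date = as.Date("2019-07-01"),
                             seed = 1L) {
  cfg <- list(
    n_days = as.integer(n_days), phases = as_tibble(phases),
    items = as_tibble(items), instability_windows = as_tibble(instability_windows),
    event_days = as_tibble(event_days), theme_base_rates = theme_base_rates,
    missing_rate = missing_rate, start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  ph <- cfg$phases
  if (cfg$n_days < 1) abort_config("n_days must be positive")
  if (!nrow(ph) || ph$start[1] != 1) abort_config("first phase must start at day 1")
  if (nrow(ph) > 1 && any(diff(ph$start) <= 0)) {
    abort_config("phase starts must be strictly increasing")
  }
  len <- diff(c(ph$start, cfg$n_days + 1L))
  if (any(len < 7)) abort_config("each phase must be at least 7 days long")
  probs <- c(ph$p_aggression, ph$p_selfinjury, cfg$missing_rate,
             cfg$theme_base_rates)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    abort_config("probabilities must lie in [0, 1]")
  }
  iw <- cfg$instability_windows
  if (nrow(iw)) {
    if (any(iw$start < 1 | iw$end > cfg$n_days | iw$start > iw$end)) {
      abort_config("instability windows must lie within [1, n_days]")
    }
    if (any(iw$noise_multiplier < 1)) abort_config("noise_multiplier must be >= 1")
    if (any(iw$alternation_prob < 0 | iw$alternation_prob > 1)) {
      abort_config("alternation_prob must lie in [0, 1]")
    }
  }
  ev <- cfg$event_days
  if (nrow(ev) && any(ev$day < 1 | ev$day > cfg$n_days)) {
    abort_config("event days must lie within [1, n_days]")
  }
  invisible(cfg)
}

#' Generate a synthetic single case with known ground truth
#'
#' Behaviors are Bernoulli draws from the phase-wise incident
#' probabilities. Each 0-5 item is a clamp-rounded Gaussian latent:
#' baseline + behavior_lift on days its driving behavior occurred + noise
#' whose SD is inflated inside instability windows. Inside instability
#' windows, urge items are additionally replaced (with probability
#' `alternation_prob`) by the extreme opposite to the previous day's value,
#' planting high-fluctuation episodes. Themes are Bernoulli draws at the
#' configured base rates. Day-level MCAR missingness is applied last.
#' Fully deterministic under a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A list of class `ema_case` with elements `diary`
#'   ([ema_diary()]), `themes` ([theme_matrix()]), `events`
#'   ([event_log()]) and `truth` (list with `transition_days`,
#'   `instability_windows`, `event_days`).
#' @export
generate_case <- function(config = generator_config()) {
  cfg <- validate_generator_config(config)
  run_seeded(cfg$seed, function() {
    n <- cfg$n_days
    idx <- findInterval(seq_len(n), cfg$phases$start)
    aggression <- stats::rbinom(n, 1, cfg$phases$p_aggression[idx])
    self_injury <- stats::rbinom(n, 1, cfg$phases$p_selfinjury[idx])

    mult <- rep(1, n)
    alt_p <- rep(0, n)
    iw <- cfg$instability_windows
    for (k in seq_len(nrow(iw))) {
      span <- iw$start[k]:iw$end[k]
      mult[span] <- pmax(mult[span], iw$noise_multiplier[k])
      alt_p[span] <- pmax(alt_p[span], iw$alternation_prob[k])
    }

    items <- matrix(NA_real_, n, nrow(cfg$items),
                    dimnames = list(NULL, cfg$items$item))
    for (k in seq_len(nrow(cfg$items))) {
      par <- cfg$items[k, ]
      driver <- switch(par$driver,
                       aggression = aggression,
                       self_injury = self_injury,
                       any = pmax(aggression, self_injury))
      latent <- par$baseline + par$behavior_lift * driver +
        stats::rnorm(n, 0, par$noise_sd * mult)
      val <- clamp(round(latent), 0, 5)
      if (par$item %in% c("urge_selfinjury", "urge_aggression")) {
        flip <- stats::runif(n) < alt_p
        for (t in which(flip)) {
          prev <- if (t == 1) val[1] else val[t - 1]
          val[t] <- if (prev >= 2.5) 0 else 5
        }
      }
      items[, k] <- val
    }

    diary <- ema_diary(tibble(
      day = seq_len(n),
      date = cfg$start_date + seq_len(n) - 1,
      aggression = aggression,
      self_injury = self_injury,
      as_tibble(items)
    ))
    diary <- apply_missingness(diary, cfg$missing_rate)

    rates <- cfg$theme_base_rates
    themes <- theme_matrix(tibble(
      day = seq_len(n),
      as_tibble(vapply(rates, function(p) stats::rbinom(n, 1, p), integer(n)))
    ))

    events <- event_log(cfg$event_days, n_days = n)

    structure(list(
      diary = diary, themes = themes, events = events,
      truth = list(
        transition_days = cfg$phases$start[-1],
        instability_windows = iw,
        event_days = events
      ),
      config = cfg
    ), class = "ema_case")
  })
}

#' Mask whole diary days at random
#'
#' Each day is independently masked with probability `rate`; masking a day
#' removes all self-report fields of that day (diary entries are
#' all-or-none per day).
#'
#' @param diary An [ema_diary()].
#' @param rate Masking probability in `[0, 1]`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The masked [ema_diary()].
#' @export
apply_missingness <- function(diary, rate, seed = NULL) {
  if (is.na(rate) || rate < 0 || rate > 1) abort_config("rate must lie in [0, 1]")
  mask_fn <- function() stats::runif(nrow(diary)) < rate
  mask <- if (is.null(seed)) mask_fn() else run_seeded(seed, mask_fn)
  diary[mask, diary_selfreport_cols()] <- NA
  diary
}

#' Write the three case CSVs to a directory
#'
#' @param case An `ema_case` from [generate_case()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_case_csv <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    diary = file.path(dir, "diary.csv"),
    themes = file.path(dir, "themes.csv"),
    events = file.path(dir, "events.csv")
  )
  write_diary_csv(case$diary, paths[["diary"]])
  write_theme_csv(case$themes, paths[["themes"]])
  write_event_csv(case$events, paths[["events"]])
  invisible(paths)
}
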