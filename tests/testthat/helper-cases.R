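# Shared synthetic fixtures for the recovery studies. The recovery case
# has four 56-day phases with incident-probability jumps of 0.40-0.55
# (emulating the magnitude of the case's printed changes), 12% day-level
# missingness, one planted extraordinary event 4 days before the second
# transition (event-only ground truth) and one planted destabilization
# window immediately before the third transition (instability-only
# ground truth). The urge items are deliberately uncoupled from the
# behaviors here (lift 0): with coupling, every behavior transition
# induces a true urge-level shift that dynamic complexity correctly
# registers, so an "event-only, no instability" planted label would be
# false by construction. Decoupling makes the planted mechanism labels
# true in the generated data.

recovery_config <- function(seed) {
  items <- default_item_params()
  items$behavior_lift[items$item %in% c("urge_selfinjury", "urge_aggression")] <- 0
  generator_config(
    n_days = 224L,
    phases = tibble::tibble(
      start = c(1L, 57L, 113L, 169L),
      p_aggression = c(0.05, 0.45, 0.05, 0.50),
      p_selfinjury = c(0.10, 0.60, 0.15, 0.65)
    ),
    items = items,
    instability_windows = tibble::tibble(
      start = 160L, end = 168L, noise_multiplier = 3, alternation_prob = 0.7
    ),
    event_days = tibble::tibble(
      day = 53L, valence = "negative", label = "planted event"
    ),
    missing_rate = 0.12,
    seed = seed
  )
}

# Minimal identifiable design for the transition-recovery study: one
# transition at day 57 between two 56-day phases with jumps of 0.45
# (aggression) and 0.55 (self-injury), 12% missing; even-numbered seeds
# plant a decrease instead of an increase so both directions are covered.
transition_config <- function(seed) {
  items <- default_item_params()
  items$behavior_lift[items$item %in% c("urge_selfinjury", "urge_aggression")] <- 1
  p_agg <- c(0.05, 0.50)
  p_si <- c(0.10, 0.65)
  if (seed %% 2 == 0) {
    p_agg <- rev(p_agg)
    p_si <- rev(p_si)
  }
  generator_config(
    n_days = 112L,
    phases = tibble::tibble(start = c(1L, 57L), p_aggression = p_agg,
                            p_selfinjury = p_si),
    items = items,
    instability_windows = default_instability_windows()[0, ],
    event_days = default_event_days()[0, ],
    missing_rate = 0.12,
    seed = seed
  )
}

# Noise-free variant: saturated incident contrasts (phases alternate
# between never and always), for smoke tests that assert exact
# phase-table shape rather than recovery rates.
clean_config <- function(seed) {
  cfg <- recovery_config(seed)
  generator_config(
    n_days = cfg$n_days,
    phases = tibble::tibble(
      start = cfg$phases$start,
      p_aggression = c(0, 1, 0, 1),
      p_selfinjury = c(0, 1, 0, 1)
    ),
    items = cfg$items,
    instability_windows = cfg$instability_windows,
    event_days = cfg$event_days,
    missing_rate = 0.12,
    seed = seed
  )
}

# Detected change-point days (either behavior series) for one case.
recovered_cp_days <- function(case, min_len = 7, min_change = 0.25) {
  unlist(lapply(c("aggression", "self_injury"), function(b) {
    detect_levels(case$diary[[b]], min_len = min_len,
                  min_change = min_change, series_name = b)$changepoints$day
  }))
}
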