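# Transition direction and change-mechanism classification: was a
# transition preceded by an extraordinary event, accompanied by
# significant instability, both, or neither?

#' Direction of each transition
#'
#' A transition is undesirable when the new phase has a higher combined
#' challenging-behavior frequency (sum of the two behaviors' phase means)
#' than the old phase, desirable when lower, and a tie is reported
#' explicitly.
#'
#' @param segmentation An `ema_segmentation` (see [build_segmentation()]).
#' @return A tibble with one row per transition: `transition_day`,
#'   `old_phase`, `new_phase`, `direction`
#'   (`"desirable"`/`"undesirable"`/`"tie"`).
#' @export
transition_direction <- function(segmentation) {
  k <- nrow(segmentation)
  if (k < 2) {
    return(tibble(transition_day = integer(0), old_phase = integer(0),
                  new_phase = integer(0), direction = character(0)))
  }
  load <- segmentation$aggression_mean + segmentation$self_injury_mean
  new <- load[-1]
  old <- load[-k]
  tibble(
    transition_day = segmentation$start[-1],
    old_phase = segmentation$phase[-k],
    new_phase = segmentation$phase[-1],
    direction = ifelse(new > old, "undesirable",
                       ifelse(new < old, "desirable", "tie"))
  )
}

#' Classify the change mechanism of one transition
#'
#' An extraordinary event counts when it falls in the week strictly prior
#' to the transition point (`[t - width, t - 1]`; the transition day
#' itself is excluded so the cause stays precedent). Instability counts
#' when any significantly flagged dynamic-complexity window of either urge
#' item ends in the week before or during the change
#' (`[t - width, t + width]`). The mechanism is the 2x2 truth table:
#' event and instability, event only, instability only, or unknown.
#'
#' @param t_day Transition point (start day of the new phase).
#' @param events An [event_log()].
#' @param flagged_days Integer vector of window-end days flagged as
#'   significantly unstable (union over the urge items' traces).
#' @param width Week length in days (default 7).
#' @param trace_start First day for which dynamic complexity exists
#'   (window width); used to note transitions whose instability window is
#'   only partially covered.
#' @return A list with `mechanism`, `event_present`,
#'   `instability_present`, `event_labels`, `note`.
#' @export
classify_mechanism <- function(t_day, events, flagged_days, width = 7,
                               trace_start = width) {
  ev <- events[events$day >= t_day - width & events$day <= t_day - 1, ,
               drop = FALSE]
  event_present <- nrow(ev) > 0
  instability_present <- any(flagged_days >= t_day - width &
                               flagged_days <= t_day + width)
  note <- if (t_day - width < trace_start) {
    "instability window only partially covered at the start of the timeline"
  } else {
    NA_character_
  }
  mech <- if (event_present && instability_present) {
    "event_and_instability"
  } else if (event_present) {
    "event_induced"
  } else if (instability_present) {
    "instability_induced"
  } else {
    "unknown"
  }
  list(mechanism = mech, event_present = event_present,
       instability_present = instability_present,
       event_labels = paste(ev$label, collapse = "; "), note = note)
}

#' Mechanism table: one row per transition
#'
#' Summarises, for each transition, its direction, the extraordinary
#' events of the week prior, whether instability was flagged the week
#' before or during the change, and the resulting mechanism
#' classification.
#'
#' @param segmentation An `ema_segmentation`.
#' @param events An [event_log()].
#' @param traces A list of flagged `complexity_trace`s (see
#'   [flag_instability()]), one per urge item; their flags are pooled.
#' @param width Week length in days (default 7).
#' @return A tibble: `transition_day`, `direction`, `events`,
#'   `instability`, `mechanism`, `note`.
#' @export
mechanism_table <- function(segmentation, events, traces, width = 7) {
  dirs <- transition_direction(segmentation)
  if (!nrow(dirs)) {
    return(tibble(transition_day = integer(0), direction = character(0),
                  events = character(0), instability = logical(0),
                  mechanism = character(0), note = character(0)))
  }
  if (inherits(traces, "complexity_trace")) traces <- list(traces)
  flagged_days <- sort(unique(unlist(lapply(traces, function(tr) {
    tr$day[tr$flagged]
  }))))
  rows <- lapply(seq_len(nrow(dirs)), function(i) {
    cl <- classify_mechanism(dirs$transition_day[i], events, flagged_days,
                             width = width)
    tibble(
      transition_day = dirs$transition_day[i],
      direction = dirs$direction[i],
      events = if (nzchar(cl$event_labels)) cl$event_labels else "none",
      instability = cl$instability_present,
      mechanism = cl$mechanism,
      note = cl$note
    )
  })
  bind_rows(rows)
}
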