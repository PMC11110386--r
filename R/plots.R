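# Figures: raw binary timelines with missing-day shading and phase
# backgrounds, and dynamic complexity panels with their significance
# thresholds.

phase_rects <- function(segmentation, ymin, ymax) {
  data.frame(
    xmin = segmentation$start - 0.5,
    xmax = segmentation$end + 0.5,
    ymin = ymin, ymax = ymax,
    phase = factor(segmentation$phase %% 2)
  )
}

#' Plot the raw behavior timelines
#'
#' One tile row per behavior: colored cells are incident days, light cells
#' incident-free days, gray cells missing diary days. Phase backgrounds
#' (alternating shading) follow the segmentation; extraordinary events are
#' drawn as markers above the rows.
#'
#' @param diary An [ema_diary()].
#' @param segmentation Optional `ema_segmentation` for phase shading.
#' @param events Optional [event_log()] for event markers.
#' @return A ggplot object.
#' @export
plot_timeline <- function(diary, segmentation = NULL, events = NULL) {
  long <- pivot_longer(diary[, c("day", "aggression", "self_injury")],
                       c("aggression", "self_injury"),
                       names_to = "behavior", values_to = "incident")
  long$status <- ifelse(is.na(long$incident), "missing",
                        ifelse(long$incident == 1, "incident", "none"))
  g <- ggplot(long)
  if (!is.null(segmentation) && nrow(segmentation) > 1) {
    g <- g + geom_rect(
      data = phase_rects(segmentation, -Inf, Inf),
      aes(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax, alpha = phase),
      fill = "steelblue", inherit.aes = FALSE, show.legend = FALSE
    ) + scale_alpha_manual(values = c("0" = 0.05, "1" = 0.15))
  }
  g <- g +
    geom_tile(aes(x = day, y = behavior, fill = status), height = 0.8) +
    scale_fill_manual(values = c(incident = "firebrick",
                                 none = "grey92", missing = "grey55")) +
    labs(x = "day", y = NULL, fill = NULL)
  if (!is.null(events) && nrow(events)) {
    g <- g + geom_point(
      data = as.data.frame(events),
      aes(x = day, y = 2.6, shape = valence), color = "black", size = 2,
      inherit.aes = FALSE
    ) + scale_shape_manual(values = c(positive = 24, negative = 25))
  }
  g + theme_minimal()
}

#' Plot the dynamic complexity traces
#'
#' One panel per item: the windowed dynamic complexity timeline, a
#' horizontal red line at the one-tailed significance threshold, flagged
#' windows as red points, phase shading and event markers.
#'
#' @param traces A list of flagged `complexity_trace`s (or one trace).
#' @param segmentation Optional `ema_segmentation` for phase shading.
#' @param events Optional [event_log()] for event markers.
#' @return A ggplot object.
#' @export
plot_complexity <- function(traces, segmentation = NULL, events = NULL) {
  if (inherits(traces, "complexity_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  thr <- unique(df[, c("item", "threshold")])
  g <- ggplot(df, aes(x = day, y = DC))
  if (!is.null(segmentation) && nrow(segmentation) > 1) {
    g <- g + geom_rect(
      data = phase_rects(segmentation, -Inf, Inf),
      aes(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax, alpha = phase),
      fill = "steelblue", inherit.aes = FALSE, show.legend = FALSE
    ) + scale_alpha_manual(values = c("0" = 0.05, "1" = 0.15))
  }
  g <- g +
    geom_line(linewidth = 0.3) +
    geom_hline(data = thr, aes(yintercept = threshold), color = "red") +
    geom_point(data = df[df$flagged, , drop = FALSE], color = "red",
               size = 0.8) +
    facet_wrap(~item, ncol = 1) +
    labs(x = "day", y = "dynamic complexity")
  if (!is.null(events) && nrow(events)) {
    g <- g + geom_vline(data = as.data.frame(events),
                        aes(xintercept = day, linetype = valence),
                        color = "grey40", linewidth = 0.3)
  }
  g + theme_minimal()
}
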