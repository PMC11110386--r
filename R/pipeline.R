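# End-to-end orchestration: imputation -> segmentation -> labelling and
# salience -> association screen -> dynamic complexity and flags ->
# mechanism table, with all artifacts written eagerly to an output
# directory.

#' Pipeline configuration
#'
#' Houses the pipeline's fixed analysis constants: a 7-day minimum phase
#' and complexity window (one weekly routine, controlling day-of-week
#' effects), a 25-percentage-point minimum level change, a 14-day pairing
#' proximity, the dominance ratio for single-day marking, the one-tailed
#' instability alpha (0.05) and the association significance threshold
#' (0.01).
#'
#' @param min_len Minimum phase duration in days.
#' @param min_change Minimum absolute mean change (0-1 scale).
#' @param proximity Maximum day gap when pairing change-points.
#' @param dominance_ratio Delta ratio for dominant marking.
#' @param dc_width Dynamic complexity window width in days.
#' @param dc_alpha One-tailed alpha for instability flags.
#' @param assoc_alpha Significance threshold for the association screen.
#' @param s_min,s_max Ordinal item scale bounds.
#' @param suppress Apply the automatic change-point suppression rules.
#' @param missing_frac Missingness fraction for suppression rule (b).
#' @param seed Seed recorded with the run (used when simulating).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_len = 7, min_change = 0.25, proximity = 14,
                            dominance_ratio = 2, dc_width = 7,
                            dc_alpha = 0.05, assoc_alpha = 0.01,
                            s_min = 0, s_max = 5, suppress = TRUE,
                            missing_frac = 0.4, seed = 1L) {
  cfg <- list(min_len = min_len, min_change = min_change,
              proximity = proximity, dominance_ratio = dominance_ratio,
              dc_width = dc_width, dc_alpha = dc_alpha,
              assoc_alpha = assoc_alpha, s_min = s_min, s_max = s_max,
              suppress = isTRUE(suppress), missing_frac = missing_frac,
              seed = as.integer(seed))
  if (any(unlist(cfg[c("min_len", "min_change", "proximity",
                       "dominance_ratio", "dc_width")]) <= 0)) {
    abort_config("all thresholds must be positive")
  }
  if (cfg$dc_alpha <= 0 || cfg$dc_alpha >= 1 ||
      cfg$assoc_alpha <= 0 || cfg$assoc_alpha >= 1) {
    abort_config("alpha values must lie in (0, 1)")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as plain-text YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path Path to a YAML key-value file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) abort_config(sprintf(
    "unknown configuration key(s): %s", paste(extra, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full three-step pipeline on one case
#'
#' Executes level detection and transition pairing on both behavior
#' series, phase construction with attractor labels and factor salience,
#' the exact association screen, local-level imputation and windowed
#' dynamic complexity with significance flags on the two urge items, and
#' the mechanism table. Any stage failure aborts with the stage name and
#' cause. When `out_dir` is given, every table, the run log, the
#' serialized configuration and the two figures are written there; reruns
#' with the same inputs are byte-identical on the CSV side.
#'
#' @param diary An [ema_diary()].
#' @param themes Optional [theme_matrix()] (salience + associations).
#' @param events Optional [event_log()] (mechanism classification).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param plots Whether to render figures when `out_dir` is given.
#' @return A list of class `ema_report` with elements `summary`, `levels`,
#'   `transitions`, `segmentation`, `salience`, `associations`, `traces`,
#'   `mechanisms`, `config`, `log`.
#' @export
run_pipeline <- function(diary, themes = NULL, events = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         plots = TRUE) {
  log <- character(0)

  summary <- run_stage("completion_summary", completion_summary(diary))

  levels <- run_stage("detect_levels", {
    lv <- lapply(stats::setNames(diary_behaviors(), diary_behaviors()),
                 function(b) {
      detect_levels(diary[[b]], min_len = config$min_len,
                    min_change = config$min_change, series_name = b)
    })
    if (config$suppress) {
      lv <- lapply(lv, function(ld) {
        out <- suppress_changepoints(ld, diary[[ld$series_name]],
                                     missing_frac = config$missing_frac)
        log <<- c(log, attr(out, "log"))
        out
      })
    }
    lv
  })

  transitions <- run_stage("pair_changepoints", {
    tr <- pair_changepoints(levels$self_injury, levels$aggression,
                            proximity = config$proximity,
                            dominance_ratio = config$dominance_ratio)
    log <- c(log, attr(tr, "log"))
    tr
  })

  segmentation <- run_stage("segmentation", {
    label_attractors(build_segmentation(diary, transitions))
  })

  salience <- NULL
  associations <- NULL
  if (!is.null(themes)) {
    salience <- run_stage("salience_summary",
                          salience_summary(segmentation, themes))
    associations <- run_stage("assoc_screen",
                              assoc_screen(themes, diary, segmentation,
                                           alpha = config$assoc_alpha))
  }

  traces <- run_stage("dynamic_complexity", {
    lapply(stats::setNames(c("urge_aggression", "urge_selfinjury"),
                           c("urge_aggression", "urge_selfinjury")),
           function(item) {
      imp <- impute_local_level(diary[[item]], config$s_min, config$s_max)
      flag_instability(
        dynamic_complexity(imp, width = config$dc_width,
                           s_min = config$s_min, s_max = config$s_max,
                           item_name = item),
        alpha = config$dc_alpha
      )
    })
  })

  mechanisms <- NULL
  if (!is.null(events)) {
    mechanisms <- run_stage("mechanism_table",
                            mechanism_table(segmentation, events, traces,
                                            width = config$dc_width))
  }

  report <- structure(list(
    diary = diary, themes = themes, events = events, summary = summary,
    levels = levels, transitions = transitions, segmentation = segmentation,
    salience = salience, associations = associations, traces = traces,
    mechanisms = mechanisms, config = config, log = log
  ), class = "ema_report")

  if (!is.null(out_dir)) {
    run_stage("write_report", write_report(report, out_dir, plots = plots))
  }
  report
}

md_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  lines <- c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  )
  paste(lines, collapse = "\n")
}

#' Write all report artifacts to a directory
#'
#' Writes the phase table (with attractor labels), the transition list,
#' the association screen, the complexity trace, the mechanism table (CSV
#' and Markdown), the phase table as JSON, the serialized configuration,
#' the run log, and the timeline/complexity figures.
#'
#' @param report An `ema_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param plots Whether to render figures.
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  utils::write.csv(as.data.frame(report$segmentation), p("phase_table.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(as.data.frame(report$segmentation),
                       p("phase_table.json"), digits = NA)
  utils::write.csv(as.data.frame(report$transitions), p("transitions.csv"),
                   row.names = FALSE, na = "")
  trace_df <- do.call(rbind, lapply(report$traces, as.data.frame))
  utils::write.csv(trace_df[, c("day", "item", "F", "D", "DC", "flagged")],
                   p("complexity.csv"), row.names = FALSE, na = "")
  if (!is.null(report$associations)) {
    utils::write.csv(as.data.frame(report$associations),
                     p("associations.csv"), row.names = FALSE, na = "")
  }
  if (!is.null(report$salience)) {
    utils::write.csv(as.data.frame(report$salience), p("salience.csv"),
                     row.names = FALSE, na = "")
  }
  if (!is.null(report$mechanisms)) {
    utils::write.csv(as.data.frame(report$mechanisms), p("mechanisms.csv"),
                     row.names = FALSE, na = "")
    writeLines(md_table(report$mechanisms), p("mechanisms.md"))
  }
  write_pipeline_config(report$config, p("config.yaml"))
  writeLines(c(sprintf("completed %d of %d days (%d%%)",
                       report$summary$n_completed, report$summary$n_days,
                       report$summary$pct_completed),
               report$log), p("run_log.txt"))
  if (isTRUE(plots)) {
    ggsave(p("timeline.png"),
           plot_timeline(report$diary, report$segmentation, report$events),
           width = 10, height = 4, dpi = 150)
    ggsave(p("complexity.png"),
           plot_complexity(report$traces, report$segmentation,
                           report$events),
           width = 10, height = 6, dpi = 150)
  }
  invisible(out_dir)
}
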