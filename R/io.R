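# Columnar text formats and the end-to-end pipeline driver. Times are
# seconds written as decimal text with six or more fractional digits; cycle
# indices are 1-based in all outputs.

spike_schema <- c("unit_id", "time_s", "shank", "class", "width_us")
stim_schema <- c("stim_id", "onset_s", "intensity_mw", "duration_ms")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", "),
                 "; expected schema: ", paste(required, collapse = ", ")))
  }
}

#' Read / write a spike table
#'
#' CSV with columns `unit_id`, `time_s`, `shank`, `class`, `width_us`.
#' Unsorted per-unit spike times are sorted on load with a warning.
#'
#' @param path file path.
#' @return `read_spike_table()`: spike tibble sorted by unit and time.
#' @export
read_spike_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, spike_schema, "spike table")
  unsorted <- df %>% group_by(.data$unit_id) %>%
    summarise(u = is.unsorted(.data$time_s), .groups = "drop")
  if (any(unsorted$u)) {
    warn("spike times were not sorted within unit; sorting on load")
  }
  df %>% arrange(.data$unit_id, .data$time_s)
}

#' @rdname read_spike_table
#' @param spikes spike tibble.
#' @export
write_spike_table <- function(spikes, path) {
  check_schema(spikes, spike_schema, "spike table")
  readr::write_csv(spikes, path)
  invisible(path)
}

#' Read / write an event table
#'
#' CSV with `event_id`, `onset_s`, `offset_s`, `shank`, `n_cycles`,
#' `peaks` (semicolon-joined seconds) and `provenance`.
#'
#' @param path file path.
#' @return `read_events()`: event tibble with a `peaks` list-column.
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("event_id", "onset_s", "offset_s", "n_cycles", "peaks"),
               "event table")
  df$peaks <- lapply(strsplit(as.character(df$peaks), ";"), as.numeric)
  as_tibble(df)
}

#' @rdname read_events
#' @param events event tibble.
#' @export
write_events <- function(events, path) {
  out <- events
  out$peaks <- vapply(events$peaks,
                      function(p) paste(sprintf("%.6f", p), collapse = ";"),
                      character(1))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write a stimulation table
#'
#' CSV with `stim_id`, `onset_s`, `intensity_mw`, `duration_ms` and, when
#' annotated, `evoked_event_id` and `latency_s`.
#'
#' @param path file path.
#' @return `read_stims()`: stim tibble.
#' @export
read_stims <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, stim_schema, "stim table")
  as_tibble(df)
}

#' @rdname read_stims
#' @param stims stim tibble.
#' @export
write_stims <- function(stims, path) {
  check_schema(stims, stim_schema, "stim table")
  readr::write_csv(stims, path)
  invisible(path)
}

#' Run the full analysis pipeline on a spike table
#'
#' Executes detection (per shank), spike-width classification, cycle
#' metrics, trajectory pooling and the headline trajectory correlations;
#' when a stim table is supplied, the optogenetic analyses (matching,
#' probability curve, length-versus-stimulus test, spontaneous-versus-
#' evoked comparison, comodulation) run as well.
#'
#' @param spikes spike table (`unit_id`, `time_s`, `shank`, `width_us`).
#' @param detection a [detection_config()].
#' @param stims optional stim table.
#' @param lengths length categories kept in trajectory pooling.
#' @param duration_s session duration; defaults to the last spike time.
#' @return A list of class `"spindle_pipeline"`: `events`, `units`,
#'   `trajectories`, `correlations` (tidied), `opto` (or `NULL`), `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(spikes, detection = detection_config(),
                         stims = NULL, lengths = 5:14,
                         duration_s = NULL) {
  check_schema(spikes, c("unit_id", "time_s", "shank", "width_us"),
               "spike table")
  if (is.null(duration_s)) duration_s <- max(spikes$time_s)

  # classify units from spike width
  units <- spikes %>%
    group_by(.data$unit_id, .data$shank) %>%
    summarise(width_us = first(.data$width_us), n_spikes = n(),
              .groups = "drop") %>%
    classify_units()
  spikes <- spikes %>%
    select(-dplyr::any_of("class")) %>%
    left_join(units[, c("unit_id", "class")], by = "unit_id")

  # detect per shank
  events <- bind_rows(lapply(sort(unique(spikes$shank)), function(sh) {
    tr <- smooth_mua(spikes$time_s[spikes$shank == sh],
                     kernel_sd_ms = detection$smoothing_kernel_sd_ms,
                     dt_s = detection$dt_s,
                     t_start = 0, t_end = duration_s, shank = sh)
    detect_spindles(tr, detection)
  }))
  if (nrow(events) > 0) {
    events <- events %>% arrange(.data$onset_s) %>%
      mutate(event_id = dplyr::row_number())
  }

  trajectories <- recovered_trajectories(spikes, events, units, lengths)
  correlations <- bind_rows(
    tidy(first_cycle_vs_duration(trajectories, "participation", "nRT")),
    tidy(first_cycle_vs_duration(trajectories, "participation", "TC")),
    tidy(first_vs_last_cycle(trajectories, "participation", "nRT"))
  )

  opto <- NULL
  if (!is.null(stims) && nrow(stims) > 0) {
    matched <- match_evoked(events, stims)
    period_s <- mean(unlist(lapply(events$peaks, diff)))
    dur_ms <- (matched$events$offset_s - matched$events$onset_s) * 1000
    opto <- list(
      stims = matched$stims,
      events = matched$events,
      probability_curve = probability_curve(matched$stims),
      length_vs_stimulus = tryCatch(
        length_vs_stimulus(matched$events, matched$stims),
        error = function(e) NULL),
      spont_vs_evoked = tryCatch(
        spont_vs_evoked(dur_ms[!matched$events$evoked],
                        dur_ms[matched$events$evoked]),
        error = function(e) NULL),
      comodulation = tryCatch(comodulation(matched$events),
                              error = function(e) NULL)
    )
  }

  cfg <- list(detection = unclass(detection), lengths = lengths,
              duration_s = duration_s)
  out <- list(events = events, units = units, trajectories = trajectories,
              correlations = correlations, opto = opto, config = cfg,
              config_hash = rlang::hash(cfg))
  class(out) <- "spindle_pipeline"
  out
}

#' @export
print.spindle_pipeline <- function(x, ...) {
  cat("<spindle_pipeline> config", substr(x$config_hash, 1, 8), "\n")
  cat("  events:", nrow(x$events), " units:", nrow(x$units), "\n")
  cat("  headline correlations:\n")
  print(as.data.frame(x$correlations[, c("analysis", "population",
                                         "estimate", "p_value")]))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `"spindle_pipeline"` object.
#' @param ... unused.
#' @export
glance.spindle_pipeline <- function(x, ...) {
  tibble(n_events = nrow(x$events), n_units = nrow(x$units),
         n_length_categories = dplyr::n_distinct(x$trajectories$length_k),
         has_opto = !is.null(x$opto), config_hash = x$config_hash)
}

#' Write the result bundle of a pipeline run
#'
#' Writes events, unit table, trajectories and correlations (plus opto
#' results when present) as CSV files into `dir`, each stamped with the
#' pipeline's config hash in a comment-free sidecar `run_info.csv`.
#'
#' @param pipeline a `"spindle_pipeline"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(pipeline$events, file.path(dir, "events.csv"))
  readr::write_csv(pipeline$units, file.path(dir, "units.csv"))
  readr::write_csv(pipeline$trajectories, file.path(dir, "trajectories.csv"))
  readr::write_csv(pipeline$correlations, file.path(dir, "correlations.csv"))
  if (!is.null(pipeline$opto)) {
    write_stims(pipeline$opto$stims, file.path(dir, "stims_annotated.csv"))
    readr::write_csv(pipeline$opto$probability_curve,
                     file.path(dir, "probability_curve.csv"))
    if (!is.null(pipeline$opto$comodulation)) {
      readr::write_csv(pipeline$opto$comodulation,
                       file.path(dir, "comodulation.csv"))
    }
  }
  readr::write_csv(tibble(config_hash = pipeline$config_hash,
                          written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                   file.path(dir, "run_info.csv"))
  invisible(dir)
}

#' Read a declarative run configuration
#'
#' YAML file with optional top-level blocks `session`, `detection`,
#' `protocol` and `seed`; unknown top-level keys or unknown fields inside a
#' block are rejected.
#'
#' @param path YAML file path.
#' @return List with `session` ([session_config()]), `detection`
#'   ([detection_config()]), `protocol` ([stim_protocol()] or `NULL`) and
#'   `seed`.
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example-config.yaml",
#'                                    package = "spindlr"))
#' cfg$session$spindle_rate
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("session", "detection", "protocol", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  build <- function(fn, args, what) {
    if (is.null(args)) return(fn())
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0) {
      abort(paste0("unknown ", what, " field(s): ",
                   paste(bad, collapse = ", ")))
    }
    do.call(fn, args)
  }
  list(
    session = build(session_config, raw$session, "session"),
    detection = build(detection_config, raw$detection, "detection"),
    protocol = if (is.null(raw$protocol)) NULL else
      build(stim_protocol, raw$protocol, "protocol"),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  )
}
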