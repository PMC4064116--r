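# Evoked-spindle analyses: pulse-event matching, evoked-probability curves,
# stimulus-length independence tests, spontaneous-versus-evoked length
# comparisons and comodulation.

#' Match spindle events to laser pulses
#'
#' An event whose onset falls within `[pulse onset, pulse onset +
#' response_window_s]` is evoked and linked to the earliest qualifying
#' pulse; each pulse links to at most one event. All other events are
#' spontaneous. Evoked + spontaneous partitions the event set exactly.
#'
#' @param events event tibble (sorted by onset).
#' @param stims stim tibble (`stim_id`, `onset_s`, `intensity_mw`,
#'   `duration_ms`), sorted by onset.
#' @param response_window_s response window after pulse onset (seconds).
#' @return A list with `stims` (input plus `evoked_event_id`, `latency_s`)
#'   and `events` (input plus `evoked` logical and `stim_id`).
#' @export
match_evoked <- function(events, stims, response_window_s = 0.3) {
  events <- arrange(events, .data$onset_s)
  stims <- arrange(stims, .data$onset_s)
  ev_stim <- rep(NA_integer_, nrow(events))
  stim_used <- rep(FALSE, nrow(stims))
  for (i in seq_len(nrow(events))) {
    ok <- which(!stim_used &
                  events$onset_s[i] >= stims$onset_s &
                  events$onset_s[i] <= stims$onset_s + response_window_s)
    if (length(ok) > 0) {
      j <- ok[1]                      # earliest qualifying pulse
      ev_stim[i] <- stims$stim_id[j]
      stim_used[j] <- TRUE
    }
  }
  events$evoked <- !is.na(ev_stim)
  events$stim_id <- ev_stim
  stims$evoked_event_id <- NA_integer_
  stims$latency_s <- NA_real_
  hit <- which(events$evoked)
  if (length(hit) > 0) {
    j <- match(ev_stim[hit], stims$stim_id)
    stims$evoked_event_id[j] <- events$event_id[hit]
    stims$latency_s[j] <- events$onset_s[hit] - stims$onset_s[j]
  }
  list(stims = stims, events = events)
}

#' Evoked-spindle probability per stimulus group
#'
#' Fraction of pulses with a linked evoked event per stimulus level, with
#' exact binomial confidence intervals.
#'
#' @param stims annotated stim tibble from [match_evoked()] (or a
#'   simulated session's `stims`).
#' @param by grouping column, `"intensity_mw"` or `"duration_ms"`.
#' @param conf_level confidence level for the binomial CI.
#' @return Tibble `level`, `n_stims`, `n_evoked`, `p_evoked`, `ci_lo`,
#'   `ci_hi`, ordered by level.
#' @export
probability_curve <- function(stims, by = c("intensity_mw", "duration_ms"),
                              conf_level = 0.95) {
  by <- match.arg(by)
  grp <- stims %>%
    group_by(level = .data[[by]]) %>%
    summarise(n_stims = n(),
              n_evoked = sum(!is.na(.data$evoked_event_id)),
              .groups = "drop") %>%
    filter(.data$n_stims > 0) %>%
    arrange(.data$level)
  if (nrow(grp) < 2) abort("need at least 2 stimulus groups")
  ci <- map2(grp$n_evoked, grp$n_stims, function(x, n) {
    bt <- stats::binom.test(x, n, conf.level = conf_level)
    c(bt$conf.int[1], bt$conf.int[2])
  })
  grp %>%
    mutate(p_evoked = .data$n_evoked / .data$n_stims,
           ci_lo = map_dbl(ci, 1), ci_hi = map_dbl(ci, 2))
}

#' Do evoked spindle lengths depend on the stimulus?
#'
#' Kruskal-Wallis (or Mann-Whitney for two levels) rank test of evoked
#' spindle lengths across stimulus groups.
#'
#' @param events annotated events from [match_evoked()] (evoked events
#'   carry `stim_id`).
#' @param stims stim tibble with the grouping column.
#' @param by `"intensity_mw"` or `"duration_ms"`.
#' @param length_col event-length column, default `"n_cycles"`.
#' @return One-row tibble as returned by [rank_tests()].
#' @export
length_vs_stimulus <- function(events, stims,
                               by = c("intensity_mw", "duration_ms"),
                               length_col = "n_cycles") {
  by <- match.arg(by)
  ev <- events[events$evoked %in% TRUE, ]
  if (nrow(ev) == 0) abort("no evoked events")
  ev <- ev %>% left_join(stims[, c("stim_id", by)], by = "stim_id")
  groups <- split(ev[[length_col]], ev[[by]])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) abort("need evoked events in at least 2 groups")
  rank_tests(groups)
}

#' Compare spontaneous and evoked spindle-length distributions
#'
#' Two-sided Mann-Whitney test plus the fraction of each set beyond the
#' short/long duration cutoffs (spindles shorter than `short_cutoff_ms` or
#' longer than `long_cutoff_ms`).
#'
#' @param spontaneous_ms,evoked_ms spindle durations in milliseconds.
#' @param short_cutoff_ms,long_cutoff_ms tail cutoffs (ms).
#' @return One-row tibble with the test and the four tail fractions.
#' @export
spont_vs_evoked <- function(spontaneous_ms, evoked_ms,
                            short_cutoff_ms = 600, long_cutoff_ms = 1100) {
  if (length(spontaneous_ms) < 2 || length(evoked_ms) < 2) {
    abort("need at least 2 events per set")
  }
  ht <- suppressWarnings(wilcox.test(spontaneous_ms, evoked_ms,
                                     exact = FALSE))
  tibble(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    n_spontaneous = length(spontaneous_ms), n_evoked = length(evoked_ms),
    frac_short_spont = mean(spontaneous_ms < short_cutoff_ms),
    frac_short_evoked = mean(evoked_ms < short_cutoff_ms),
    frac_long_spont = mean(spontaneous_ms > long_cutoff_ms),
    frac_long_evoked = mean(evoked_ms > long_cutoff_ms)
  )
}

#' Comodulation of spontaneous and evoked spindle lengths
#'
#' Two analyses of slow shared length modulation: (a) the Pearson
#' correlation between each evoked spindle's length and the mean length of
#' spontaneous spindles with onsets within `pair_window_s` of it; (b) the
#' correlation between local spindle density (number of same-set events
#' within a `density_window_s` window centred on each event) and spindle
#' length, separately for spontaneous and evoked spindles.
#'
#' @param events annotated events from [match_evoked()] (columns `onset_s`,
#'   `evoked`, and the length column).
#' @param pair_window_s half-window for pairing evoked with neighbouring
#'   spontaneous spindles (seconds).
#' @param density_window_s window for the density correlation (seconds).
#' @param length_col event-length column, default `"n_cycles"`.
#' @param min_events minimum events per set.
#' @return Tibble with one row per analysis: `analysis`, `r`, `p_value`,
#'   `n`.
#' @export
comodulation <- function(events, pair_window_s = 15, density_window_s = 10,
                         length_col = "n_cycles", min_events = 10) {
  spont <- events[!(events$evoked %in% TRUE), ]
  evo <- events[events$evoked %in% TRUE, ]
  if (nrow(spont) < min_events || nrow(evo) < min_events) {
    abort("too few events for comodulation analysis")
  }
  # (a) evoked length vs mean neighbouring spontaneous length
  nb_mean <- map_dbl(evo$onset_s, function(t) {
    sel <- abs(spont$onset_s - t) <= pair_window_s
    if (!any(sel)) NA_real_ else mean(spont[[length_col]][sel])
  })
  keep <- is.finite(nb_mean)
  res_a <- cor_guarded(evo[[length_col]][keep], nb_mean[keep])
  # (b) density vs length within each set
  dens_cor <- function(d) {
    dens <- map_dbl(d$onset_s, function(t) {
      sum(abs(d$onset_s - t) <= density_window_s / 2) - 1
    })
    cor_guarded(dens, d[[length_col]])
  }
  res_s <- dens_cor(spont)
  res_e <- dens_cor(evo)
  tibble(
    analysis = c("evoked_vs_spontaneous_length", "density_vs_length_spont",
                 "density_vs_length_evoked"),
    r = c(res_a$r, res_s$r, res_e$r),
    p_value = c(res_a$p, res_s$p, res_e$p),
    n = c(sum(keep), nrow(spont), nrow(evo))
  )
}
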