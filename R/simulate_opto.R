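# Optogenetic session generator: laser pulse trains, permissive /
# non-permissive network states, evoked spindles whose probability follows a
# saturating logistic in log intensity while their lengths are drawn
# independently of the stimulus, plus spontaneous spindles sharing an
# optional slow length modulation with the evoked ones.

in_permissive <- function(t, protocol) {
  cyc <- protocol$permissive_epoch_s + protocol$nonpermissive_epoch_s
  (t %% cyc) < protocol$permissive_epoch_s
}

# Draw a spindle length, optionally shifted by the slow shared modulation
# delta (in cycles), clamped to the support of dist.
draw_length <- function(n, dist, delta = 0, truncate = FALSE) {
  k_supp <- as.integer(names(dist))
  if (truncate) {
    keep <- k_supp > min(k_supp) & k_supp < max(k_supp)
    dist <- dist[keep] / sum(dist[keep])
    k_supp <- k_supp[keep]
  }
  k <- sample(k_supp, n, replace = TRUE, prob = dist)
  k <- as.integer(round(k + delta))
  pmin(pmax(k, min(k_supp)), max(k_supp))
}

#' Simulate an optogenetic stimulation session
#'
#' Delivers laser pulses on a fixed grid; pulses falling in permissive
#' network epochs evoke a spindle with probability
#' [evoked_p_curve()]`(intensity)`, beginning at a uniform latency within
#' the response window. Evoked spindle lengths are drawn from the session's
#' length distribution independently of stimulus intensity and duration.
#' Spontaneous spindles occur in permissive epochs at the configured rate.
#' When `protocol$length_comodulation > 0`, a slow sinusoidal modulation
#' shifts the mean length of both spontaneous and evoked spindles so that
#' their lengths co-vary over time. Overlapping events are resolved by
#' suppressing the later onset (suppressed evoked responses are unlinked
#' from their pulse).
#'
#' @param config a [session_config()].
#' @param protocol a [stim_protocol()].
#' @param trajectories trajectory table.
#' @param seed integer seed.
#' @return A list of class `"opto_session"`: a [simulate_session()]-style
#'   session (`spikes`, `units`, `ground_truth`, `config`) plus `stims`, a
#'   tibble with `stim_id`, `onset_s`, `intensity_mw`, `duration_ms`,
#'   `evoked_event_id` (NA if none) and `latency_s`, and `protocol`.
#' @export
simulate_opto_session <- function(config, protocol,
                                  trajectories = default_trajectories(),
                                  seed = 1L) {
  set.seed(seed)
  units <- make_units(config)
  base_period <- 1 / config$base_freq_hz
  max_len_s <- max(as.integer(names(config$length_distribution))) *
    base_period * 1.1

  pulse_on <- seq(protocol$pulse_interval_s,
                  config$duration_s - max_len_s - protocol$response_window_s,
                  by = protocol$pulse_interval_s)
  n_pulse <- length(pulse_on)
  stims <- tibble(
    stim_id = seq_len(n_pulse), onset_s = pulse_on,
    intensity_mw = rep_len(protocol$intensities_mw, n_pulse),
    duration_ms = rep_len(protocol$durations_ms, n_pulse)
  )

  delta_at <- function(t) {
    if (protocol$length_comodulation <= 0) return(rep(0, length(t)))
    protocol$length_comodulation *
      sin(2 * pi * t / protocol$comodulation_period_s)
  }

  # Evoked responses
  permissive <- in_permissive(stims$onset_s, protocol)
  p_evoke <- evoked_p_curve(stims$intensity_mw, protocol) * permissive
  evoked <- runif(n_pulse) < p_evoke
  latency <- ifelse(evoked,
                    runif(n_pulse, 0.03, protocol$response_window_s), NA_real_)
  ev_onset <- stims$onset_s + latency
  ev_len <- rep(NA_integer_, n_pulse)
  if (any(evoked)) {
    ev_len[evoked] <- draw_length(sum(evoked), config$length_distribution,
                                  delta_at(ev_onset[evoked]),
                                  protocol$truncate_evoked_lengths)
  }

  # Spontaneous events in permissive epochs
  sched <- draw_event_onsets(config)
  sp_keep <- in_permissive(sched$onset, protocol)
  sp_onset <- sched$onset[sp_keep]
  sp_len <- draw_length(length(sp_onset), config$length_distribution,
                        delta_at(sp_onset))

  cand <- bind_rows(
    tibble(onset_s = ev_onset[evoked], length_k = ev_len[evoked],
           provenance = "evoked", stim_id = stims$stim_id[evoked]),
    tibble(onset_s = sp_onset, length_k = sp_len,
           provenance = "ground_truth", stim_id = NA_integer_)
  ) %>% arrange(.data$onset_s)

  # Suppress later-onset overlaps
  keep <- rep(TRUE, nrow(cand))
  last_end <- -Inf
  end_s <- cand$onset_s + cand$length_k * base_period + config$min_event_gap_s
  for (i in seq_len(nrow(cand))) {
    if (cand$onset_s[i] < last_end) keep[i] <- FALSE else last_end <- end_s[i]
  }
  n_suppressed <- sum(!keep)
  cand <- cand[keep, ]

  events <- vector("list", nrow(cand))
  ev_spikes <- vector("list", nrow(cand))
  ev_part <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    k <- cand$length_k[i]
    geom <- event_geometry(k, cand$onset_s[i], config)
    local <- runif(1) < config$spindle_locality
    shanks <- if (local) sample.int(config$n_shanks, 1) else
      seq_len(config$n_shanks)
    traj_k <- trajectories[trajectories$length_k == k, ]
    traj_k <- traj_k[order(traj_k$cycle_index), ]
    sp_list <- vector("list", length(shanks))
    pt_list <- vector("list", length(shanks))
    for (s in seq_along(shanks)) {
      u <- units[units$shank == shanks[s], ]
      gen <- gen_event_spikes(geom, u, traj_k, config)
      sp_list[[s]] <- gen$spikes
      pt_list[[s]] <- gen$participation
    }
    events[[i]] <- tibble(
      event_id = i, onset_s = geom$start, offset_s = geom$end,
      shank = if (local) shanks else NA_integer_,
      n_cycles = k, peaks = list(geom$peaks),
      provenance = cand$provenance[i]
    )
    ev_spikes[[i]] <- bind_rows(sp_list)
    ev_part[[i]] <- bind_rows(pt_list) %>% mutate(event_id = i)
  }
  events <- bind_rows(events)

  # Link surviving evoked events back to their pulses
  stims$evoked_event_id <- NA_integer_
  stims$latency_s <- NA_real_
  if (nrow(cand) > 0) {
    linked <- which(cand$provenance == "evoked")
    for (i in linked) {
      sid <- cand$stim_id[i]
      stims$evoked_event_id[sid] <- events$event_id[i]
      stims$latency_s[sid] <- events$onset_s[i] - stims$onset_s[sid]
    }
  }

  bg <- lapply(seq_len(nrow(units)), function(r) {
    rate <- if (units$class[r] == "TC") config$background_rate_tc_hz else
      config$background_rate_nrt_hz
    n_bg <- rpois(1, rate * config$duration_s)
    if (n_bg == 0) return(NULL)
    tibble(unit_id = units$unit_id[r],
           time_s = sort(runif(n_bg, 0, config$duration_s)))
  })
  bg <- bind_rows(bg)
  if (nrow(events) > 0 && nrow(bg) > 0) {
    bg <- bg %>% left_join(units[, c("unit_id", "shank")], by = "unit_id")
    keep_bg <- rep(TRUE, nrow(bg))
    for (i in seq_len(nrow(events))) {
      in_ev <- bg$time_s >= events$onset_s[i] & bg$time_s < events$offset_s[i]
      if (!is.na(events$shank[i])) in_ev <- in_ev & bg$shank == events$shank[i]
      keep_bg <- keep_bg & !in_ev
    }
    bg <- bg[keep_bg, c("unit_id", "time_s")]
  }

  spikes <- bind_rows(bg, bind_rows(ev_spikes)) %>%
    left_join(units, by = "unit_id") %>%
    arrange(.data$unit_id, .data$time_s) %>%
    select("unit_id", "time_s", "shank", "class", "width_us")

  out <- list(spikes = spikes, units = units,
              ground_truth = list(events = events,
                                  participation = bind_rows(ev_part)),
              stims = stims, protocol = protocol, config = config,
              seed = seed, n_suppressed_overlaps = n_suppressed)
  class(out) <- c("opto_session", "spindle_session")
  out
}
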