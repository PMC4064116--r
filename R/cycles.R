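# Cycle-resolved population statistics: spikes/cycle, participation
# probability, spikes/burst given participation, jitter, per-cycle
# cross-correlograms, phase locking and the spatial CCG profile.
#
# Conventions: all cycle windows are half-open [start, end); a spike exactly
# at a boundary belongs to the later cycle. "Participation" counts any spike
# of the unit inside the cycle window. Metrics are pooled per spindle-length
# category across all events and units ("across all cells in all animals"
# style averaging); jitter is the population SD (divisor n).

# Assign spikes to cycle windows. Returns one row per (event, cycle, unit)
# with a positive spike count. Events with shank = NA are treated as global
# (units on every shank can participate); otherwise only same-shank spikes
# count.
assign_spikes_to_cycles <- function(spikes, events) {
  cw <- cycle_windows(events)
  if (nrow(cw) == 0 || nrow(spikes) == 0) {
    return(tibble(event_id = integer(), n_cycles = integer(),
                  cycle_index = integer(), unit_id = integer(),
                  n_spikes = integer()))
  }
  has_shank <- "shank" %in% names(cw) && "shank" %in% names(spikes)
  shanks <- if (has_shank) unique(spikes$shank) else NA_integer_
  out <- vector("list", length(shanks))
  for (si in seq_along(shanks)) {
    sh <- shanks[si]
    if (has_shank) {
      w <- cw[is.na(cw$shank) | cw$shank == sh, ]
      sp <- spikes[spikes$shank == sh, ]
    } else {
      w <- cw
      sp <- spikes
    }
    if (nrow(w) == 0 || nrow(sp) == 0) next
    w <- w[order(w$start_s), ]
    idx <- findInterval(sp$time_s, w$start_s)
    valid <- idx >= 1 & idx <= nrow(w)
    valid[valid] <- sp$time_s[valid] < w$end_s[idx[valid]]
    if (!any(valid)) next
    out[[si]] <- tibble(
      event_id = w$event_id[idx[valid]],
      n_cycles = w$n_cycles[idx[valid]],
      cycle_index = w$cycle_index[idx[valid]],
      peak_s = w$peak_s[idx[valid]],
      unit_id = sp$unit_id[valid],
      time_s = sp$time_s[valid]
    )
  }
  bind_rows(out)
}

# Number of units of each class eligible for an event (same shank, or all
# units for global events).
eligible_units <- function(events, units) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    u <- if (!is.na(events$shank[i]) && "shank" %in% names(units)) {
      units[units$shank == events$shank[i], ]
    } else units
    tibble(event_id = events$event_id[i],
           n_tc = sum(u$class == "TC"),
           n_nrt = sum(u$class == "nRT"))
  })
  bind_rows(rows)
}

#' Per-event cycle metrics for both populations
#'
#' For every (event, cycle, population) computes the mean spikes per cycle
#' over eligible units, the participation fraction (units with at least one
#' spike in the cycle), the conditional spikes per burst (mean count among
#' participating units) and the jitter contributions (spike-time offsets
#' from the cycle peak).
#'
#' @param spikes spike table (`unit_id`, `time_s`, `shank`, `class`).
#' @param events event tibble with `peaks` list-column.
#' @param units unit table (`unit_id`, `shank`, `class`).
#' @return Tibble with one row per (event, cycle, population):
#'   `event_id`, `n_cycles`, `cycle_index`, `population`, `n_units`,
#'   `n_participating`, `total_spikes`, `spikes_per_cycle`,
#'   `participation`, `spikes_per_burst`.
#' @export
cycle_metrics <- function(spikes, events, units) {
  if (nrow(events) == 0) abort("no events supplied")
  asg <- assign_spikes_to_cycles(spikes, events) %>%
    left_join(units[, c("unit_id", "class")], by = "unit_id") %>%
    filter(.data$class %in% c("TC", "nRT"))
  counts <- asg %>%
    group_by(.data$event_id, .data$n_cycles, .data$cycle_index,
             .data$class, .data$unit_id) %>%
    summarise(n_spikes = n(), .groups = "drop")
  elig <- eligible_units(events, units)
  grid <- cycle_windows(events) %>%
    select("event_id", "n_cycles", "cycle_index") %>%
    left_join(elig, by = "event_id") %>%
    tidyr::pivot_longer(cols = c("n_tc", "n_nrt"), names_to = "population",
                        values_to = "n_units") %>%
    mutate(population = if_else(.data$population == "n_tc", "TC", "nRT"))
  agg <- counts %>%
    group_by(.data$event_id, .data$cycle_index, .data$class) %>%
    summarise(n_participating = n(), total_spikes = sum(.data$n_spikes),
              .groups = "drop") %>%
    rename(population = "class")
  grid %>%
    left_join(agg, by = c("event_id", "cycle_index", "population")) %>%
    mutate(
      n_participating = dplyr::coalesce(.data$n_participating, 0L),
      total_spikes = dplyr::coalesce(.data$total_spikes, 0L),
      spikes_per_cycle = .data$total_spikes / .data$n_units,
      participation = .data$n_participating / .data$n_units,
      spikes_per_burst = if_else(.data$n_participating > 0,
                                 .data$total_spikes / .data$n_participating,
                                 NA_real_)
    )
}

# Pool per-event metrics into per-length-category trajectories.
pool_metrics <- function(metrics) {
  metrics %>%
    group_by(length_k = .data$n_cycles, .data$cycle_index,
             .data$population) %>%
    summarise(
      spikes_per_cycle = mean(.data$spikes_per_cycle),
      participation = mean(.data$participation),
      spikes_per_burst = sum(.data$total_spikes) /
        pmax(sum(.data$n_participating), 1L),
      n_events = n_distinct(.data$event_id),
      n_unit_cycles = sum(.data$n_units),
      .groups = "drop"
    )
}

#' Recovered activity trajectories from a spike table and events
#'
#' Runs [cycle_metrics()] and pools per spindle-length category, yielding
#' the measured counterpart of [default_trajectories()]: participation
#' probability, conditional spikes/burst and mean spikes/cycle per
#' (length, cycle, population).
#'
#' @inheritParams cycle_metrics
#' @param lengths keep only these length categories (default 5--14 cycles).
#' @return Tibble `length_k`, `cycle_index`, `population`,
#'   `spikes_per_cycle`, `participation`, `spikes_per_burst`, `n_events`,
#'   `n_unit_cycles`.
#' @export
recovered_trajectories <- function(spikes, events, units, lengths = 5:14) {
  cycle_metrics(spikes, events, units) %>%
    pool_metrics() %>%
    filter(.data$length_k %in% lengths)
}

#' Mean spikes per cycle, pooled by spindle length
#'
#' @inheritParams cycle_metrics
#' @param population `"TC"` or `"nRT"`.
#' @return Tibble `length_k`, `cycle_index`, `spikes_per_cycle`, `n_events`.
#' @export
spikes_per_cycle <- function(spikes, events, units,
                             population = c("nRT", "TC")) {
  population <- match.arg(population)
  recovered_trajectories(spikes, events, units,
                         lengths = unique(events$n_cycles)) %>%
    filter(.data$population == .env$population) %>%
    select("length_k", "cycle_index", "spikes_per_cycle", "n_events")
}

#' Participation probability per cycle, pooled by spindle length
#'
#' Fraction of units of the class firing at least one spike in the cycle,
#' averaged across events of the same length category.
#'
#' @inheritParams spikes_per_cycle
#' @return Tibble `length_k`, `cycle_index`, `participation`, `n_events`.
#' @export
participation_probability <- function(spikes, events, units,
                                      population = c("nRT", "TC")) {
  population <- match.arg(population)
  if (!any(units$class == population)) {
    abort(paste0("no units of class ", population))
  }
  recovered_trajectories(spikes, events, units,
                         lengths = unique(events$n_cycles)) %>%
    filter(.data$population == .env$population) %>%
    select("length_k", "cycle_index", "participation", "n_events")
}

#' Conditional spikes per burst per cycle
#'
#' Mean spike count in the cycle among (unit, cycle) pairs with at least
#' one spike, i.e. given the cell participated in the cycle. Equals
#' spikes-per-cycle divided by participation where participation > 0.
#'
#' @inheritParams spikes_per_cycle
#' @return Tibble `length_k`, `cycle_index`, `spikes_per_burst`, `n_events`;
#'   `spikes_per_burst` is `NA` where no unit ever participated.
#' @export
spikes_per_burst_in_cycle <- function(spikes, events, units,
                                      population = c("nRT", "TC")) {
  population <- match.arg(population)
  out <- recovered_trajectories(spikes, events, units,
                                lengths = unique(events$n_cycles)) %>%
    filter(.data$population == .env$population)
  out$spikes_per_burst[out$participation == 0] <- NA_real_
  select(out, "length_k", "cycle_index", "spikes_per_burst", "n_events")
}

#' Spike-timing jitter per cycle
#'
#' Pooled population SD (divisor n) of spike-time offsets from the cycle
#' peak, per (length category, cycle index), for one population.
#'
#' @inheritParams spikes_per_cycle
#' @return Tibble `length_k`, `cycle_index`, `jitter_ms`, `n_spikes`.
#' @export
spindle_jitter <- function(spikes, events, units,
                           population = c("nRT", "TC")) {
  population <- match.arg(population)
  asg <- assign_spikes_to_cycles(spikes, events) %>%
    left_join(units[, c("unit_id", "class")], by = "unit_id") %>%
    filter(.data$class == .env$population)
  asg %>%
    group_by(length_k = .data$n_cycles, .data$cycle_index) %>%
    summarise(
      jitter_ms = sqrt(mean((.data$time_s - .data$peak_s)^2) -
                         mean(.data$time_s - .data$peak_s)^2) * 1000,
      n_spikes = n(), .groups = "drop"
    )
}

#' Cycle-by-cycle TC-to-nRT cross-correlogram
#'
#' For each (spindle length, cycle index): histogram of (nRT spike time -
#' TC spike time) lags where the TC reference spikes are restricted to that
#' cycle's window; target nRT spikes are taken within `window_ms` of each
#' reference, regardless of cycle. Reports the peak lag per group.
#'
#' @inheritParams cycle_metrics
#' @param bin_ms,window_ms histogram bin and half-window (ms).
#' @param lengths restrict to these length categories (default: all).
#' @return A list with `ccg` (tibble `length_k`, `cycle_index`, `lag_ms`,
#'   `count`) and `peaks` (tibble `length_k`, `cycle_index`, `peak_lag_ms`,
#'   `n_pairs`).
#' @export
cycle_ccg <- function(spikes, events, units, bin_ms = 1, window_ms = 50,
                      lengths = NULL) {
  if (bin_ms > window_ms) abort("bin must not exceed window")
  asg <- assign_spikes_to_cycles(spikes, events) %>%
    left_join(units[, c("unit_id", "class")], by = "unit_id")
  if (!is.null(lengths)) asg <- filter(asg, .data$n_cycles %in% lengths)
  refs <- filter(asg, .data$class == "TC")
  # targets: all nRT spikes, sorted once
  tgt <- sort(spikes$time_s[spikes$class == "nRT"])
  groups <- refs %>% distinct(.data$n_cycles, .data$cycle_index)
  ccg_rows <- vector("list", nrow(groups))
  peak_rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- refs %>% filter(.data$n_cycles == groups$n_cycles[i],
                         .data$cycle_index == groups$cycle_index[i])
    cc <- crosscorrelogram(sort(g$time_s), tgt, bin_ms, window_ms)
    ccg_rows[[i]] <- mutate(cc, length_k = groups$n_cycles[i],
                            cycle_index = groups$cycle_index[i])
    peak_rows[[i]] <- tibble(
      length_k = groups$n_cycles[i], cycle_index = groups$cycle_index[i],
      peak_lag_ms = ccg_peak_lag(cc),
      n_pairs = sum(cc$count)
    )
  }
  list(ccg = bind_rows(ccg_rows) %>%
         select("length_k", "cycle_index", "lag_ms", "count"),
       peaks = bind_rows(peak_rows) %>%
         arrange(.data$length_k, .data$cycle_index))
}

# Activation-latency peak of a TC->nRT CCG: the histogram is lightly
# smoothed (3-bin moving average) and the peak searched at positive lags
# only (nRT follows TC in the ping-pong cycle; the negative side can carry
# the tail of the previous cycle's nRT burst at the window edge). The
# reported latency is the count-weighted mean lag within +/-5 ms of the
# smoothed mode, giving sub-bin precision without a tie-prone grid.
ccg_peak_lag <- function(cc, halfwidth_ms = 20) {
  if (all(cc$count == 0)) return(NA_real_)
  k <- min(9, 2 * floor(length(cc$count) / 4) + 1)
  sm <- as.numeric(stats::filter(cc$count, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- cc$count[is.na(sm)]
  pos <- cc$lag_ms > 0
  if (!any(pos)) return(NA_real_)
  centre <- cc$lag_ms[pos][which.max(sm[pos])]
  # centre-of-mass of the bump, iteratively re-centred: robust for the
  # broad lag distributions produced by burst-burst convolution
  for (it in 1:2) {
    nb <- abs(cc$lag_ms - centre) <= halfwidth_ms
    if (sum(cc$count[nb]) == 0) break
    centre <- sum(cc$lag_ms[nb] * cc$count[nb]) / sum(cc$count[nb])
  }
  centre
}

#' Phase locking of a unit to the spindle oscillation
#'
#' Assigns each in-event spike a phase (one spindle cycle is 360 degrees; a
#' cycle peak is 0) by linear interpolation between the surrounding cycle
#' peaks, and returns the circular mean angle and resultant vector length.
#'
#' @param spike_times numeric spike times of one unit (seconds).
#' @param events event tibble with `peaks` list-column.
#' @return One-row tibble `mean_angle_deg` in `[0, 360)`, `vector_length`,
#'   `n_spikes`; values are `NA` when no spike falls inside an event.
#' @export
phase_locking <- function(spike_times, events) {
  phases <- spike_phases(spike_times, events)
  if (length(phases) == 0) {
    return(tibble(mean_angle_deg = NA_real_, vector_length = NA_real_,
                  n_spikes = 0L))
  }
  z <- mean(exp(1i * phases))
  ang <- (Arg(z) / pi * 180) %% 360
  tibble(mean_angle_deg = ang, vector_length = Mod(z),
         n_spikes = length(phases))
}

# Spike phases in radians; peaks are multiples of 2*pi. Spikes between two
# peaks interpolate linearly; spikes in the opening/closing half cycles use
# the neighbouring period.
spike_phases <- function(spike_times, events) {
  out <- lapply(seq_len(nrow(events)), function(i) {
    pk <- events$peaks[[i]]
    k <- length(pk)
    sel <- spike_times >= events$onset_s[i] & spike_times < events$offset_s[i]
    ts <- spike_times[sel]
    if (length(ts) == 0 || k < 2) return(NULL)
    # extend the peak grid by one period on both sides
    grid <- c(pk[1] - (pk[2] - pk[1]), pk, pk[k] + (pk[k] - pk[k - 1]))
    idx <- findInterval(ts, grid)
    idx <- pmin(pmax(idx, 1L), length(grid) - 1L)
    frac <- (ts - grid[idx]) / (grid[idx + 1] - grid[idx])
    2 * pi * (idx - 2 + frac)
  })
  unlist(out) %||% numeric(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TC-nRT cross-correlogram modulation versus shank distance
#'
#' For shank-local events, computes the TC-reference/nRT-target CCG
#' separately for unit pairs at each shank offset (0, 1, 2, ... shanks
#' apart). Modulation is the spike-pair mass inside the peak region
#' (centred on the pooled same-shank peak latency) divided by the mass
#' expected there under independence, estimated from surrogate target
#' trains resampled uniformly within each event (finite even with no
#' background target spikes). A flat profile gives modulation ~ 1.
#' Per-event modulation values are compared between offsets with
#' Mann-Whitney tests.
#'
#' @inheritParams cycle_metrics
#' @param bin_ms,window_ms CCG bin and half-window (ms).
#' @param n_surrogate surrogate resamples per event for the baseline.
#' @param peak_halfwidth_ms half-width of the peak region (ms).
#' @return A list with `profile` (tibble `offset_shanks`, `modulation`,
#'   `n_pairs`, pooled across events), `per_event` (per event and offset)
#'   and `tests` (Mann-Whitney p-values, offset 0 versus each other
#'   offset).
#' @export
spatial_ccg_profile <- function(spikes, events, units, bin_ms = 2,
                                window_ms = 50, n_surrogate = 3,
                                peak_halfwidth_ms = 10) {
  ev <- events[!is.na(events$shank), ]
  if (nrow(ev) == 0) abort("no shank-local events supplied")
  offsets <- sort(unique(abs(outer(unique(units$shank), unique(units$shank),
                                   "-"))))
  get_pair <- function(i, d) {
    on <- ev$onset_s[i]; off <- ev$offset_s[i]
    ref <- spikes$time_s[spikes$class == "TC" &
                           spikes$shank == ev$shank[i] &
                           spikes$time_s >= on & spikes$time_s < off]
    tgt_shanks <- unique(units$shank[abs(units$shank - ev$shank[i]) == d])
    tgt <- spikes$time_s[spikes$class == "nRT" &
                           spikes$shank %in% tgt_shanks &
                           spikes$time_s >= on - 0.1 &
                           spikes$time_s < off + 0.1]
    list(ref = sort(ref), tgt = sort(tgt), on = on, off = off)
  }
  # peak region from the pooled same-shank CCG
  pooled0 <- NULL
  for (i in seq_len(nrow(ev))) {
    p <- get_pair(i, 0)
    if (length(p$ref) == 0 || length(p$tgt) == 0) next
    cc <- crosscorrelogram(p$ref, p$tgt, bin_ms, window_ms)
    pooled0 <- if (is.null(pooled0)) cc else
      mutate(pooled0, count = .data$count + cc$count)
  }
  if (is.null(pooled0)) abort("no TC-nRT spike pairs found")
  centre <- ccg_peak_lag(pooled0)
  in_peak <- function(cc) {
    abs(cc$lag_ms - centre) <= peak_halfwidth_ms
  }
  per_event <- vector("list", 0)
  for (i in seq_len(nrow(ev))) {
    for (d in offsets) {
      p <- get_pair(i, d)
      if (length(p$ref) == 0 || length(p$tgt) == 0) next
      cc <- crosscorrelogram(p$ref, p$tgt, bin_ms, window_ms)
      obs <- sum(cc$count[in_peak(cc)])
      sur <- vapply(seq_len(n_surrogate), function(s) {
        st <- sort(runif(length(p$tgt), p$on - 0.1, p$off + 0.1))
        sc <- crosscorrelogram(p$ref, st, bin_ms, window_ms)
        sum(sc$count[in_peak(sc)])
      }, numeric(1))
      per_event[[length(per_event) + 1]] <- tibble(
        event_id = ev$event_id[i], offset_shanks = d,
        obs = obs, expected = mean(sur),
        modulation = (obs + 1) / (mean(sur) + 1),
        n_pairs = sum(cc$count)
      )
    }
  }
  per_event <- bind_rows(per_event)
  profile <- per_event %>%
    group_by(.data$offset_shanks) %>%
    summarise(modulation = (sum(.data$obs) + 1) / (sum(.data$expected) + 1),
              n_pairs = sum(.data$n_pairs), .groups = "drop")
  tests <- NULL
  if (length(offsets) > 1) {
    tests <- bind_rows(lapply(setdiff(offsets, 0), function(d) {
      a <- per_event$modulation[per_event$offset_shanks == 0]
      b <- per_event$modulation[per_event$offset_shanks == d]
      p <- if (length(a) > 0 && length(b) > 0)
        suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
      tibble(offset_shanks = d, p_value = p)
    }))
  }
  list(profile = profile, per_event = per_event, tests = tests,
       peak_lag_ms = centre)
}
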