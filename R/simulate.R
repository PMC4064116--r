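# Synthetic ping-pong spindle generator.
#
# Events are parameterised by a trajectory table (participation probability
# and spikes/burst per length category and cycle). Each cycle of each event
# recruits each TC unit with probability p_tc(k, c); a recruited unit fires
# one burst (shifted-Poisson size with mean b(k, c), >= 1 spike) centred at
# the cycle peak plus Gaussian jitter. nRT units do the same with their own
# p/b, centred tc_nrt_lag_ms after the peak. Bursts are confined to their
# generating cycle window so per-cycle bookkeeping is exact, matching the
# one-burst-per-cell-per-cycle physiology of low-threshold bursting.

#' Cycle-period multipliers for a spindle
#'
#' Mean-one multipliers applied to the base period for the `k - 1` inter-peak
#' intervals of a `k`-cycle spindle. The natural-sleep profile shortens
#' periods over the first cycles and lengthens them again before termination
#' (accelerate, then decelerate); the urethane profile accelerates
#' monotonically. Depth is +/-8% of the base period.
#'
#' @param length_k number of cycles.
#' @param profile `"natural_sleep"` or `"urethane"`.
#' @return Numeric vector of length `length_k - 1` with mean 1.
#' @export
cycle_period_profile <- function(length_k,
                                 profile = c("natural_sleep", "urethane")) {
  profile <- match.arg(profile)
  n <- length_k - 1
  if (n < 1) abort("length_k must be >= 2")
  if (n == 1) return(1)
  x <- (seq_len(n) - 1) / (n - 1)
  if (profile == "natural_sleep") {
    shape <- -sin(pi * x)          # dip in the middle: fast mid-spindle
  } else {
    shape <- 0.5 - x               # monotone acceleration
  }
  m <- 1 + 0.16 * (shape - mean(shape))
  m
}

#' Sample extracellular spike widths for a unit class
#'
#' Widths are drawn from the class-specific modes of the bimodal
#' half-amplitude spike-width distribution: narrow nRT-axonal spikes
#' ~ Normal(100, 15) microseconds, wide TC spikes ~ Normal(275, 40)
#' microseconds, truncated to be positive. The two modes are separable at
#' the 150 microsecond classification boundary.
#'
#' @param class `"TC"` or `"nRT"`.
#' @param n number of widths to draw.
#' @return Numeric vector of widths in microseconds.
#' @export
sample_spike_widths <- function(class = c("TC", "nRT"), n) {
  class <- match.arg(class)
  stopifnot(n >= 1)
  mu <- if (class == "TC") 275 else 100
  sigma <- if (class == "TC") 40 else 15
  w <- rnorm(n, mu, sigma)
  while (any(w <= 0)) w[w <= 0] <- rnorm(sum(w <= 0), mu, sigma)
  w
}

# Unit table for a configured session.
make_units <- function(config) {
  per_shank <- config$n_tc_units + config$n_nrt_units
  out <- bind_rows(lapply(seq_len(config$n_shanks), function(sh) {
    tibble(
      unit_id = (sh - 1) * per_shank + seq_len(per_shank),
      shank = sh,
      class = rep(c("TC", "nRT"), c(config$n_tc_units, config$n_nrt_units))
    )
  }))
  out$width_us <- NA_real_
  out$width_us[out$class == "TC"] <-
    sample_spike_widths("TC", sum(out$class == "TC"))
  out$width_us[out$class == "nRT"] <-
    sample_spike_widths("nRT", sum(out$class == "nRT"))
  out
}

# Peaks and cycle windows for one event. Returns list(peaks, start, end,
# win_lo, win_hi) where win_* are the half-open cycle windows.
event_geometry <- function(length_k, onset_s, config) {
  base_period <- 1 / config$base_freq_hz
  periods <- base_period * cycle_period_profile(length_k,
                                                config$cycle_period_profile)
  peaks <- onset_s + periods[1] / 2 + c(0, cumsum(periods))
  start <- onset_s
  end <- peaks[length_k] + periods[length_k - 1] / 2
  mids <- (peaks[-1] + peaks[-length_k]) / 2
  list(peaks = peaks, start = start, end = end,
       win_lo = c(start, mids), win_hi = c(mids, end))
}

# Spikes for one event on one shank's units. traj_k: trajectory rows for
# this length, ordered by cycle. Returns list(spikes, participation).
gen_event_spikes <- function(geom, units, traj_k, config) {
  k <- length(geom$peaks)
  specs <- list(
    TC = list(p = traj_k$p_tc, b = traj_k$b_tc, lag = 0,
              isi = config$intra_burst_isi_tc_ms / 1000),
    nRT = list(p = traj_k$p_nrt, b = traj_k$b_nrt,
               lag = config$tc_nrt_lag_ms / 1000,
               isi = config$intra_burst_isi_nrt_ms / 1000)
  )
  eps <- 5e-4
  all_spikes <- vector("list", 2)
  all_part <- vector("list", 2)
  for (j in seq_along(specs)) {
    cls <- names(specs)[j]
    sp <- specs[[j]]
    uid <- units$unit_id[units$class == cls]
    m <- length(uid)
    if (m == 0) next
    # (cycle x unit) grid
    cyc <- rep(seq_len(k), each = m)
    unit <- rep(uid, times = k)
    p <- sp$p[cyc]
    b <- sp$b[cyc]
    part <- rbinom(length(p), 1, p) == 1
    nsp <- integer(length(p))
    nsp[part] <- 1L + rpois(sum(part), pmax(b[part] - 1, 0))
    # cap burst length so it fits in the cycle window
    win_len <- geom$win_hi[cyc] - geom$win_lo[cyc]
    cap <- pmax(1L, as.integer(floor((win_len - 2 * eps) / sp$isi)) + 1L)
    nsp <- pmin(nsp, cap)
    idx <- which(nsp > 0)
    if (length(idx) > 0) {
      centre <- geom$peaks[cyc[idx]] + sp$lag +
        rnorm(length(idx), 0, config$within_cycle_jitter_ms / 1000)
      nn <- nsp[idx]
      t0 <- rep(centre - (nn + 1) / 2 * sp$isi, nn) +
        sequence(nn) * sp$isi
      # shift whole bursts back inside their half-open cycle window
      lo <- rep(geom$win_lo[cyc[idx]] + eps, nn)
      hi <- rep(geom$win_hi[cyc[idx]] - eps, nn)
      grp <- rep(seq_along(idx), nn)
      shift_lo <- tapply(pmax(lo - t0, 0), grp, max)
      shift_hi <- tapply(pmax(t0 - hi, 0), grp, max)
      t0 <- t0 + shift_lo[grp] - shift_hi[grp]
      all_spikes[[j]] <- tibble(unit_id = rep(unit[idx], nn),
                                time_s = as.numeric(t0))
    }
    all_part[[j]] <- tibble(unit_id = unit, cycle_index = cyc,
                            class = cls, n_spikes = nsp,
                            participates = nsp > 0L)
  }
  list(spikes = bind_rows(all_spikes), participation = bind_rows(all_part))
}

#' Simulate a single spindle event
#'
#' Generates the cycle-peak times and the per-unit spike times of one
#' spindle of `length_k` cycles on one shank, using the current RNG stream.
#'
#' @param length_k number of cycles (must appear in `trajectories`).
#' @param onset_s event onset in seconds.
#' @param shank shank id the event is local to.
#' @param config a [session_config()].
#' @param trajectories a trajectory table, see [default_trajectories()].
#' @param units optional unit table (`unit_id`, `shank`, `class`); defaults
#'   to the configured complement of units on `shank`.
#' @return A list with `event` (one-row tibble: `event_id`, `onset_s`,
#'   `offset_s`, `shank`, `n_cycles`, `peaks` list-column, `provenance`),
#'   `spikes` (tibble `unit_id`, `time_s`) and `participation` (per unit and
#'   cycle: `n_spikes`, `participates`).
#' @export
simulate_spindle <- function(length_k, onset_s, shank, config, trajectories,
                             units = NULL) {
  traj_k <- dplyr::filter(trajectories, .data$length_k == .env$length_k) %>%
    arrange(.data$cycle_index)
  if (nrow(traj_k) != length_k) {
    abort(paste0("length_k = ", length_k, " not present in trajectory table"))
  }
  geom <- event_geometry(length_k, onset_s, config)
  if (geom$end > config$duration_s) {
    abort("event would extend beyond the session end; truncation is not allowed")
  }
  if (is.null(units)) {
    units <- make_units(config) %>% filter(.data$shank == .env$shank)
  }
  gen <- gen_event_spikes(geom, units, traj_k, config)
  event <- tibble(event_id = 1L, onset_s = geom$start, offset_s = geom$end,
                  shank = shank, n_cycles = length_k,
                  peaks = list(geom$peaks), provenance = "ground_truth")
  list(event = event, spikes = gen$spikes, participation = gen$participation)
}

sample_lengths <- function(n, dist) {
  k <- as.integer(names(dist))
  if (is.null(names(dist))) k <- 5:14
  sample(k, n, replace = TRUE, prob = dist)
}

# Draw non-overlapping event onsets over [0, duration - margin].
draw_event_onsets <- function(config) {
  rate_s <- config$spindle_rate / 60
  if (rate_s <= 0) return(list(onset = numeric(0), length_k = integer(0)))
  base_period <- 1 / config$base_freq_hz
  mean_len <- sum(config$length_distribution *
                    as.integer(names(config$length_distribution))) * base_period
  gap_mean <- 1 / rate_s - mean_len - config$min_event_gap_s
  if (gap_mean <= 0.05) {
    abort("spindle_rate too high for non-overlapping events; lower it")
  }
  max_len <- max(as.integer(names(config$length_distribution))) * base_period * 1.1
  onsets <- numeric(0)
  lens <- integer(0)
  t <- rexp(1, 1 / gap_mean)
  while (TRUE) {
    k <- sample_lengths(1, config$length_distribution)
    dur <- k * base_period  # slight overestimate is fine
    if (t + max_len + 0.05 > config$duration_s) break
    onsets <- c(onsets, t)
    lens <- c(lens, k)
    t <- t + dur + config$min_event_gap_s + rexp(1, 1 / gap_mean)
  }
  list(onset = onsets, length_k = lens)
}

#' Simulate a multi-shank spindle session with ground truth
#'
#' Generates background Poisson firing plus spindle events at the configured
#' rate, with lengths drawn from the configured length distribution. Each
#' event is either local to one random shank (with probability
#' `spindle_locality`) or global, sharing its cycle-peak times across all
#' shanks. During an event, units on the participating shank(s) fire only
#' their spindle bursts (thalamic cells fire exclusively in low-threshold
#' bursts during spindles), so the trajectory table directly parameterises
#' the measurable per-cycle statistics.
#'
#' @param config a [session_config()].
#' @param trajectories trajectory table, see [default_trajectories()].
#' @param seed integer seed; the session is reproducible given
#'   `(config, trajectories, seed)`.
#' @return A list of class `"spindle_session"` with elements `spikes`
#'   (tibble: `unit_id`, `time_s`, `shank`, `class`, `width_us`), `units`,
#'   `ground_truth` (list: `events`, `participation`) and `config`.
#' @export
simulate_session <- function(config, trajectories = default_trajectories(),
                             seed = 1L) {
  if (config$duration_s <= 0) abort("duration must be positive")
  if (config$n_tc_units + config$n_nrt_units <= 0) abort("no units configured")
  set.seed(seed)
  units <- make_units(config)
  sched <- draw_event_onsets(config)
  n_ev <- length(sched$onset)

  events <- vector("list", n_ev)
  ev_spikes <- vector("list", n_ev)
  ev_part <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    k <- sched$length_k[i]
    geom <- event_geometry(k, sched$onset[i], config)
    local <- runif(1) < config$spindle_locality
    shanks <- if (local) sample.int(config$n_shanks, 1) else
      seq_len(config$n_shanks)
    sp_list <- vector("list", length(shanks))
    pt_list <- vector("list", length(shanks))
    traj_k <- trajectories[trajectories$length_k == k, ]
    traj_k <- traj_k[order(traj_k$cycle_index), ]
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
      provenance = "ground_truth"
    )
    ev_spikes[[i]] <- bind_rows(sp_list)
    ev_part[[i]] <- bind_rows(pt_list) %>% mutate(event_id = i)
  }
  events <- bind_rows(events)
  participation <- bind_rows(ev_part)

  # Background firing, suppressed inside events on the unit's shank(s).
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
    keep <- rep(TRUE, nrow(bg))
    for (i in seq_len(nrow(events))) {
      in_ev <- bg$time_s >= events$onset_s[i] & bg$time_s < events$offset_s[i]
      if (!is.na(events$shank[i])) {
        in_ev <- in_ev & bg$shank == events$shank[i]
      }
      keep <- keep & !in_ev
    }
    bg <- bg[keep, c("unit_id", "time_s")]
  }

  spikes <- bind_rows(bg, bind_rows(ev_spikes)) %>%
    left_join(units, by = "unit_id") %>%
    arrange(.data$unit_id, .data$time_s) %>%
    select("unit_id", "time_s", "shank", "class", "width_us")

  out <- list(spikes = spikes, units = units,
              ground_truth = list(events = events,
                                  participation = participation),
              config = config, seed = seed)
  class(out) <- "spindle_session"
  out
}

#' @export
print.spindle_session <- function(x, ...) {
  cat("<spindle_session>\n")
  cat("  duration:", x$config$duration_s, "s;",
      nrow(x$units), "units on", x$config$n_shanks, "shank(s)\n")
  cat("  spikes:", nrow(x$spikes), "  ground-truth events:",
      nrow(x$ground_truth$events), "\n")
  invisible(x)
}

#' Cycle windows of an event table
#'
#' Expands an event table (with a `peaks` list-column) into one row per
#' cycle with its half-open window `[start_s, end_s)` and peak time. Cycle
#' boundaries are the midpoints between adjacent peaks; the event onset and
#' offset close the first and last cycle.
#'
#' @param events event tibble (`event_id`, `onset_s`, `offset_s`,
#'   `n_cycles`, `peaks`).
#' @return Tibble with `event_id`, `n_cycles`, `cycle_index`, `start_s`,
#'   `end_s`, `peak_s`, and `shank` if present in `events`.
#' @export
cycle_windows <- function(events) {
  if (nrow(events) == 0) {
    return(tibble(event_id = integer(), n_cycles = integer(),
                  cycle_index = integer(), start_s = numeric(),
                  end_s = numeric(), peak_s = numeric()))
  }
  rows <- lapply(seq_len(nrow(events)), function(i) {
    pk <- events$peaks[[i]]
    k <- length(pk)
    mids <- if (k > 1) (pk[-1] + pk[-k]) / 2 else numeric(0)
    out <- tibble(event_id = events$event_id[i], n_cycles = k,
                  cycle_index = seq_len(k),
                  start_s = c(events$onset_s[i], mids),
                  end_s = c(mids, events$offset_s[i]),
                  peak_s = pk)
    if ("shank" %in% names(events)) out$shank <- events$shank[i]
    out
  })
  bind_rows(rows)
}
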