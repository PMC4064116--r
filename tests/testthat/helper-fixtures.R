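# Shared fixtures and independent oracles for the test suite.

# Memoised store so expensive simulations are built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small but fully featured natural-sleep session (one shank).
small_session <- function() {
  fixture("small_session", function() {
    cfg <- session_config(duration_s = 600)
    list(cfg = cfg,
         s = simulate_session(cfg, default_trajectories(), seed = 7))
  })
}

# A session plus its detected events and classified units.
detected_session <- function() {
  fixture("detected_session", function() {
    ss <- small_session()
    tr <- smooth_mua(ss$s$spikes$time_s[ss$s$spikes$shank == 1],
                     kernel_sd_ms = 10, dt_s = 0.002,
                     t_start = 0, t_end = ss$cfg$duration_s, shank = 1)
    ev <- detect_spindles(tr)
    list(cfg = ss$cfg, s = ss$s, trace = tr, events = ev)
  })
}

# The large end-to-end run shared by the acceptance tests: about 5,000
# natural-sleep spindles simulated in 10 sessions, detected and pooled.
acceptance_run <- function() {
  fixture("acceptance_run", function() {
    mets <- vector("list", 10)
    first_session <- NULL
    first_events <- NULL
    for (i in 1:10) {
      cfg <- session_config(duration_s = 2500)
      s <- simulate_session(cfg, default_trajectories(), seed = 1000 + i)
      tr <- smooth_mua(s$spikes$time_s[s$spikes$shank == 1], 10, 0.002,
                       0, cfg$duration_s, 1)
      ev <- detect_spindles(tr)
      un <- classify_units(s$units[, setdiff(names(s$units), "class")])
      if (i == 1) {
        first_session <- s
        first_events <- ev
      }
      mets[[i]] <- cycle_metrics(s$spikes, ev, un)
    }
    m <- dplyr::bind_rows(mets)
    traj <- m |>
      dplyr::group_by(length_k = n_cycles, cycle_index, population) |>
      dplyr::summarise(
        spikes_per_cycle = mean(spikes_per_cycle),
        participation = mean(participation),
        spikes_per_burst = sum(total_spikes) / pmax(sum(n_participating), 1),
        n_events = dplyr::n(),
        se_spc = sd(spikes_per_cycle) / sqrt(dplyr::n()),
        .groups = "drop") |>
      dplyr::filter(length_k %in% 5:14)
    list(metrics = m, trajectories = traj,
         first_session = first_session, first_events = first_events)
  })
}

# Per-(k, c) value and Monte-Carlo SE of nRT spikes/cycle from the pooled
# per-event metrics.
acc_spc <- function(run, k, c) {
  rows <- run$metrics[run$metrics$n_cycles == k &
                        run$metrics$cycle_index == c &
                        run$metrics$population == "nRT", ]
  list(value = mean(rows$spikes_per_cycle),
       se = sd(rows$spikes_per_cycle) / sqrt(nrow(rows)),
       n = nrow(rows))
}

# Brute-force per-cycle statistics for a set of events: plain loops over
# spikes, independent of the package's grouped/joined implementation.
brute_cycle_stats <- function(spikes, events, units, population) {
  uids <- units$unit_id[units$class == population]
  out <- list()
  for (i in seq_len(nrow(events))) {
    pk <- events$peaks[[i]]
    k <- length(pk)
    mids <- (pk[-1] + pk[-k]) / 2
    lo <- c(events$onset_s[i], mids)
    hi <- c(mids, events$offset_s[i])
    elig <- uids
    if (!is.na(events$shank[i])) {
      elig <- intersect(uids, units$unit_id[units$shank == events$shank[i]])
    }
    for (ci in seq_len(k)) {
      counts <- vapply(elig, function(u) {
        sum(spikes$unit_id == u &
              spikes$time_s >= lo[ci] & spikes$time_s < hi[ci])
      }, numeric(1))
      offs <- spikes$time_s[spikes$unit_id %in% elig &
                              spikes$time_s >= lo[ci] &
                              spikes$time_s < hi[ci]] - pk[ci]
      out[[length(out) + 1]] <- data.frame(
        event_id = events$event_id[i], cycle_index = ci,
        spikes_per_cycle = mean(counts),
        participation = mean(counts > 0),
        spikes_per_burst = if (any(counts > 0))
          mean(counts[counts > 0]) else NA_real_,
        jitter_ms = if (length(offs) > 0)
          sqrt(mean((offs - mean(offs))^2)) * 1000 else NA_real_
      )
    }
  }
  do.call(rbind, out)
}

# O(n^2) pair counting oracle for correlograms.
brute_correlogram <- function(reference, target, bin_ms, window_ms,
                              exclude_zero = FALSE) {
  lags <- as.vector(outer(target, reference, "-")) * 1000
  lags <- lags[abs(lags) <= window_ms]
  if (exclude_zero) lags <- lags[lags != 0]
  breaks <- seq(-window_ms, window_ms, by = bin_ms)
  hist(lags, breaks = breaks, plot = FALSE)$counts
}

# Build an mua_trace tibble directly from a numeric signal.
make_trace <- function(values, dt = 0.002, shank = 1L) {
  out <- tibble::tibble(time_s = (seq_along(values) - 1) * dt, rate = values)
  attr(out, "dt_s") <- dt
  attr(out, "shank") <- shank
  class(out) <- c("mua_trace", class(out))
  out
}
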