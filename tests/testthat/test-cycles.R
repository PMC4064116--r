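# Toy fixture: two 3-cycle events, two units per class, hand-placed spikes.
toy_data <- function() {
  pk1 <- c(1.0, 1.08, 1.16)
  pk2 <- c(3.0, 3.08, 3.16)
  events <- tibble::tibble(
    event_id = 1:2, onset_s = c(0.96, 2.96), offset_s = c(1.20, 3.20),
    shank = NA_integer_, n_cycles = 3L, peaks = list(pk1, pk2),
    provenance = "ground_truth")
  units <- tibble::tibble(unit_id = 1:4, shank = 1L,
                          class = c("TC", "TC", "nRT", "nRT"),
                          width_us = c(275, 280, 100, 95))
  spikes <- tibble::tibble(
    unit_id = c(1L, 1L, 2L, 3L, 3L, 3L, 4L, 1L, 3L),
    time_s = c(1.00, 1.005, 1.09, 1.017, 1.022, 1.095, 1.155, 3.005, 3.08),
    shank = 1L,
    class = c("TC", "TC", "TC", "nRT", "nRT", "nRT", "nRT", "TC", "nRT"),
    width_us = 0)
  list(events = events, units = units, spikes = spikes)
}

test_that("cycle metrics equal brute-force recomputation on toy events", {
  d <- toy_data()
  m <- cycle_metrics(d$spikes, d$events, d$units)
  for (pop in c("TC", "nRT")) {
    brute <- brute_cycle_stats(d$spikes, d$events, d$units, pop)
    got <- m[m$population == pop, ]
    got <- got[order(got$event_id, got$cycle_index), ]
    expect_equal(got$spikes_per_cycle, brute$spikes_per_cycle)
    expect_equal(got$participation, brute$participation)
    expect_equal(got$spikes_per_burst, brute$spikes_per_burst)
  }
  # explicit values: event 1 cycle 1 has TC unit 1 firing twice, unit 2 none
  r <- m[m$event_id == 1 & m$cycle_index == 1 & m$population == "TC", ]
  expect_equal(r$spikes_per_cycle, 1)         # 2 spikes / 2 units
  expect_equal(r$participation, 0.5)
  expect_equal(r$spikes_per_burst, 2)         # conditional on participation
})

test_that("metrics oracle also holds on simulated events", {
  d <- detected_session()
  ev <- d$events[1:8, ]
  m <- cycle_metrics(d$s$spikes, ev, d$s$units)
  for (pop in c("TC", "nRT")) {
    brute <- brute_cycle_stats(d$s$spikes, ev, d$s$units, pop)
    got <- m[m$population == pop, ]
    got <- got[order(got$event_id, got$cycle_index), ]
    brute <- brute[order(brute$event_id, brute$cycle_index), ]
    expect_equal(got$spikes_per_cycle, brute$spikes_per_cycle)
    expect_equal(got$participation, brute$participation)
  }
})

test_that("spikes/cycle = participation x spikes/burst wherever defined", {
  d <- detected_session()
  m <- cycle_metrics(d$s$spikes, d$events, d$s$units)
  pos <- m[m$participation > 0, ]
  expect_equal(pos$spikes_per_cycle,
               pos$participation * pos$spikes_per_burst,
               tolerance = 1e-12)
  # aggregated wrappers agree with each other on the same identity
  spc <- spikes_per_cycle(d$s$spikes, d$events, d$s$units, "nRT")
  pp <- participation_probability(d$s$spikes, d$events, d$s$units, "nRT")
  expect_equal(nrow(spc), nrow(pp))
})

test_that("jitter has the right degenerate values and pooled definition", {
  pk <- c(1.0, 1.08, 1.16)
  events <- tibble::tibble(event_id = 1L, onset_s = 0.96, offset_s = 1.2,
                           shank = NA_integer_, n_cycles = 3L,
                           peaks = list(pk), provenance = "ground_truth")
  units <- tibble::tibble(unit_id = 1:2, shank = 1L, class = "nRT",
                          width_us = 100)
  at_peaks <- tibble::tibble(unit_id = c(1L, 2L, 1L), time_s = pk,
                             shank = 1L, class = "nRT", width_us = 100)
  j0 <- spindle_jitter(at_peaks, events, units, "nRT")
  expect_true(all(j0$jitter_ms == 0))
  # offsets of -5 and +5 ms around one peak: population SD = 5 ms
  two <- tibble::tibble(unit_id = c(1L, 2L), time_s = c(0.995, 1.005),
                        shank = 1L, class = "nRT", width_us = 100)
  j2 <- spindle_jitter(two, events, units, "nRT")
  expect_equal(j2$jitter_ms[j2$cycle_index == 1], 5)
})

test_that("per-cycle CCG peaks at the simulator lag in every cycle", {
  d <- detected_session()
  cc <- cycle_ccg(d$s$spikes, d$events, d$s$units, bin_ms = 1,
                  window_ms = 50, lengths = c(6, 14))
  pk <- cc$peaks
  # precision commensurate with the per-cycle pair counts of this session
  big <- pk[pk$n_pairs >= 2000, ]
  expect_gt(nrow(big), 10)
  expect_true(all(abs(big$peak_lag_ms - 17) <= 3.51))
  expect_true(all(abs(pk$peak_lag_ms - 17) <= 10))
  # latency roughly constant across cycles of long spindles
  lat <- pk$peak_lag_ms[pk$length_k == 14]
  expect_lt(max(lat) - min(lat), 8)
  expect_error(cycle_ccg(d$s$spikes, d$events, d$s$units, bin_ms = 60,
                         window_ms = 50), "window")
})

test_that("cycle CCGs sum to the whole-event CCG (conservation)", {
  d <- toy_data()
  cc <- cycle_ccg(d$spikes, d$events, d$units, bin_ms = 2, window_ms = 30)
  summed <- cc$ccg |>
    dplyr::group_by(lag_ms) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  # whole-event CCG with the same in-event reference restriction
  tc <- d$spikes$time_s[d$spikes$class == "TC"]
  nrt <- sort(d$spikes$time_s[d$spikes$class == "nRT"])
  whole <- brute_correlogram(tc, nrt, 2, 30)
  expect_equal(summed$count, whole)
  # no nRT spikes -> all-zero histogram
  sp_tc <- d$spikes[d$spikes$class == "TC", ]
  cc0 <- cycle_ccg(sp_tc, d$events, d$units, bin_ms = 2, window_ms = 30)
  expect_true(all(cc0$ccg$count == 0))
})

test_that("phase locking recovers degenerate and lag-induced angles", {
  d <- toy_data()
  # spikes exactly at peaks: angle 0, resultant length 1
  at_pk <- unlist(d$events$peaks)
  pl <- phase_locking(at_pk, d$events)
  expect_equal(pl$mean_angle_deg %% 360, 0, tolerance = 1e-6)
  expect_equal(pl$vector_length, 1, tolerance = 1e-9)
  # uniform phases: resultant length near 0
  set.seed(6)
  unif <- runif(2000, d$events$onset_s[1], d$events$offset_s[1])
  expect_lt(phase_locking(unif, d$events[1, ])$vector_length, 0.12)
  # empty input flagged
  expect_equal(phase_locking(numeric(0), d$events)$n_spikes, 0)

  # simulator: nRT phase lags TC by ~ 360 * lag / period degrees
  s <- small_session()$s
  ev <- s$ground_truth$events
  tc <- phase_locking(s$spikes$time_s[s$spikes$class == "TC"], ev)
  nrt <- phase_locking(s$spikes$time_s[s$spikes$class == "nRT"], ev)
  dlt <- (nrt$mean_angle_deg - tc$mean_angle_deg) %% 360
  expected <- 360 * 17 / (1000 / s$config$base_freq_hz)   # ~ 77 deg
  expect_lt(abs(dlt - expected), 15)
  expect_gt(tc$vector_length, 0.3)
})

test_that("CCG modulation is local for shank-local spindles", {
  run <- fixture("spatial_sessions", function() {
    mk <- function(locality, seed) {
      cfg <- session_config(duration_s = 240, n_shanks = 4,
                            n_tc_units = 6, n_nrt_units = 6,
                            spindle_locality = locality)
      s <- simulate_session(cfg, default_trajectories(), seed = seed)
      ev <- s$ground_truth$events
      ev <- ev[!is.na(ev$shank), ]
      spatial_ccg_profile(s$spikes, ev, s$units, bin_ms = 2,
                          window_ms = 50, n_surrogate = 2)
    }
    set.seed(30)
    list(local = mk(1, 31))
  })
  prof <- run$local$profile
  m0 <- prof$modulation[prof$offset_shanks == 0]
  m2 <- prof$modulation[prof$offset_shanks == 2]
  expect_gt(m0, 1.5)                   # clear same-shank modulation
  expect_lt(abs(m2 - 1), 0.2)          # distant shanks at independence level
  expect_gt(m0, m2 * 1.5)              # decays with distance
  expect_true(all(is.finite(prof$modulation)))
  p400 <- run$local$tests$p_value[run$local$tests$offset_shanks == 2]
  expect_lt(p400, 0.05)
})

test_that("degenerate metric inputs are rejected or flagged", {
  d <- toy_data()
  expect_error(participation_probability(d$spikes, d$events,
                                         d$units[d$units$class == "TC", ],
                                         "nRT"),
               "no units")
  expect_error(cycle_metrics(d$spikes, d$events[0, ], d$units), "no events")
})
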