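test_that("degenerate config gives one spike per unit exactly at each peak", {
  cfg <- session_config(duration_s = 20, within_cycle_jitter_ms = 0,
                        n_tc_units = 3, n_nrt_units = 3)
  tr <- constant_trajectories(p_tc = 1, p_nrt = 1, b_tc = 1, b_nrt = 1)
  set.seed(1)
  out <- simulate_spindle(6, 5, 1, cfg, tr)
  pk <- out$event$peaks[[1]]
  expect_length(pk, 6)
  units <- unique(out$spikes$unit_id)
  expect_length(units, 6)
  for (u in units) {
    ts <- sort(out$spikes$time_s[out$spikes$unit_id == u])
    expect_length(ts, 6)
    lag <- if (u <= 3) 0 else cfg$tc_nrt_lag_ms / 1000
    expect_equal(ts, pk + lag, tolerance = 1e-9)
  }
})

test_that("sessions are reproducible and respect rate settings", {
  cfg <- session_config(duration_s = 120)
  a <- simulate_session(cfg, default_trajectories(), seed = 3)
  b <- simulate_session(cfg, default_trajectories(), seed = 3)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$ground_truth$events, b$ground_truth$events)

  silent <- simulate_session(session_config(duration_s = 60,
                                            spindle_rate = 0),
                             default_trajectories(), seed = 3)
  expect_equal(nrow(silent$ground_truth$events), 0)
  expect_gt(nrow(silent$spikes), 0)
})

test_that("event statistics match the configured study conditions", {
  s <- small_session()$s
  ev <- s$ground_truth$events
  expect_gt(nrow(ev), 50)
  # mean length ~ 10.7 cycles
  expect_equal(mean(ev$n_cycles), 10.7,
               tolerance = 3 * sd(ev$n_cycles) / sqrt(nrow(ev)) / 10.7)
  # mean intra-spindle frequency ~ 12.65 Hz
  freq <- vapply(ev$peaks,
                 function(p) (length(p) - 1) / (max(p) - min(p)), numeric(1))
  expect_equal(mean(freq), 12.65, tolerance = 0.02)
  # natural-sleep periods shorten early and lengthen at the end
  prof <- cycle_period_profile(12, "natural_sleep")
  expect_lt(prof[6], prof[1])
  expect_gt(prof[11], prof[6])
  expect_true(all(diff(cycle_period_profile(12, "urethane")) < 0))
})

test_that("spike widths reproduce the bimodal width distribution", {
  set.seed(11)
  w_nrt <- sample_spike_widths("nRT", 1e4)
  w_tc <- sample_spike_widths("TC", 1e4)
  expect_equal(mean(w_nrt), 100, tolerance = 0.01)
  expect_equal(mean(w_tc), 275, tolerance = 0.01)
  # analytic tail oracle: P(TC < 150) = pnorm((150 - 275) / 40) ~ 9e-4
  expect_lt(mean(w_tc < 150), 0.005)
  expect_lt(mean(w_nrt > 150), 0.005)
})

test_that("ground-truth participation equals a brute-force spike recount", {
  s <- small_session()$s
  gt <- s$ground_truth
  ev <- gt$events[1:5, ]
  for (i in seq_len(nrow(ev))) {
    pk <- ev$peaks[[i]]
    k <- length(pk)
    mids <- (pk[-1] + pk[-k]) / 2
    lo <- c(ev$onset_s[i], mids)
    hi <- c(mids, ev$offset_s[i])
    part <- gt$participation[gt$participation$event_id == ev$event_id[i], ]
    for (ci in seq_len(k)) {
      for (u in unique(part$unit_id)) {
        recount <- sum(s$spikes$unit_id == u &
                         s$spikes$time_s >= lo[ci] &
                         s$spikes$time_s < hi[ci])
        row <- part[part$unit_id == u & part$cycle_index == ci, ]
        expect_equal(row$n_spikes, recount)
        expect_equal(row$participates, recount > 0)
      }
    }
  }
})

test_that("empirical participation tracks the input table at every cell", {
  run <- fixture("participation_check", function() {
    cfg <- session_config(duration_s = 7500)
    s <- simulate_session(cfg, default_trajectories(), seed = 77)
    part <- s$ground_truth$participation |>
      dplyr::left_join(s$ground_truth$events[, c("event_id", "n_cycles")],
                       by = "event_id")
    part |>
      dplyr::group_by(length_k = n_cycles, cycle_index, class) |>
      dplyr::summarise(p_hat = mean(participates), n = dplyr::n(),
                       .groups = "drop")
  })
  truth <- tidy_trajectories(default_trajectories())
  j <- dplyr::inner_join(run, truth,
                         by = c("length_k", "cycle_index",
                                class = "population"))
  se <- sqrt(j$participation * (1 - j$participation) / j$n)
  z <- abs(j$p_hat - j$participation) / se
  # 3-SE check cell-wise; with ~240 cells a rare benign excursion is
  # expected under the null, so demand 97% within 3 SE and all within 4.5
  expect_gt(mean(z < 3), 0.97)
  expect_lt(max(z), 4.5)
})

test_that("population cross-correlogram peaks at the configured TC-nRT lag", {
  s <- small_session()$s
  ev <- s$ground_truth$events
  sp <- s$spikes
  in_event <- function(t) {
    idx <- findInterval(t, ev$onset_s)
    idx >= 1 & t < ev$offset_s[pmax(idx, 1)]
  }
  tc <- sort(sp$time_s[sp$class == "TC" & in_event(sp$time_s)])
  nrt <- sort(sp$time_s[sp$class == "nRT" & in_event(sp$time_s)])
  cc <- spindlr:::crosscorrelogram(tc, nrt, bin_ms = 1, window_ms = 50)
  peak <- cc$lag_ms[which.max(cc$count)]
  expect_lt(abs(peak - 17), 1.01)
})

test_that("invalid simulation requests are rejected", {
  cfg <- session_config(duration_s = 10)
  tr <- default_trajectories()
  expect_error(simulate_spindle(6, 9.8, 1, cfg, tr), "session end")
  expect_error(simulate_spindle(4, 1, 1, cfg, tr), "not present")
  expect_error(session_config(tc_nrt_lag_ms = 60), "half cycle")
  expect_error(session_config(duration_s = -1))
  expect_error(simulate_session(session_config(n_tc_units = 1,
                                               duration_s = 0)),
               "positive")
})
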