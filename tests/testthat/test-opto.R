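# A small optogenetic session reused across tests.
opto_session <- function() {
  fixture("opto_session", function() {
    cfg <- session_config(duration_s = 4000, spindle_rate = 4,
                          n_tc_units = 2, n_nrt_units = 2)
    pr <- stim_protocol(nonpermissive_epoch_s = 0)
    o <- simulate_opto_session(cfg, pr, default_trajectories(), seed = 55)
    m <- match_evoked(o$ground_truth$events,
                      o$stims[, c("stim_id", "onset_s", "intensity_mw",
                                  "duration_ms")])
    list(cfg = cfg, pr = pr, o = o, m = m)
  })
}

test_that("evoked-probability curve is thresholded, monotone and saturating", {
  pr <- stim_protocol()
  expect_equal(evoked_p_curve(0.05, pr), 0)        # below threshold
  ii <- c(0.14, 0.5, 1, 4.4, 10.5)
  p <- evoked_p_curve(ii, pr)
  expect_true(all(diff(p) >= 0))
  expect_lte(max(p), pr$evoked_p_max)
  expect_equal(evoked_p_curve(10.5, pr), 0.56, tolerance = 0.01)
})

test_that("match_evoked applies the response-window rule and partitions", {
  stims <- tibble::tibble(stim_id = 1:2, onset_s = c(10, 20),
                          intensity_mw = 5, duration_ms = 10)
  events <- tibble::tibble(
    event_id = 1:3, onset_s = c(10.1, 20.4, 30),
    offset_s = c(10.9, 21.2, 30.8), shank = NA_integer_,
    n_cycles = 8L, peaks = list(numeric(0), numeric(0), numeric(0)),
    provenance = "ground_truth")
  m <- match_evoked(events, stims, response_window_s = 0.3)
  expect_equal(m$events$evoked, c(TRUE, FALSE, FALSE))   # 0.4 s > window
  expect_equal(m$stims$evoked_event_id, c(1L, NA))
  expect_equal(m$stims$latency_s[1], 0.1)
  # partition: every event exactly once, no event both evoked & spontaneous
  expect_equal(sum(m$events$evoked) + sum(!m$events$evoked), nrow(events))
})

test_that("matching recovers the simulator's evoked labels", {
  d <- opto_session()
  truth <- d$o$stims$evoked_event_id
  got <- d$m$stims$evoked_event_id
  agree <- (is.na(truth) == is.na(got)) & (is.na(truth) | truth == got)
  expect_gt(mean(agree), 0.95)
})

test_that("probability curve recovers the evoked-response model", {
  d <- opto_session()
  pc <- probability_curve(d$m$stims)
  expect_equal(nrow(pc), 3)
  expect_true(all(diff(pc$p_evoked) >= -0.02))
  # each group's estimate consistent with the generating curve
  truth <- evoked_p_curve(pc$level, d$pr)
  expect_true(all(truth >= pc$ci_lo - 0.05 & truth <= pc$ci_hi + 0.05))
  # all-subthreshold stims evoke nothing
  stims0 <- tibble::tibble(stim_id = 1:40, onset_s = seq(5, 200, by = 5),
                           intensity_mw = rep(c(0.02, 0.05), 20),
                           duration_ms = 10, evoked_event_id = NA_integer_,
                           latency_s = NA_real_)
  pc0 <- probability_curve(stims0)
  expect_true(all(pc0$p_evoked == 0))
})

test_that("evoked lengths do not depend on the stimulus unless forced", {
  d <- opto_session()
  kw <- length_vs_stimulus(d$m$events, d$m$stims)
  expect_equal(kw$method, "kruskal_wallis")
  expect_gt(kw$p_value, 0.05)
  # positive control: force a length-intensity coupling
  ev <- d$m$events[d$m$events$evoked, ]
  st <- d$m$stims
  ev2 <- ev %>% dplyr::left_join(st[, c("stim_id", "intensity_mw")],
                                 by = "stim_id")
  ev2$n_cycles <- ev2$n_cycles + as.integer(round(ev2$intensity_mw))
  ev2$intensity_mw <- NULL
  kw2 <- length_vs_stimulus(ev2, st)
  expect_lt(kw2$p_value, 0.001)
  # single stimulus group is rejected
  st1 <- st
  st1$intensity_mw <- 5
  expect_error(length_vs_stimulus(ev, st1), "2 groups")
})

test_that("spontaneous-vs-evoked comparison tests tails and location", {
  set.seed(16)
  same <- spont_vs_evoked(rnorm(300, 850, 200), rnorm(300, 850, 200))
  expect_gt(same$p_value, 0.01)
  expect_equal(same$frac_short_spont, same$frac_short_evoked,
               tolerance = 0.3)
  # truncated evoked tails: spontaneous keeps the extremes
  spont <- rnorm(600, 850, 260)
  evoked <- spont[spont > 600 & spont < 1100][1:300]
  r <- spont_vs_evoked(spont, evoked)
  expect_gt(r$frac_short_spont, r$frac_short_evoked)
  expect_gt(r$frac_long_spont, r$frac_long_evoked)
  expect_error(spont_vs_evoked(1, c(2, 3)), "at least 2")
})

test_that("evoked lengths avoid the extreme categories when truncated", {
  cfg <- session_config(duration_s = 2000, spindle_rate = 4,
                        n_tc_units = 2, n_nrt_units = 2)
  pr <- stim_protocol(nonpermissive_epoch_s = 0,
                      truncate_evoked_lengths = TRUE)
  o <- simulate_opto_session(cfg, pr, default_trajectories(), seed = 56)
  ev <- o$ground_truth$events
  evoked_k <- ev$n_cycles[ev$provenance == "evoked"]
  spont_k <- ev$n_cycles[ev$provenance != "evoked"]
  expect_true(all(evoked_k >= 6 & evoked_k <= 13))
  expect_true(any(spont_k %in% c(5, 14)))
})

test_that("comodulation is detected when enabled and absent when disabled", {
  d <- opto_session()                      # modulation off
  cm0 <- comodulation(d$m$events)
  expect_lt(abs(cm0$r[1]), 0.15)
  # non-permissive epochs really block evoked responses
  pr2 <- stim_protocol(permissive_epoch_s = 60, nonpermissive_epoch_s = 60)
  o2 <- simulate_opto_session(
    session_config(duration_s = 1500, spindle_rate = 4,
                   n_tc_units = 1, n_nrt_units = 1),
    pr2, default_trajectories(), seed = 57)
  nonperm <- (o2$stims$onset_s %% 120) >= 60
  expect_true(all(is.na(o2$stims$evoked_event_id[nonperm])))
  expect_error(comodulation(d$m$events[1:5, ]), "too few")
})
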