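test_that("smooth_mua conserves spike mass", {
  tr1 <- smooth_mua(5, kernel_sd_ms = 10, dt_s = 0.001, t_end = 10)
  area <- sum(tr1$rate) * 0.001
  expect_equal(area, 1, tolerance = 1e-3)
  expect_equal(tr1$time_s[which.max(tr1$rate)], 5, tolerance = 0.002)
  # unimodal bump
  r <- tr1$rate[tr1$rate > max(tr1$rate) * 1e-6]
  expect_equal(sum(diff(sign(diff(r))) < 0), 1)

  set.seed(2)
  ts <- sort(runif(5000, 0, 100))
  tr2 <- smooth_mua(ts, 10, 0.002, t_end = 100)
  expect_equal(mean(tr2$rate), 50, tolerance = 0.05)

  expect_equal(sum(smooth_mua(numeric(0), 10, 0.002, t_end = 1)$rate), 0)
})

test_that("periodic burst train produces the right spectral peak", {
  f0 <- 12.9
  bursts <- seq(1, 59, by = 1 / f0)
  spikes <- sort(as.vector(outer(bursts, c(0, 0.004, 0.008), "+")))
  tr <- smooth_mua(spikes, 5, 0.002, t_end = 60)
  # package trace spectrum
  sp <- stats::spec.pgram(stats::ts(tr$rate, deltat = 0.002), taper = 0,
                          plot = FALSE)
  pk_trace <- sp$freq[which.max(sp$spec[sp$freq > 2])]
  sel <- sp$freq > 2
  pk_trace <- sp$freq[sel][which.max(sp$spec[sel])]
  # discrete Fourier oracle on the binned train itself
  dt <- 0.002
  binned <- tabulate(findInterval(spikes, seq(0, 60, by = dt)),
                     nbins = 60 / dt)
  ft <- Mod(fft(binned - mean(binned)))
  freqs <- (seq_along(ft) - 1) / (60)
  sel2 <- freqs > 2 & freqs < 100
  pk_oracle <- freqs[sel2][which.max(ft[sel2])]
  expect_equal(pk_oracle, f0, tolerance = 0.02)
  expect_equal(pk_trace, pk_oracle, tolerance = 0.02)
})

test_that("estimate_phase recovers frequency and peak phase of a sinusoid", {
  dt <- 0.002
  t <- seq(0, 20, by = dt)
  trace <- make_trace(100 + 30 * cos(2 * pi * 13 * t), dt)
  ph <- estimate_phase(trace)
  interior <- ph$time_s > 1 & ph$time_s < 19
  expect_true(all(abs(ph$freq_hz[interior] - 13) <= 0.5))
  # phase 0 at signal maxima (peak convention)
  peak_times <- seq(0, 20, by = 1 / 13)
  pk_idx <- round(peak_times / dt) + 1
  pk_idx <- pk_idx[pk_idx > 500 & pk_idx < length(t) - 500]
  expect_true(all(abs(ph$phase[pk_idx]) < 0.2))
})

test_that("chirp frequency estimate increases monotonically", {
  dt <- 0.002
  t <- seq(0, 30, by = dt)
  finst <- 10 + 5 * t / 30                     # analytic instantaneous freq
  phase <- 2 * pi * cumsum(finst) * dt
  trace <- make_trace(50 + 20 * cos(phase), dt)
  ph <- estimate_phase(trace)
  interior <- ph$time_s > 2 & ph$time_s < 28
  est <- ph$freq_hz[interior]
  # monotone increasing up to grid resolution, and close to the truth
  expect_true(all(diff(est) >= 0))
  expect_lt(max(abs(est - finst[interior])), 0.8)
})

test_that("segment_cycles counts sinusoid cycles and partitions the event", {
  dt <- 0.002
  t <- seq(0, 12, by = dt)
  f <- 11
  trace <- make_trace(80 + 25 * cos(2 * pi * f * t), dt)
  seg <- segment_cycles(trace, c(2, 8))
  expect_false(is.null(seg))
  expect_lte(abs(length(seg$peaks) - floor(f * 6)), 1)
  # boundaries partition [onset, offset] with no overlap
  pk <- seg$peaks
  mids <- (pk[-1] + pk[-length(pk)]) / 2
  bounds <- c(seg$onset_s, mids, seg$offset_s)
  expect_true(all(diff(bounds) > 0))
  expect_true(all(pk > bounds[-length(bounds)] & pk < bounds[-1]))
})

test_that("detector recovers ground-truth events with accurate cycle counts", {
  d <- detected_session()
  gt <- d$s$ground_truth$events
  ev <- d$events
  period <- 1 / d$cfg$base_freq_hz
  hit <- vapply(seq_len(nrow(gt)), function(i) {
    any(abs(ev$onset_s - gt$onset_s[i]) < period)
  }, logical(1))
  expect_gt(mean(hit), 0.9)
  # cycle-count distribution close to truth (total-variation distance)
  tv <- function(a, b) {
    ks <- 2:30
    pa <- tabulate(a, 30)[ks] / length(a)
    pb <- tabulate(b, 30)[ks] / length(b)
    sum(abs(pa - pb)) / 2
  }
  expect_lt(tv(ev$n_cycles, gt$n_cycles), 0.1)
  # estimated frequency of every event lies in the scanned band
  freq <- unlist(lapply(ev$peaks, function(p) 1 / diff(p)))
  expect_true(all(freq >= 7 & freq <= 20 + 1e-9))
})

test_that("no spindles are detected in pure background activity", {
  cfg <- session_config(duration_s = 600, spindle_rate = 0)
  s <- simulate_session(cfg, default_trajectories(), seed = 5)
  tr <- smooth_mua(s$spikes$time_s, 10, 0.002, t_end = 600, shank = 1)
  ev <- detect_spindles(tr)
  expect_lt(nrow(ev) / 10, 1)      # < 1 false event per minute
})

test_that("short oscillations below min_cycles are rejected", {
  dt <- 0.002
  t <- seq(0, 10, by = dt)
  x <- 60 + rep(0, length(t))
  burst <- t > 5 & t < 5 + 4 / 12          # 4 cycles at 12 Hz
  x[burst] <- 60 + 50 * sin(2 * pi * 12 * (t[burst] - 5))
  set.seed(9)
  trace <- make_trace(x + rnorm(length(t), 0, 2), dt)
  ev <- detect_spindles(trace, detection_config(min_cycles = 5))
  expect_equal(nrow(ev), 0)
  ev4 <- detect_spindles(trace, detection_config(min_cycles = 3))
  expect_gt(nrow(ev4), 0)
})

test_that("detection is translation-equivariant", {
  d <- detected_session()
  delta <- 50
  sp <- d$s$spikes$time_s[d$s$spikes$shank == 1] + delta
  tr2 <- smooth_mua(sp, 10, 0.002, t_start = delta,
                    t_end = d$cfg$duration_s + delta, shank = 1)
  ev2 <- detect_spindles(tr2)
  expect_equal(nrow(ev2), nrow(d$events))
  expect_equal(ev2$onset_s, d$events$onset_s + delta, tolerance = 1e-6)
  expect_equal(ev2$n_cycles, d$events$n_cycles)
})

test_that("cycle periods accelerate then decelerate in natural sleep", {
  d <- detected_session()
  traj <- cycle_length_trajectory(d$events)
  t10 <- traj[traj$length_k == 10, ]
  expect_equal(nrow(t10), 9)
  expect_lt(t10$mean_period_s[5], t10$mean_period_s[1])   # acceleration
  expect_gt(t10$mean_period_s[9], t10$mean_period_s[5])   # final slowing
  # constant-period generator gives a flat trajectory
  pk <- seq(0, by = 0.08, length.out = 11)
  flat_ev <- tibble::tibble(event_id = 1L, onset_s = -0.04,
                            offset_s = max(pk) + 0.04, shank = 1L,
                            n_cycles = 11L, peaks = list(pk),
                            provenance = "ground_truth")
  ft <- cycle_length_trajectory(flat_ev)
  expect_true(all(abs(ft$mean_period_s - 0.08) < 1e-9))
})

test_that("coherence behaves at its limits and tracks spindle locality", {
  d <- detected_session()
  tr <- d$trace
  expect_equal(shank_coherence(tr, tr), 1, tolerance = 1e-6)
  set.seed(4)
  n1 <- make_trace(rnorm(30000), 0.002)
  n2 <- make_trace(rnorm(30000), 0.002)
  expect_lt(shank_coherence(n1, n2), 0.1)
  expect_error(shank_coherence(n1, make_trace(rnorm(100), 0.002)),
               "equal length")

  run <- fixture("coherence_sessions", function() {
    mk <- function(locality, seed) {
      cfg <- session_config(duration_s = 300, n_shanks = 3,
                            n_tc_units = 6, n_nrt_units = 6,
                            spindle_locality = locality)
      s <- simulate_session(cfg, default_trajectories(), seed = seed)
      tr1 <- smooth_mua(s$spikes$time_s[s$spikes$shank == 1], 10, 0.002,
                        t_end = 300, shank = 1)
      tr3 <- smooth_mua(s$spikes$time_s[s$spikes$shank == 3], 10, 0.002,
                        t_end = 300, shank = 3)
      shank_coherence(tr1, tr3)
    }
    c(global = mk(0, 21), local = mk(1, 22))
  })
  expect_gt(run["global"], run["local"])
})
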