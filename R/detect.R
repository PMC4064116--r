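# Spindle detection from smoothed multiunit activity (MUA), per shank:
# Gaussian-kernel rate estimation, band-pass + analytic-signal envelope
# thresholding with two-pass robust baseline statistics, and Morlet-wavelet
# phase segmentation of each event into cycles.

#' Smooth spike times into a multiunit rate trace
#'
#' Gaussian-kernel rate estimate on a uniform grid. The integral of the
#' trace equals the number of spikes (each spike contributes a unit-area
#' Gaussian bump).
#'
#' @param spike_times numeric vector of spike times (seconds), any order.
#' @param kernel_sd_ms SD of the Gaussian kernel (milliseconds).
#' @param dt_s sampling step (seconds).
#' @param t_start,t_end grid limits (seconds); default 0 to
#'   `max(spike_times) + 4 kernel SD`.
#' @param shank optional shank id carried as an attribute.
#' @return A tibble of class `"mua_trace"` with columns `time_s`, `rate`
#'   (spikes/s) and attributes `dt_s` and `shank`.
#' @export
smooth_mua <- function(spike_times, kernel_sd_ms = 10, dt_s = 0.002,
                       t_start = 0, t_end = NULL, shank = NA_integer_) {
  sdv <- kernel_sd_ms / 1000
  if (is.null(t_end)) {
    t_end <- if (length(spike_times) == 0) t_start + 1 else
      max(spike_times) + 4 * sdv
  }
  grid <- seq(t_start, t_end, by = dt_s)
  n <- length(grid)
  counts <- numeric(n)
  if (length(spike_times) > 0) {
    idx <- findInterval(spike_times, grid - dt_s / 2)
    idx <- idx[idx >= 1 & idx <= n]
    tab <- tabulate(idx, nbins = n)
    half <- max(1L, ceiling(4 * sdv / dt_s))
    kt <- (-half:half) * dt_s
    kern <- exp(-kt^2 / (2 * sdv^2))
    kern <- kern / (sum(kern) * dt_s)          # unit area in spikes/s
    counts <- stats::filter(tab, kern, sides = 2)
    counts[is.na(counts)] <- 0
    # renormalise edges so rate integrates to the spike count
    counts <- as.numeric(counts)
  }
  out <- tibble(time_s = grid, rate = counts)
  attr(out, "dt_s") <- dt_s
  attr(out, "shank") <- shank
  class(out) <- c("mua_trace", class(out))
  out
}

# FFT band-pass with raised-cosine transitions; returns the analytic signal
# of the band-passed input (complex), so Mod() is the envelope and the real
# part the band-passed trace.
analytic_bandpass <- function(x, fs, lo, hi, transition = 2) {
  n <- length(x)
  nfft <- stats::nextn(n, 2)
  X <- fft(c(x - mean(x), rep(0, nfft - n)))
  f <- (seq_len(nfft) - 1) * fs / nfft
  # positive-frequency gain with cosine-tapered edges
  g <- numeric(nfft)
  pos <- f <= fs / 2
  fp <- f[pos]
  ramp_up <- (fp - (lo - transition)) / transition
  ramp_dn <- ((hi + transition) - fp) / transition
  gain <- pmin(pmax(ramp_up, 0), 1) * pmin(pmax(ramp_dn, 0), 1)
  gain <- sin(pi / 2 * gain)^2
  g[pos] <- 2 * gain                  # analytic: double positive freqs
  g[1] <- 0
  if (nfft %% 2 == 0) g[nfft / 2 + 1] <- gain[length(gain)]
  y <- fft(X * g, inverse = TRUE) / nfft
  y[seq_len(n)]
}

# Complex Morlet transform of a (short) demeaned signal at a set of
# frequencies. Kernels are L1-normalised so equal-amplitude oscillations
# give equal |W| at every frequency. Returns list(amp, phase, freq) where
# amp/phase are n x nfreq matrices.
morlet_transform <- function(x, dt, freqs, n_cycles = 6) {
  n <- length(x)
  amp <- matrix(0, n, length(freqs))
  ph <- matrix(0, n, length(freqs))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- ceiling(4 * sigma_t / dt)
    tt <- (-half:half) * dt
    w <- exp(1i * 2 * pi * f * tt - tt^2 / (2 * sigma_t^2))
    w <- w * dt / (sigma_t * sqrt(2 * pi))
    m <- length(w)
    nfft <- stats::nextn(n + m, 2)
    X <- fft(c(x, rep(0, nfft - n)))
    W <- fft(c(w, rep(0, nfft - m)))
    y <- fft(X * W, inverse = TRUE) / nfft
    y <- y[half + seq_len(n)]
    amp[, j] <- Mod(y)
    ph[, j] <- Arg(y)
  }
  list(amp = amp, phase = ph, freqs = freqs)
}

#' Instantaneous spindle phase and frequency from a Morlet transform
#'
#' At each sample the Morlet scale with maximal transform magnitude within
#' `[wavelet_lo_hz, wavelet_hi_hz]` provides the phase (radians; an
#' oscillation peak is phase 0) and the dominant frequency (Hz).
#'
#' @param trace a [smooth_mua()] trace.
#' @param config a [detection_config()].
#' @param freq_step_hz spacing of the scanned frequency grid (Hz).
#' @return A tibble `time_s`, `phase`, `freq_hz`, `amplitude`.
#' @export
estimate_phase <- function(trace, config = detection_config(),
                           freq_step_hz = 0.5) {
  dt <- attr(trace, "dt_s")
  freqs <- seq(config$wavelet_lo_hz, config$wavelet_hi_hz, by = freq_step_hz)
  mt <- morlet_transform(trace$rate - mean(trace$rate), dt, freqs)
  best <- max.col(mt$amp, ties.method = "first")
  idx <- cbind(seq_len(nrow(mt$amp)), best)
  tibble(time_s = trace$time_s,
         phase = mt$phase[idx],
         freq_hz = freqs[best],
         amplitude = mt$amp[idx])
}

# Unwrap phase and return the times where it crosses multiples of 2*pi
# (oscillation peaks), linearly interpolated between samples.
phase_peak_times <- function(time_s, phase) {
  uw <- phase
  d <- diff(phase)
  d[d > pi] <- d[d > pi] - 2 * pi
  d[d < -pi] <- d[d < -pi] + 2 * pi
  uw <- cumsum(c(phase[1], d))
  targets <- seq(ceiling(min(uw) / (2 * pi)), floor(max(uw) / (2 * pi)))
  if (length(targets) == 0) return(numeric(0))
  vapply(targets * 2 * pi, function(tg) {
    i <- which(uw[-length(uw)] <= tg & uw[-1] > tg)[1]
    if (is.na(i)) return(NA_real_)
    frac <- (tg - uw[i]) / (uw[i + 1] - uw[i])
    time_s[i] + frac * (time_s[i + 1] - time_s[i])
  }, numeric(1)) |> (\(v) v[!is.na(v)])()
}

#' Segment an event window into oscillation cycles
#'
#' Cycle peaks are the phase-zero crossings of the unwrapped Morlet phase
#' within the window; cycle boundaries are midpoints between adjacent peaks,
#' with the event onset/offset (half a local period outside the
#' first/last peak) closing the first and last cycle.
#'
#' @param trace a [smooth_mua()] trace (or a cropped window of one).
#' @param window numeric `c(start, end)` in seconds.
#' @param config a [detection_config()].
#' @return A list with `peaks` (times), `onset_s`, `offset_s` or `NULL`
#'   when fewer than two peaks are found.
#' @export
segment_cycles <- function(trace, window, config = detection_config()) {
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(sel) < 8) return(NULL)
  ph <- estimate_phase(trace[sel, ], config)
  pk <- phase_peak_times(ph$time_s, ph$phase)
  pk <- pk[pk >= window[1] & pk <= window[2]]
  if (length(pk) < 2) return(NULL)
  k <- length(pk)
  list(peaks = pk,
       onset_s = pk[1] - (pk[2] - pk[1]) / 2,
       offset_s = pk[k] + (pk[k] - pk[k - 1]) / 2)
}

# index runs above threshold, merged across short gaps
threshold_runs <- function(above, merge_gap_n) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) <= 1) return(runs)
  merged <- list(runs[1, ])
  for (i in 2:nrow(runs)) {
    lastr <- merged[[length(merged)]]
    if (runs[i, 1] - lastr[2] <= merge_gap_n) {
      merged[[length(merged)]] <- c(lastr[1], runs[i, 2])
    } else {
      merged[[length(merged)]] <- lastr
      merged[[length(merged) + 1]] <- runs[i, ]
    }
  }
  do.call(rbind, merged)
}

#' Detect spindle events in a rate trace
#'
#' Band-passes the trace in the spindle band, thresholds the analytic-signal
#' envelope at `baseline median + threshold_sd x robust SD` (baseline
#' statistics computed in two passes, excluding supra-threshold samples so
#' the spindles themselves do not inflate the threshold), merges events
#' separated by less than `merge_gap_ms`, segments each event into cycles
#' with [segment_cycles()], validates each candidate cycle peak against the
#' raw MUA rate (the local rate must rise above the baseline rate), and
#' discards events with fewer than `min_cycles` cycles.
#'
#' @param trace a [smooth_mua()] trace (duration >= 2 s).
#' @param config a [detection_config()].
#' @param peak_rate_sd cycle-peak validation threshold: multiples of the
#'   robust baseline-rate SD above the baseline median rate.
#' @return Event tibble: `event_id`, `onset_s`, `offset_s`, `shank`,
#'   `n_cycles`, `peaks` (list-column), `provenance = "detected"`.
#' @export
detect_spindles <- function(trace, config = detection_config(),
                            peak_rate_sd = 3) {
  dt <- attr(trace, "dt_s")
  if (diff(range(trace$time_s)) < 2) abort("trace must be at least 2 s long")
  x <- trace$rate
  fs <- 1 / dt
  an <- analytic_bandpass(x, fs, config$band_lo_hz, config$band_hi_hz)
  env <- Mod(an)

  thr1 <- median(env) + config$threshold_sd * mad(env)
  base <- env[env <= thr1]
  thr <- median(base) + config$threshold_sd * mad(base)
  above <- env > thr
  if (!any(above)) return(empty_events())

  runs <- threshold_runs(above, round(config$merge_gap_ms / 1000 / dt))
  min_dur_n <- round(0.5 * config$min_cycles / config$band_hi_hz / dt)
  runs <- runs[runs[, 2] - runs[, 1] >= min_dur_n, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_events())

  # robust baseline statistics of the locally averaged rate (+/-20 ms) for
  # cycle-peak validation; averaging suppresses background shot noise
  avg_half <- max(1L, round(0.02 / dt))
  wkern <- rep(1 / (2 * avg_half + 1), 2 * avg_half + 1)
  wx <- as.numeric(stats::filter(x, wkern, sides = 2))
  wx[is.na(wx)] <- 0
  dilate <- round(0.2 / dt)
  in_run <- rep(FALSE, length(x))
  for (i in seq_len(nrow(runs))) {
    in_run[max(1, runs[i, 1] - dilate):min(length(x), runs[i, 2] + dilate)] <- TRUE
  }
  rbase <- wx[!in_run]
  if (length(rbase) < 100) rbase <- wx
  rmed <- median(rbase)
  rsd <- max(mad(rbase), 1e-6)
  rate_thr <- rmed + peak_rate_sd * rsd

  pad <- 0.3
  t0 <- trace$time_s[1]
  events <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    wa <- t0 + (runs[i, 1] - 1) * dt - pad
    wb <- t0 + (runs[i, 2] - 1) * dt + pad
    seg <- segment_cycles(trace, c(max(wa, t0), min(wb, max(trace$time_s))),
                          config)
    if (is.null(seg)) next
    pk <- validate_peaks(seg$peaks, trace$time_s[1], wx, rate_thr, dt)
    k <- length(pk)
    if (k < config$min_cycles) next
    events[[i]] <- tibble(
      onset_s = pk[1] - (pk[2] - pk[1]) / 2,
      offset_s = pk[k] + (pk[k] - pk[k - 1]) / 2,
      shank = attr(trace, "shank"),
      n_cycles = k, peaks = list(pk), provenance = "detected"
    )
  }
  out <- bind_rows(events)
  if (nrow(out) == 0) return(empty_events())
  out <- out %>% arrange(.data$onset_s) %>%
    mutate(event_id = dplyr::row_number()) %>%
    select("event_id", dplyr::everything())
  out
}

empty_events <- function() {
  tibble(event_id = integer(), onset_s = numeric(), offset_s = numeric(),
         shank = integer(), n_cycles = integer(), peaks = list(),
         provenance = character())
}

# Keep the longest consecutive stretch of peaks whose local MUA rate rises
# above the baseline-derived threshold and whose spacing stays within the
# spindle band's period range.
validate_peaks <- function(peaks, t0, wx, rate_thr, dt) {
  if (length(peaks) == 0) return(peaks)
  n <- length(wx)
  ok <- vapply(peaks, function(p) {
    j <- min(max(round((p - t0) / dt) + 1, 1), n)
    wx[j] >= rate_thr
  }, logical(1))
  # spacing constraint: successive peaks within the spindle-band period range
  good_gap <- c(TRUE, diff(peaks) >= 0.05 & diff(peaks) <= 1 / 7)
  keep <- ok
  # find longest run where peaks valid and gaps valid within the run
  best <- integer(0)
  cur <- integer(0)
  for (i in seq_along(peaks)) {
    if (keep[i] && (length(cur) == 0 || good_gap[i])) {
      cur <- c(cur, i)
    } else {
      if (length(cur) > length(best)) best <- cur
      cur <- if (keep[i]) i else integer(0)
    }
  }
  if (length(cur) > length(best)) best <- cur
  peaks[best]
}

#' Mean cycle period per position, by spindle length
#'
#' Groups events by their cycle count and returns the mean and SEM of the
#' inter-peak interval at each cycle position.
#'
#' @param events event tibble with a `peaks` list-column.
#' @return Tibble `length_k`, `position` (interval index, 1 = between the
#'   first two peaks), `mean_period_s`, `sem_s`, `n`.
#' @export
cycle_length_trajectory <- function(events) {
  if (nrow(events) == 0) abort("no events supplied")
  rows <- lapply(seq_len(nrow(events)), function(i) {
    pk <- events$peaks[[i]]
    if (length(pk) < 2) return(NULL)
    tibble(length_k = length(pk), position = seq_len(length(pk) - 1),
           period_s = diff(pk))
  })
  bind_rows(rows) %>%
    group_by(.data$length_k, .data$position) %>%
    summarise(mean_period_s = mean(.data$period_s),
              sem_s = sd(.data$period_s) / sqrt(n()),
              n = n(), .groups = "drop")
}

#' Spindle-band coherence between two rate traces
#'
#' Mean magnitude-squared coherence across the spindle band, estimated with
#' a smoothed periodogram.
#'
#' @param trace_a,trace_b equal-length [smooth_mua()] traces.
#' @param band numeric `c(lo, hi)` in Hz.
#' @param spans smoothing spans passed to [stats::spec.pgram()].
#' @return A single coherence value in `[0, 1]`.
#' @export
shank_coherence <- function(trace_a, trace_b, band = c(7, 15),
                            spans = c(31, 31)) {
  if (nrow(trace_a) != nrow(trace_b)) abort("traces must have equal length")
  dt <- attr(trace_a, "dt_s")
  xx <- stats::ts(cbind(a = trace_a$rate, b = trace_b$rate), deltat = dt)
  sp <- stats::spec.pgram(xx, spans = spans, taper = 0.1, plot = FALSE,
                          detrend = TRUE)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  mean(sp$coh[sel])
}
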