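# Unit classification by extracellular spike width, burst detection and
# autocorrelograms. Wide spikes (> 150 microseconds at half amplitude) are
# thalamocortical (TC) relay cells; narrow spikes (< 150 microseconds) are
# nRT axon terminals recorded in the relay nucleus.

#' Spike width at half amplitude
#'
#' Width of the principal deflection of an extracellular mean waveform at
#' half of its peak amplitude, with linear interpolation between samples.
#' Works on either polarity (the larger absolute deflection is used).
#'
#' @param waveform numeric vector of waveform samples.
#' @param sampling_rate_hz sampling rate (Hz).
#' @return Width in microseconds, or `NA` for a flat waveform.
#' @export
spike_width <- function(waveform, sampling_rate_hz) {
  if (length(waveform) < 3 || diff(range(waveform)) == 0) return(NA_real_)
  w <- waveform - median(waveform)
  if (max(abs(w)) == 0) return(NA_real_)
  if (abs(min(w)) > abs(max(w))) w <- -w          # principal deflection up
  ipk <- which.max(w)
  half <- w[ipk] / 2
  # walk left and right from the peak to the half-amplitude crossings
  left <- NA_real_
  for (i in seq(ipk, 2)) {
    if (w[i - 1] <= half && w[i] >= half) {
      left <- (i - 1) + (half - w[i - 1]) / (w[i] - w[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk, length(w) - 1)) {
    if (w[i] >= half && w[i + 1] <= half) {
      right <- i + (w[i] - half) / (w[i] - w[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) / sampling_rate_hz * 1e6
}

#' Classify units by spike width
#'
#' Widths above 150 microseconds are TC cells, below 150 are nRT-axonal
#' units; exactly 150 (or `NA`) is left `"unknown"`.
#'
#' @param widths_us numeric vector of spike widths (microseconds), or a
#'   data frame with a `width_us` column.
#' @return For a numeric input, a character vector of classes; for a data
#'   frame, the data frame with a `class` column added/replaced.
#' @export
classify_units <- function(widths_us) {
  if (is.data.frame(widths_us)) {
    widths_us$class <- classify_units(widths_us$width_us)
    return(widths_us)
  }
  case_when(
    is.na(widths_us) ~ "unknown",
    widths_us > WIDTH_BOUNDARY_US ~ "TC",
    widths_us < WIDTH_BOUNDARY_US ~ "nRT",
    TRUE ~ "unknown"
  )
}

#' Detect bursts in a spike train
#'
#' A burst starts at a spike preceded by at least `pre_silence_ms` of
#' silence and continues while inter-spike intervals stay at or below
#' `isi_ceiling_ms` (conventional low-threshold-burst heuristics). Spikes
#' outside such clusters are counted as one-spike bursts, so every spike
#' belongs to exactly one burst.
#'
#' @param spike_times sorted numeric spike times (seconds).
#' @param isi_ceiling_ms maximum intra-burst inter-spike interval (ms).
#' @param pre_silence_ms minimum pre-burst silence (ms).
#' @return Tibble `burst_id`, `start_s`, `end_s`, `n_spikes`,
#'   `intra_burst_freq_hz` (`NA` for singletons).
#' @export
detect_bursts <- function(spike_times, isi_ceiling_ms = 15,
                          pre_silence_ms = 70) {
  n <- length(spike_times)
  if (n == 0) {
    return(tibble(burst_id = integer(), start_s = numeric(),
                  end_s = numeric(), n_spikes = integer(),
                  intra_burst_freq_hz = numeric()))
  }
  if (is.unsorted(spike_times)) abort("spike_times must be sorted")
  ceil_s <- isi_ceiling_ms / 1000
  pre_s <- pre_silence_ms / 1000
  isi_prev <- c(Inf, diff(spike_times))
  # a multi-spike burst can only begin where the pre-silence holds
  burst_id <- integer(n)
  cur <- 0L
  in_burst <- FALSE
  for (i in seq_len(n)) {
    if (in_burst && isi_prev[i] <= ceil_s) {
      burst_id[i] <- cur
    } else {
      cur <- cur + 1L
      burst_id[i] <- cur
      in_burst <- isi_prev[i] >= pre_s
    }
  }
  tibble(time_s = spike_times, burst_id = burst_id) %>%
    group_by(.data$burst_id) %>%
    summarise(start_s = min(.data$time_s), end_s = max(.data$time_s),
              n_spikes = n(), .groups = "drop") %>%
    mutate(intra_burst_freq_hz = if_else(
      .data$n_spikes > 1,
      (.data$n_spikes - 1) / (.data$end_s - .data$start_s),
      NA_real_))
}

#' Summary statistics of a burst table
#'
#' @param bursts output of [detect_bursts()].
#' @return One-row tibble: `n_bursts`, `mean_spikes_per_burst`,
#'   `mean_intra_burst_freq_hz` (`NA` when all bursts are singletons).
#' @export
burst_stats <- function(bursts) {
  if (nrow(bursts) == 0) abort("no bursts supplied")
  tibble(
    n_bursts = nrow(bursts),
    mean_spikes_per_burst = mean(bursts$n_spikes),
    mean_intra_burst_freq_hz =
      if (all(is.na(bursts$intra_burst_freq_hz))) NA_real_ else
        mean(bursts$intra_burst_freq_hz, na.rm = TRUE)
  )
}

#' Spike-train autocorrelogram
#'
#' Counts of spike pairs at signed lags, zero-lag (self) pairs excluded.
#' Symmetric by construction.
#'
#' @param spike_times sorted numeric spike times (seconds).
#' @param bin_ms lag bin width (ms).
#' @param window_ms maximum absolute lag (ms).
#' @return Tibble `lag_ms` (bin centres), `count`.
#' @export
autocorrelogram <- function(spike_times, bin_ms = 1, window_ms = 100) {
  if (bin_ms > window_ms) abort("bin must not exceed window")
  ts <- sort(spike_times)
  w <- window_ms / 1000
  n <- length(ts)
  # positive lags of all ordered pairs within the window (two-pointer sweep)
  lags <- vector("list", n)
  hi <- 1L
  for (i in seq_len(n)) {
    if (hi < i + 1L) hi <- i + 1L
    while (hi <= n && ts[hi] - ts[i] <= w) hi <- hi + 1L
    if (hi > i + 1L) lags[[i]] <- ts[(i + 1L):(hi - 1L)] - ts[i]
  }
  lags <- unlist(lags) * 1000
  lags <- lags[lags > 0]
  nb <- as.integer(ceiling(window_ms / bin_ms))
  pos <- if (length(lags) > 0) {
    tabulate(pmin(floor(lags / bin_ms) + 1L, nb), nbins = nb)
  } else rep(0L, nb)
  centres <- (seq_len(nb) - 0.5) * bin_ms
  tibble(lag_ms = c(-rev(centres), centres), count = c(rev(pos), pos))
}

# Pair-lag histogram of (target - reference); shared by auto- and
# cross-correlograms. Uses a two-pointer sweep, O(n + pairs).
crosscorrelogram <- function(reference, target, bin_ms = 1, window_ms = 50,
                             exclude_zero = FALSE) {
  if (bin_ms > window_ms) abort("bin must not exceed window")
  w <- window_ms / 1000
  breaks <- seq(-window_ms, window_ms, by = bin_ms)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- numeric(length(centres))
  if (length(reference) > 0 && length(target) > 0) {
    lo <- 1L
    nT <- length(target)
    lags <- vector("list", length(reference))
    for (i in seq_along(reference)) {
      r <- reference[i]
      while (lo <= nT && target[lo] < r - w) lo <- lo + 1L
      j <- lo
      if (j <= nT && target[j] <= r + w) {
        hi <- j
        while (hi < nT && target[hi + 1] <= r + w) hi <- hi + 1L
        lags[[i]] <- target[j:hi] - r
      }
    }
    lags <- unlist(lags)
    if (exclude_zero) lags <- lags[lags != 0]
    if (length(lags) > 0) {
      h <- hist(lags * 1000, breaks = breaks, plot = FALSE)
      counts <- h$counts
    }
  }
  tibble(lag_ms = centres, count = counts)
}
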