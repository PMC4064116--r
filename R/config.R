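#' Session configuration for the synthetic spindle generator
#'
#' Bundles every tunable of the ping-pong spindle simulator. Defaults emulate
#' natural-sleep recordings from multi-shank silicon probes in the
#' ventrobasal thalamus: 12.65 Hz mean intra-spindle frequency, a fixed
#' 17 ms TC-to-nRT lag, a length distribution over 5--14 cycles with mean
#' 10.7 cycles, and mostly shank-global events.
#'
#' @param n_tc_units,n_nrt_units units of each class per shank.
#' @param n_shanks number of electrode shanks.
#' @param shank_spacing_um spacing between neighbouring shanks (micrometers).
#' @param duration_s session duration in seconds.
#' @param spindle_rate spindle events per minute.
#' @param length_distribution numeric weights over length categories 5..14
#'   cycles; normalised internally. The default ramps linearly so the mean
#'   length is 10.7 cycles.
#' @param base_freq_hz mean intra-spindle oscillation frequency (Hz).
#' @param cycle_period_profile `"natural_sleep"` (periods shorten over the
#'   first cycles, then lengthen again before termination) or `"urethane"`
#'   (monotone acceleration). Modulation depth is +/-8% of the base period,
#'   normalised so the mean period is exactly `1/base_freq_hz`.
#' @param tc_nrt_lag_ms lag of nRT burst centres after TC burst centres /
#'   cycle peaks (milliseconds).
#' @param within_cycle_jitter_ms SD of the Gaussian jitter applied to burst
#'   centres (milliseconds).
#' @param background_rate_tc_hz,background_rate_nrt_hz per-unit homogeneous
#'   Poisson background rates (Hz).
#' @param intra_burst_isi_tc_ms,intra_burst_isi_nrt_ms fixed intra-burst
#'   inter-spike intervals (milliseconds). Values are chosen so bursts fit
#'   inside one oscillation cycle (one burst per cell per cycle).
#' @param spindle_locality probability that an event is confined to a single
#'   shank rather than appearing synchronously on all shanks.
#' @param min_event_gap_s minimum silent gap enforced between successive
#'   spindle events (seconds).
#' @return A list of class `"session_config"`.
#' @export
session_config <- function(n_tc_units = 12,
                           n_nrt_units = 12,
                           n_shanks = 1,
                           shank_spacing_um = 200,
                           duration_s = 600,
                           spindle_rate = 12,
                           length_distribution = default_length_distribution(),
                           base_freq_hz = 12.65,
                           cycle_period_profile = c("natural_sleep", "urethane"),
                           tc_nrt_lag_ms = 17,
                           within_cycle_jitter_ms = 4,
                           background_rate_tc_hz = 1.5,
                           background_rate_nrt_hz = 4,
                           intra_burst_isi_tc_ms = 6.7,
                           intra_burst_isi_nrt_ms = 8,
                           spindle_locality = 0.2,
                           min_event_gap_s = 0.5) {
  cycle_period_profile <- match.arg(cycle_period_profile)
  cfg <- list(
    n_tc_units = n_tc_units, n_nrt_units = n_nrt_units,
    n_shanks = n_shanks, shank_spacing_um = shank_spacing_um,
    duration_s = duration_s, spindle_rate = spindle_rate,
    length_distribution = length_distribution / sum(length_distribution),
    base_freq_hz = base_freq_hz,
    cycle_period_profile = cycle_period_profile,
    tc_nrt_lag_ms = tc_nrt_lag_ms,
    within_cycle_jitter_ms = within_cycle_jitter_ms,
    background_rate_tc_hz = background_rate_tc_hz,
    background_rate_nrt_hz = background_rate_nrt_hz,
    intra_burst_isi_tc_ms = intra_burst_isi_tc_ms,
    intra_burst_isi_nrt_ms = intra_burst_isi_nrt_ms,
    spindle_locality = spindle_locality,
    min_event_gap_s = min_event_gap_s
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

#' Default spindle-length distribution
#'
#' Linearly increasing weights over 5--14 cycles whose mean is 10.7
#' cycles/spindle, the mean spindle length of the natural-sleep condition.
#' @return Named numeric vector of normalised weights ("5".."14").
#' @export
default_length_distribution <- function() {
  k <- 5:14
  w <- 1 + 0.4210526 * (k - 5)
  w <- w / sum(w)
  names(w) <- as.character(k)
  w
}

validate_session_config <- function(cfg) {
  num_pos <- c("n_tc_units", "n_nrt_units", "n_shanks", "duration_s",
               "base_freq_hz", "intra_burst_isi_tc_ms", "intra_burst_isi_nrt_ms")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      abort(paste0("session_config$", f, " must be a positive scalar"))
    }
  }
  if (cfg$spindle_rate < 0) abort("spindle_rate must be >= 0")
  if (abs(sum(cfg$length_distribution) - 1) > 1e-8) {
    abort("length_distribution must sum to 1")
  }
  half_period_ms <- 500 / cfg$base_freq_hz
  if (cfg$tc_nrt_lag_ms <= 0 || cfg$tc_nrt_lag_ms >= half_period_ms) {
    abort("tc_nrt_lag_ms must lie in (0, half cycle period)")
  }
  if (cfg$spindle_locality < 0 || cfg$spindle_locality > 1) {
    abort("spindle_locality must be a probability")
  }
  invisible(cfg)
}

#' Detection configuration
#'
#' Parameters of MUA-based spindle detection and Morlet-phase cycle
#' segmentation.
#'
#' @param band_lo_hz,band_hi_hz spindle band for the band-pass filter (Hz).
#' @param wavelet_lo_hz,wavelet_hi_hz frequency range scanned by the Morlet
#'   transform when estimating phase (Hz).
#' @param smoothing_kernel_sd_ms SD of the Gaussian kernel used to smooth
#'   multiunit activity into a rate trace (milliseconds).
#' @param dt_s sampling step of the rate trace (seconds).
#' @param threshold_sd detection threshold in multiples of the robust SD of
#'   the baseline envelope above the baseline median.
#' @param min_cycles minimum number of oscillation cycles per event.
#' @param merge_gap_ms events separated by less than this gap are merged
#'   (milliseconds).
#' @return A list of class `"detection_config"`.
#' @export
detection_config <- function(band_lo_hz = 7, band_hi_hz = 15,
                             wavelet_lo_hz = 7, wavelet_hi_hz = 20,
                             smoothing_kernel_sd_ms = 10,
                             dt_s = 0.002,
                             threshold_sd = 2,
                             min_cycles = 5,
                             merge_gap_ms = 100) {
  if (band_lo_hz >= band_hi_hz) abort("band_lo_hz must be < band_hi_hz")
  if (min_cycles < 2) abort("min_cycles must be >= 2")
  cfg <- list(band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
              wavelet_lo_hz = wavelet_lo_hz, wavelet_hi_hz = wavelet_hi_hz,
              smoothing_kernel_sd_ms = smoothing_kernel_sd_ms,
              dt_s = dt_s, threshold_sd = threshold_sd,
              min_cycles = min_cycles, merge_gap_ms = merge_gap_ms)
  class(cfg) <- "detection_config"
  cfg
}

#' Optogenetic stimulation protocol
#'
#' Defines laser pulse trains and the evoked-spindle response model used by
#' [simulate_opto_session()]: pulses are delivered on a fixed grid, spindles
#' can only be evoked (and occur spontaneously) during permissive network
#' epochs, and the probability of evoking a spindle is a saturating logistic
#' function of log stimulus intensity while evoked spindle length is drawn
#' independently of the stimulus.
#'
#' @param intensities_mw vector of laser intensities cycled over pulses (mW).
#' @param durations_ms vector of pulse durations cycled over pulses (ms).
#' @param pulse_interval_s interval between successive pulses (seconds).
#' @param evoked_p_max saturation probability of the evoked-response curve.
#' @param intensity_i50_mw intensity at half saturation (mW).
#' @param slope logistic slope in log10-intensity units.
#' @param threshold_mw intensities strictly below this evoke nothing.
#' @param response_window_s evoked spindles begin within this window after
#'   pulse onset (seconds).
#' @param permissive_epoch_s,nonpermissive_epoch_s durations of alternating
#'   permissive / non-permissive network states (seconds).
#' @param length_comodulation amplitude (in cycles) of a slow shared
#'   sinusoidal modulation of spontaneous and evoked length means; 0
#'   disables it. The calibrated reference amplitude used in the package's
#'   comodulation analyses is 1.6 cycles.
#' @param comodulation_period_s period of the shared modulation (seconds).
#' @param truncate_evoked_lengths if `TRUE`, evoked lengths are redrawn to
#'   avoid the extreme length categories (shortest and longest spindles
#'   occur only spontaneously).
#' @return A list of class `"stim_protocol"`.
#' @export
stim_protocol <- function(intensities_mw = c(0.14, 4.4, 10.5),
                          durations_ms = 10,
                          pulse_interval_s = 5,
                          evoked_p_max = 0.56,
                          intensity_i50_mw = 0.5,
                          slope = 5,
                          threshold_mw = 0.1,
                          response_window_s = 0.3,
                          permissive_epoch_s = 120,
                          nonpermissive_epoch_s = 40,
                          length_comodulation = 0,
                          comodulation_period_s = 120,
                          truncate_evoked_lengths = FALSE) {
  if (any(intensities_mw <= 0)) abort("intensities must be positive")
  if (evoked_p_max < 0 || evoked_p_max > 1) abort("evoked_p_max must be in [0,1]")
  p <- list(intensities_mw = intensities_mw, durations_ms = durations_ms,
            pulse_interval_s = pulse_interval_s,
            evoked_p_max = evoked_p_max, intensity_i50_mw = intensity_i50_mw,
            slope = slope, threshold_mw = threshold_mw,
            response_window_s = response_window_s,
            permissive_epoch_s = permissive_epoch_s,
            nonpermissive_epoch_s = nonpermissive_epoch_s,
            length_comodulation = length_comodulation,
            comodulation_period_s = comodulation_period_s,
            truncate_evoked_lengths = truncate_evoked_lengths)
  class(p) <- "stim_protocol"
  p
}

#' Evoked-spindle probability as a function of stimulus intensity
#'
#' Saturating logistic in log10 intensity, hard-thresholded at
#' `protocol$threshold_mw`. Monotone nondecreasing in intensity.
#'
#' @param intensity_mw numeric vector of intensities (mW).
#' @param protocol a [stim_protocol()].
#' @return Probabilities in `[0, evoked_p_max]`.
#' @export
evoked_p_curve <- function(intensity_mw, protocol) {
  p <- protocol$evoked_p_max /
    (1 + exp(-protocol$slope *
               (log10(intensity_mw) - log10(protocol$intensity_i50_mw))))
  p[intensity_mw < protocol$threshold_mw] <- 0
  p
}
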