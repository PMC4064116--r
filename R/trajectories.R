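#' Built-in cycle-by-cycle activity trajectories
#'
#' Returns the default trajectory table that drives the synthetic spindle
#' generator: for every spindle length category `length_k` (5--14 cycles) and
#' cycle index, the participation probability (`p_tc`, `p_nrt`), mean spikes
#' per burst given participation (`b_tc`, `b_nrt`) and the resulting
#' unconditional mean spikes per cycle (`s_tc = p_tc * b_tc`,
#' `s_nrt = p_nrt * b_nrt`) for thalamocortical (TC) relay cells and
#' reticular-thalamic (nRT) axonal units.
#'
#' The table encodes the canonical ping-pong picture of rodent spindles:
#' short spindles open with high nRT recruitment (60% participation, 3.5
#' nRT spikes/cycle for 6-cycle events) that declines monotonically
#' (1.55 spikes/cycle by termination), while long spindles open from a lower
#' level (2.1 spikes/cycle for 14-cycle events), peak by cycle 3
#' (3.15 spikes/cycle) and collapse before termination (0.83 spikes/cycle).
#' nRT burst size declines over the spindle while TC burst size stays flat
#' and TC participation ramps up slowly. First-cycle nRT participation falls
#' with spindle length along a concave curve whose ten category values
#' correlate with length at r = -0.91; the last-cycle values give a
#' first-versus-last correlation of 0.88; TC first-cycle participation
#' carries a weak positive trend (r = 0.63).
#'
#' @param condition `"natural_sleep"` or `"urethane"`. The urethane table
#'   keeps the same participation/burst structure but is paired with a
#'   monotonically accelerating cycle-period profile by the simulator.
#' @return A tibble with columns `length_k`, `cycle_index`, `p_tc`, `p_nrt`,
#'   `b_tc`, `b_nrt`, `s_tc`, `s_nrt`.
#' @examples
#' tr <- default_trajectories()
#' dplyr::filter(tr, length_k == 6, cycle_index == 1)$s_nrt  # 3.5
#' @export
default_trajectories <- function(condition = c("natural_sleep", "urethane")) {
  condition <- match.arg(condition)
  k <- 5:14
  u <- (k - 5) / 9

  # nRT participation, cycle 1 and final cycle, per length category.
  # Curvature exponents are frozen so that the ten category means carry the
  # intended length correlations (see the methods vignette).
  p1_nrt <- 0.60 - 0.24 * u^0.3650805
  pend_nrt <- 0.47 - 0.24 * u^1.198761
  # plateau value reached by cycle 3 in long spindles
  ppk_nrt <- ifelse(k <= 6, NA_real_,
                    p1_nrt + (0.62 - p1_nrt[k == 14]) * (k - 6) / 8)

  # nRT spikes/cycle anchors: linear across k through the printed values
  s1_nrt <- 3.5 - 0.175 * (k - 6)
  send_nrt <- 1.55 - 0.09 * (k - 6)
  spk_nrt <- ifelse(k <= 6, NA_real_, s1_nrt + 1.05 * (k - 6) / 8)

  # TC participation: slow ramp 35-40% -> 40-45%; fixed first-cycle
  # deviations (orthogonal to the trend) set the length correlation to 0.63.
  tc_dev <- c(0.023982, -0.025110, -0.002701, 0.003275, -0.003192,
              -0.016695, 0.022938, -0.017927, 0.034078, -0.018647)
  p1_tc <- 0.35 + 0.05 * u + tc_dev
  pend_tc <- 0.40 + 0.05 * u
  b_tc <- 3.19

  rows <- lapply(seq_along(k), function(i) {
    kk <- k[i]
    cyc <- seq_len(kk)
    x <- (cyc - 1) / (kk - 1)
    if (kk <= 6) {
      p_nrt <- p1_nrt[i] + (pend_nrt[i] - p1_nrt[i]) * x
      s_nrt <- s1_nrt[i] + (send_nrt[i] - s1_nrt[i]) * x
    } else {
      # rise to the cycle-3 plateau, then decline to the endpoint
      p_nrt <- ifelse(cyc <= 3,
                      p1_nrt[i] + (ppk_nrt[i] - p1_nrt[i]) * (cyc - 1) / 2,
                      ppk_nrt[i] + (pend_nrt[i] - ppk_nrt[i]) * (cyc - 3) / (kk - 3))
      s_nrt <- ifelse(cyc <= 3,
                      s1_nrt[i] + (spk_nrt[i] - s1_nrt[i]) * (cyc - 1) / 2,
                      spk_nrt[i] + (send_nrt[i] - spk_nrt[i]) * (cyc - 3) / (kk - 3))
    }
    p_tc <- p1_tc[i] + (pend_tc[i] - p1_tc[i]) * x
    tibble(
      length_k = kk, cycle_index = cyc,
      p_tc = p_tc, p_nrt = p_nrt,
      b_tc = b_tc, b_nrt = s_nrt / p_nrt,
      s_tc = p_tc * b_tc, s_nrt = s_nrt
    )
  })
  out <- bind_rows(rows)
  validate_trajectories(out)
  out
}

#' Flat trajectory table for stationarity experiments
#'
#' A constant-participation, constant-burst-size table: every cycle of every
#' length category uses the same `p` and `b` for each population. Useful for
#' testing that synchrony measures (jitter, cross-correlogram latency) are
#' recovered as flat when the generator is stationary.
#'
#' @param p_tc,p_nrt participation probabilities in `[0, 1]`.
#' @param b_tc,b_nrt mean spikes per burst (>= 1).
#' @param lengths integer vector of length categories.
#' @return A trajectory tibble (see [default_trajectories()]).
#' @export
constant_trajectories <- function(p_tc = 0.4, p_nrt = 0.5,
                                  b_tc = 3.19, b_nrt = 5,
                                  lengths = 5:14) {
  out <- bind_rows(lapply(lengths, function(kk) {
    tibble(length_k = kk, cycle_index = seq_len(kk),
           p_tc = p_tc, p_nrt = p_nrt, b_tc = b_tc, b_nrt = b_nrt,
           s_tc = p_tc * b_tc, s_nrt = p_nrt * b_nrt)
  }))
  validate_trajectories(out)
  out
}

validate_trajectories <- function(tr) {
  stopifnot(all(c("length_k", "cycle_index", "p_tc", "p_nrt",
                  "b_tc", "b_nrt", "s_tc", "s_nrt") %in% names(tr)))
  if (any(tr$cycle_index > tr$length_k)) {
    abort("trajectory table has cycle_index > length_k")
  }
  if (any(tr$p_tc < 0 | tr$p_tc > 1 | tr$p_nrt < 0 | tr$p_nrt > 1)) {
    abort("participation probabilities must lie in [0, 1]")
  }
  if (any(tr$b_tc < 1 | tr$b_nrt < 1)) {
    abort("spikes per burst must be >= 1")
  }
  dev <- c(tr$s_tc - tr$p_tc * tr$b_tc, tr$s_nrt - tr$p_nrt * tr$b_nrt)
  if (any(abs(dev) > 0.05)) {
    abort("spikes/cycle must equal participation x spikes/burst within 0.05")
  }
  invisible(tr)
}
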