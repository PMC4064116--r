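# Trajectory-level statistics: correlations of first-cycle activity with
# spindle duration, first-versus-last-cycle correlations, trend tests
# across cycles, and rank tests. Correlations are computed on the per-length
# category means (one dot per length category, unweighted), without
# multiple-testing correction.

#' Convert a wide trajectory table to the long (measured) format
#'
#' Turns a [default_trajectories()]-style wide table into the long format
#' produced by [recovered_trajectories()], with one row per (length, cycle,
#' population).
#'
#' @param trajectories wide trajectory tibble.
#' @return Tibble `length_k`, `cycle_index`, `population`,
#'   `spikes_per_cycle`, `participation`, `spikes_per_burst`.
#' @export
tidy_trajectories <- function(trajectories) {
  bind_rows(
    trajectories %>%
      select("length_k", "cycle_index", participation = "p_tc",
             spikes_per_burst = "b_tc", spikes_per_cycle = "s_tc") %>%
      mutate(population = "TC"),
    trajectories %>%
      select("length_k", "cycle_index", participation = "p_nrt",
             spikes_per_burst = "b_nrt", spikes_per_cycle = "s_nrt") %>%
      mutate(population = "nRT")
  ) %>%
    select("length_k", "cycle_index", "population", "spikes_per_cycle",
           "participation", "spikes_per_burst")
}

as_long_trajectories <- function(trajectories) {
  if (all(c("p_tc", "p_nrt") %in% names(trajectories))) {
    tidy_trajectories(trajectories)
  } else {
    trajectories
  }
}

new_spindle_cor <- function(x, y, n, r, p, analysis, metric, population,
                            method = "pearson") {
  structure(
    list(r = r, p = p, n = n, pairs = tibble(x = x, y = y),
         analysis = analysis, metric = metric, population = population,
         method = method),
    class = "spindle_cor"
  )
}

cor_guarded <- function(x, y, method = "pearson") {
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = 0, p = 1))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation of first-cycle activity with spindle duration
#'
#' Pearson correlation between the spindle length category (number of
#' cycles, k = 5..14) and the cycle-1 category mean of the chosen metric,
#' one point per length category.
#'
#' @param trajectories long trajectory table ([recovered_trajectories()])
#'   or wide ([default_trajectories()]).
#' @param metric `"participation"`, `"spikes_per_burst"` or
#'   `"spikes_per_cycle"`.
#' @param population `"nRT"` or `"TC"`.
#' @return A `"spindle_cor"` object; see [tidy.spindle_cor()].
#' @export
first_cycle_vs_duration <- function(trajectories,
                                    metric = "participation",
                                    population = c("nRT", "TC")) {
  population <- match.arg(population)
  tr <- as_long_trajectories(trajectories)
  d <- tr %>%
    filter(.data$population == .env$population, .data$cycle_index == 1) %>%
    arrange(.data$length_k)
  d <- d[complete.cases(d[, c("length_k", metric)]), ]
  if (nrow(d) < 3) abort("need at least 3 length categories")
  res <- cor_guarded(d$length_k, d[[metric]])
  new_spindle_cor(d$length_k, d[[metric]], nrow(d), res$r, res$p,
                  "first_cycle_vs_duration", metric, population)
}

#' Correlation between first-cycle and last-cycle activity
#'
#' Pearson correlation, across length categories, between the cycle-1 and
#' final-cycle (cycle k of category k) category means of the chosen metric.
#'
#' @inheritParams first_cycle_vs_duration
#' @return A `"spindle_cor"` object.
#' @export
first_vs_last_cycle <- function(trajectories,
                                metric = "participation",
                                population = c("nRT", "TC")) {
  population <- match.arg(population)
  tr <- as_long_trajectories(trajectories)
  d <- tr %>%
    filter(.data$population == .env$population,
           .data$cycle_index == 1 | .data$cycle_index == .data$length_k)
  wide <- d %>%
    mutate(which = if_else(.data$cycle_index == 1, "first", "last")) %>%
    select("length_k", "which", dplyr::all_of(metric)) %>%
    tidyr::pivot_wider(names_from = "which",
                       values_from = dplyr::all_of(metric)) %>%
    arrange(.data$length_k)
  wide <- wide[complete.cases(wide), ]
  if (nrow(wide) < 3) abort("need at least 3 length categories")
  res <- cor_guarded(wide$first, wide$last)
  new_spindle_cor(wide$first, wide$last, nrow(wide), res$r, res$p,
                  "first_vs_last_cycle", metric, population)
}

#' Trend of a per-cycle metric across the spindle
#'
#' Spearman rank correlation of a metric (for example jitter or CCG peak
#' latency) against cycle index; ties are handled by mid-ranks.
#'
#' @param values numeric metric values, one per cycle.
#' @param cycle_index cycle indices (defaults to `seq_along(values)`).
#' @return A `"spindle_cor"` object (field `r` holds Spearman's rho).
#' @export
cycle_trend_test <- function(values, cycle_index = seq_along(values)) {
  keep <- is.finite(values)
  values <- values[keep]
  cycle_index <- cycle_index[keep]
  if (length(values) < 4) abort("need at least 4 cycles for a trend test")
  res <- cor_guarded(cycle_index, values, method = "spearman")
  new_spindle_cor(cycle_index, values, length(values), res$r, res$p,
                  "cycle_trend", "metric", "", method = "spearman")
}

#' Nonparametric comparison of groups
#'
#' Two groups: two-sided Mann-Whitney U (Wilcoxon rank-sum). Three or more:
#' Kruskal-Wallis.
#'
#' @param groups a list of numeric vectors, or a data frame with columns
#'   `value` and `group`.
#' @return One-row tibble `method`, `statistic`, `p_value`, `n_groups`, `n`.
#' @export
rank_tests <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(lengths(groups) == 0)) abort("empty group supplied")
  if (length(groups) == 2) {
    ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                       exact = FALSE))
    method <- "mann_whitney"
  } else {
    ht <- kruskal.test(groups)
    method <- "kruskal_wallis"
  }
  tibble(method = method, statistic = unname(ht$statistic),
         p_value = ht$p.value, n_groups = length(groups),
         n = sum(lengths(groups)))
}

#' @export
print.spindle_cor <- function(x, ...) {
  cat("<spindle_cor> ", x$analysis,
      if (nzchar(x$population)) paste0(" [", x$population, " ", x$metric, "]"),
      "\n", sep = "")
  cat(sprintf("  %s r = %.3f, p = %.4g, n = %d\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}

#' Tidy a spindle correlation result
#'
#' @param x a `"spindle_cor"` object.
#' @param ... unused.
#' @return One-row tibble `analysis`, `population`, `metric`, `method`,
#'   `estimate`, `p_value`, `n`.
#' @export
tidy.spindle_cor <- function(x, ...) {
  tibble(analysis = x$analysis, population = x$population,
         metric = x$metric, method = x$method,
         estimate = x$r, p_value = x$p, n = x$n)
}

#' @rdname tidy.spindle_cor
#' @export
glance.spindle_cor <- function(x, ...) tidy(x, ...)
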