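# The four lodging-resistance statistics.
#
# All integrals over the discrete lodging distribution are sums of point
# masses: the data exist only at the generated wind-speed levels, so
# int_0^s p(v) dv is the cumulative mass at speeds <= s. LR is
# right-continuous: a plant lodging at exactly s counts against resistance
# at s, because lodging is observed the moment the level is reached.

#' Wind-speed reduction index
#'
#' Fractional reduction of wind speed behind an obstacle (atmosphere or
#' maize canopy) relative to the machine outlet:
#' `RI = 1 - u1_mean / u0_mean`. Values can exceed 0 only up to 1 (full
#' blockage); negative values mean the downstream mean transiently exceeded
#' the outlet mean (gusts) and are returned unclamped.
#'
#' @param u0_mean Mean outlet speed (m/s), > 0.
#' @param u1_mean Mean downstream speed (m/s), >= 0.
#' @return Dimensionless reduction index, <= 1.
#' @export
reduction_index <- function(u0_mean, u1_mean) {
  stopifnot(is.numeric(u0_mean), is.numeric(u1_mean))
  if (any(u0_mean <= 0)) {
    stop("reduction index undefined for outlet mean <= 0", call. = FALSE)
  }
  if (any(u1_mean < 0)) stop("downstream mean must be >= 0", call. = FALSE)
  1 - u1_mean / u0_mean
}

#' Per-level reduction indices from anemometer logs
#'
#' For each level of the schedule, averages the outlet records over the
#' level's hold window to get the generated mean, averages the downstream
#' records of the requested layer (over time and stations) in the same
#' window, and forms the reduction index. Negative indices are kept but
#' flagged.
#'
#' @param outlet `anemometer_records` at the machine outlet (layer
#'   `"outlet"`).
#' @param downstream `anemometer_records` behind the canopy.
#' @param layer Which downstream layer to use: `"bottom"`, `"middle"` or
#'   `"top"`.
#' @param schedule A `wind_schedule` giving each level's hold window.
#' @return Data frame with columns `speed`, `layer`, `ri`, `flagged`.
#' @export
aggregate_reduction_index <- function(outlet, downstream, layer, schedule) {
  stopifnot(inherits(outlet, "anemometer_records"),
            inherits(downstream, "anemometer_records"),
            inherits(schedule, "wind_schedule"))
  if (!layer %in% c("bottom", "middle", "top")) {
    stop("layer must be one of bottom, middle, top", call. = FALSE)
  }
  out_rec <- outlet[outlet$layer == "outlet", , drop = FALSE]
  down_rec <- downstream[downstream$layer == layer, , drop = FALSE]
  ri <- numeric(nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    w0 <- out_rec$time_s >= schedule$t_start[k] &
      out_rec$time_s < schedule$t_end[k]
    w1 <- down_rec$time_s >= schedule$t_start[k] &
      down_rec$time_s < schedule$t_end[k]
    if (!any(w0)) {
      stop(sprintf("no outlet records in hold window of level %g m/s",
                   schedule$speed[k]), call. = FALSE)
    }
    if (!any(w1)) {
      stop(sprintf("no downstream '%s' records in hold window of level %g m/s",
                   layer, schedule$speed[k]), call. = FALSE)
    }
    ri[k] <- reduction_index(mean(out_rec$speed_ms[w0]),
                             mean(down_rec$speed_ms[w1]))
  }
  data.frame(speed = schedule$speed, layer = layer, ri = ri,
             flagged = ri < 0)
}

#' Cumulative lodged fraction
#'
#' The integral of the lodging distribution up to speed `s`: the sum of the
#' point masses at levels `v <= s`. The censored mass (plants standing at
#' S_m) is never included.
#'
#' @param dist A `lodging_distribution`.
#' @param s Wind speed in `[0, S_m]` (m/s).
#' @return Fraction of plants lodged at speeds up to `s`.
#' @export
cumulative_lodged_fraction <- function(dist, s) {
  stopifnot(inherits(dist, "lodging_distribution"))
  if (any(s < 0) || any(s > dist$s_max)) {
    stop(sprintf("s must lie in [0, %g]", dist$s_max), call. = FALSE)
  }
  vapply(s, function(si) sum(dist$masses[dist$speeds <= si]), numeric(1))
}

#' Lodging-resistance function LR(s)
#'
#' `LR(s) = 1 / (1 + int_0^s p(v) dv)` with p(v) as fractions, so LR runs
#' from 1 (nothing has lodged yet) down to 0.5 (every plant lodged at or
#' below `s`).
#'
#' @inheritParams cumulative_lodged_fraction
#' @return LR(s), dimensionless in `[0.5, 1]`.
#' @export
lodging_resistance <- function(dist, s) {
  1 / (1 + cumulative_lodged_fraction(dist, s))
}

#' Piecewise-constant lodging-resistance curve
#'
#' LR(s) is a right-continuous step function with a breakpoint at every
#' observed level: on a segment `[start, end)` the curve is constant; the
#' final segment is closed at S_m.
#'
#' @param dist A `lodging_distribution`.
#' @return Data frame of class `lodging_resistance_curve` with columns
#'   `start`, `end`, `lr`, one row per segment covering `(0, S_m]`.
#' @export
lodging_resistance_curve <- function(dist) {
  stopifnot(inherits(dist, "lodging_distribution"))
  breaks <- c(0, dist$speeds, dist$s_max)
  breaks <- breaks[!duplicated(breaks)]  # a bin at exactly S_m
  starts <- breaks[-length(breaks)]
  ends <- breaks[-1]
  lr <- 1 / (1 + cumsum(c(0, dist$masses))[seq_along(starts)])
  if (length(dist$speeds) > 0 && dist$speeds[length(dist$speeds)] == dist$s_max) {
    # mass at S_m still lowers the (degenerate) final value at s = S_m
    lr <- c(lr, 1 / (1 + sum(dist$masses)))
    starts <- c(starts, dist$s_max)
    ends <- c(ends, dist$s_max)
  }
  structure(data.frame(start = starts, end = ends, lr = lr),
            s_max = dist$s_max,
            class = c("lodging_resistance_curve", "data.frame"))
}

#' Failure wind speed (weighted L1 median)
#'
#' The failure wind speed of a cultivar is the minimizer over
#' `s in (0, S_m]` of the weighted L1 objective
#' `sum_v p(v) |v - s|`, i.e. the geometric (L1) median of the discrete
#' lodging distribution. Candidates are a regular grid of the given
#' resolution over `(0, S_m]` plus the observed bin speeds, because the
#' minimizer of the piecewise-linear objective need not coincide with an
#' observed level. Ties are broken toward the smallest candidate.
#'
#' Censored survivors enter the objective at the pseudo-speed
#' `S_m + censor_step` (one schedule step beyond the maximum, default
#' 2 m/s). When the minimum is attained at the boundary `s = S_m` and the
#' censored mass outweighs the lodged mass, the failure wind speed is not
#' identified within the tested range and the result is right-censored
#' ("> S_m").
#'
#' @param dist A `lodging_distribution`.
#' @param candidate_resolution Grid spacing for candidate speeds (m/s).
#' @param censor_step Offset of the censor pseudo-speed beyond S_m (m/s).
#' @return A list of class `fws_result` with fields `value` (m/s, `NA` when
#'   censored), `censored` (logical) and `s_max`.
#' @export
failure_wind_speed <- function(dist, candidate_resolution = 1,
                               censor_step = 2) {
  stopifnot(inherits(dist, "lodging_distribution"),
            candidate_resolution > 0, censor_step > 0)
  total <- sum(dist$masses) + dist$censored_mass
  if (total <= 0) stop("distribution has zero total mass", call. = FALSE)
  cand <- sort(unique(c(
    seq(candidate_resolution, dist$s_max, by = candidate_resolution),
    dist$speeds, dist$s_max)))
  v <- c(dist$speeds, dist$s_max + censor_step)
  p <- c(dist$masses, dist$censored_mass)
  obj <- vapply(cand, function(s) sum(p * abs(v - s)), numeric(1))
  tol <- 1e-9 * max(1, max(obj))
  minimizers <- cand[obj <= min(obj) + tol]
  at_boundary <- any(abs(minimizers - dist$s_max) <= tol)
  if (at_boundary && dist$censored_mass > sum(dist$masses)) {
    return(fws_result(NA_real_, censored = TRUE, s_max = dist$s_max))
  }
  fws_result(min(minimizers), censored = FALSE, s_max = dist$s_max)
}

#' Failure-wind-speed result
#'
#' @param value Speed in m/s, or `NA` when censored.
#' @param censored `TRUE` when the cultivar's failure speed exceeds the
#'   tested maximum ("> S_m").
#' @param s_max The schedule maximum the censoring refers to.
#' @return A list of class `fws_result`.
#' @export
fws_result <- function(value, censored = FALSE, s_max = 30) {
  if (!censored && (!is.finite(value) || value <= 0 || value > s_max)) {
    stop("uncensored FWS must lie in (0, s_max]", call. = FALSE)
  }
  structure(list(value = value, censored = censored, s_max = s_max),
            class = "fws_result")
}

#' @export
print.fws_result <- function(x, ...) {
  cat("FWS:", format(x), "m/s\n")
  invisible(x)
}

#' @export
format.fws_result <- function(x, ...) {
  if (x$censored) paste0("> ", x$s_max) else format(x$value)
}

#' Cumulative lodging index
#'
#' `CLI = (1 / S_m) * int_0^{S_m} LR(s) ds`, computed as the exact integral
#' of the piecewise-constant LR curve. CLI is 1 for a cultivar with no
#' lodging up to S_m and approaches 0.5 when all plants lodge immediately.
#' The censored mass never enters LR, so survivors raise CLI only by
#' withholding mass from the lodged bins.
#'
#' @param dist A `lodging_distribution`.
#' @return CLI, dimensionless in `[0.5, 1]`.
#' @export
cumulative_lodging_index <- function(dist) {
  stopifnot(inherits(dist, "lodging_distribution"))
  curve <- lodging_resistance_curve(dist)
  sum((curve$end - curve$start) * curve$lr) / dist$s_max
}
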