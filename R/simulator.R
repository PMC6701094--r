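# Synthetic wind-machine trials.
#
# The simulator emulates the field protocol: a stepped outlet wind schedule,
# distance- and layer-dependent attenuation behind the canopy, and a
# per-plant failure-threshold lodging model. Each plant draws a breaking
# threshold from a mixture of normals; at each level a standing plant lodges
# when the attenuated middle-layer (ear-height) speed at its position reaches
# its threshold. Lodging is recorded against the generated (outlet) level
# speed — the machine's bookkeeping — not the local attenuated speed.

# Evaluate an expression under a fixed seed without disturbing the caller's
# random-number stream.
run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Build the stepped wind schedule of a machine trial
#'
#' The outlet speed rises in coarse steps up to a change-over speed, then in
#' fine steps up to the maximum. Levels strictly below the change-over speed
#' are held longer than the faster levels. The defaults reproduce the
#' standard protocol: levels 5, 10, 12, 14, ..., 30 m/s with 30 s holds
#' below 10 m/s and 19 s holds at and above.
#'
#' @param max_speed Maximum generated speed S_m (m/s).
#' @param coarse_step Step size below `step_change_at` (m/s).
#' @param fine_step Step size from `step_change_at` upward (m/s).
#' @param step_change_at Speed at which the step size changes (m/s).
#' @param hold_coarse Hold duration for levels below `step_change_at` (s).
#' @param hold_fine Hold duration for levels at or above it (s).
#' @return A `wind_schedule`.
#' @export
build_wind_schedule <- function(max_speed = 30, coarse_step = 5,
                                fine_step = 2, step_change_at = 10,
                                hold_coarse = 30, hold_fine = 19) {
  stopifnot(max_speed >= step_change_at, coarse_step > 0, fine_step > 0,
            hold_coarse > 0, hold_fine > 0)
  speeds <- seq(coarse_step, step_change_at, by = coarse_step)
  if (max_speed > step_change_at) {
    speeds <- c(speeds, seq(step_change_at + fine_step, max_speed,
                            by = fine_step))
  }
  if (speeds[length(speeds)] < max_speed) {
    warning(sprintf("step does not divide the range; final level clamped to %g m/s",
                    max_speed), call. = FALSE)
    speeds <- c(speeds, max_speed)
  }
  holds <- ifelse(speeds < step_change_at, hold_coarse, hold_fine)
  wind_schedule(speeds, holds, s_max = max_speed)
}

#' Wind-speed attenuation profile
#'
#' Per-layer reduction indices at a near and a far anchor distance from the
#' outlet, with linear interpolation in distance between them. The defaults
#' are the open-field (no canopy) attenuation measured between 2 m and 7 m:
#' the bottom layer, slowed by ground drag, already loses 22% at 2 m, while
#' all three layers lose about two thirds of the outlet speed by 7 m.
#'
#' @param bottom,middle,top Length-2 numeric vectors `c(RI_near, RI_far)`
#'   in `[0, 1]` with `RI_far >= RI_near`.
#' @param d_near,d_far Anchor distances from the outlet (m).
#' @return A list of class `attenuation_profile`.
#' @export
attenuation_profile <- function(bottom = c(0.22, 0.59),
                                middle = c(0.02, 0.65),
                                top = c(0.02, 0.66),
                                d_near = 2, d_far = 7) {
  layers <- list(bottom = bottom, middle = middle, top = top)
  for (nm in names(layers)) {
    ri <- layers[[nm]]
    stopifnot(length(ri) == 2, all(ri >= 0), all(ri <= 1))
    if (ri[2] < ri[1]) {
      stop(nm, " layer: far RI must be >= near RI", call. = FALSE)
    }
  }
  stopifnot(d_near > 0, d_far > d_near)
  structure(c(layers, list(d_near = d_near, d_far = d_far)),
            class = "attenuation_profile")
}

# Interpolated reduction index at a distance, for one layer.
profile_ri <- function(profile, distance, layer) {
  stopifnot(inherits(profile, "attenuation_profile"))
  if (!layer %in% c("bottom", "middle", "top")) {
    stop("layer must be one of bottom, middle, top", call. = FALSE)
  }
  ri <- profile[[layer]]
  d <- pmax(distance, profile$d_near)  # below the near anchor: use RI(d_near)
  ri[1] + (ri[2] - ri[1]) * (d - profile$d_near) /
    (profile$d_far - profile$d_near)
}

#' Attenuate an outlet wind speed to a downstream position
#'
#' `u(d) = u0 * (1 - RI(d, layer))` with the profile's reduction index
#' linearly interpolated in distance. Distances below the near anchor use
#' the near-anchor index; distances beyond the far anchor are outside the
#' validated range and raise an error.
#'
#' @param u0 Outlet speed (m/s), >= 0.
#' @param distance Distance from the outlet (m), in `(0, d_far]`.
#' @param layer `"bottom"`, `"middle"` or `"top"`.
#' @param profile An `attenuation_profile`.
#' @return Attenuated speed (m/s).
#' @export
attenuate <- function(u0, distance, layer, profile = attenuation_profile()) {
  stopifnot(all(u0 >= 0))
  if (any(distance <= 0) || any(distance > profile$d_far)) {
    stop(sprintf("distance must lie in (0, %g] m", profile$d_far),
         call. = FALSE)
  }
  u0 * (1 - profile_ri(profile, distance, layer))
}

#' Cultivar simulation specification
#'
#' Parameters of the per-plant failure-threshold model for one cultivar.
#' Thresholds are drawn from a K-component normal mixture; a unimodal
#' mixture gives a single-peaked lodging distribution, two well-separated
#' components give the bimodal shapes seen in some cultivars, and a mean
#' far above the schedule maximum leaves nearly all plants standing
#' (censored).
#'
#' @param cultivar Cultivar identifier.
#' @param mixture Data frame with columns `weight`, `mean`, `sd` (weights
#'   >= 0 summing to 1, sds > 0; means in m/s).
#' @param n_plants Plants in the targeted two rows. The default 84 follows
#'   the planting density of six plants per square meter in two 7-m rows
#'   spaced 0.6 m apart.
#' @param row_positions Plant distances from the outlet (m), recycled over
#'   plants; defaults to plants evenly spaced along `(0, 7]`.
#' @param noise_sd Gaussian anemometer noise standard deviation (m/s),
#'   truncated at zero.
#' @param knockdown_prob Probability that a lodging plant knocks down each
#'   standing neighbour at the same level (domino effect); the default 0
#'   disables contagion.
#' @return A list of class `cultivar_sim_spec`.
#' @export
cultivar_sim_spec <- function(cultivar, mixture, n_plants = 84,
                              row_positions = NULL, noise_sd = 0.5,
                              knockdown_prob = 0) {
  mixture <- as.data.frame(mixture)
  stopifnot(all(c("weight", "mean", "sd") %in% names(mixture)),
            nrow(mixture) >= 1, n_plants >= 1, noise_sd >= 0,
            knockdown_prob >= 0, knockdown_prob <= 1)
  if (any(mixture$weight < 0) || abs(sum(mixture$weight) - 1) > 1e-9) {
    stop("mixture weights must be >= 0 and sum to 1", call. = FALSE)
  }
  if (any(mixture$sd <= 0)) stop("mixture sds must be > 0", call. = FALSE)
  if (is.null(row_positions)) {
    row_positions <- seq(0.5, 7, length.out = ceiling(n_plants / 2))
  }
  if (any(row_positions <= 0) || any(row_positions > 7)) {
    stop("row positions must lie in (0, 7] m", call. = FALSE)
  }
  structure(list(cultivar = as.character(cultivar), mixture = mixture,
                 n_plants = as.integer(n_plants),
                 row_positions = rep_len(row_positions, n_plants),
                 noise_sd = noise_sd, knockdown_prob = knockdown_prob),
            class = "cultivar_sim_spec")
}

#' Simulate anemometer logs for one trial
#'
#' Emits 1 Hz readings for the whole schedule: an outlet record per second
#' of each hold, plus bottom/middle/top records at a downstream station,
#' attenuated through the profile. Readings carry additive Gaussian noise
#' truncated at zero.
#'
#' @param schedule A `wind_schedule`.
#' @param profile An `attenuation_profile`.
#' @param distance Downstream station distance from the outlet (m).
#' @param noise_sd Noise standard deviation (m/s); 0 gives exact speeds.
#' @param seed Integer seed.
#' @return A list with `outlet` and `downstream` `anemometer_records`.
#' @export
simulate_anemometer_logs <- function(schedule, profile = attenuation_profile(),
                                     distance = 7, noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(schedule, "wind_schedule"))
  run_seeded(seed, {
    times <- unlist(lapply(seq_len(nrow(schedule)), function(k) {
      schedule$t_start[k] + seq_len(schedule$hold_duration[k]) - 1
    }))
    speeds <- rep(schedule$speed, schedule$hold_duration)
    noisy <- function(u) pmax(0, u + stats::rnorm(length(u), 0, noise_sd))
    outlet <- anemometer_records(times, rep("outlet", length(times)),
                                 rep(NA_real_, length(times)), noisy(speeds))
    layers <- c("bottom", "middle", "top")
    down <- do.call(rbind, lapply(layers, function(ly) {
      anemometer_records(times, rep(ly, length(times)),
                         rep(distance, length(times)),
                         noisy(attenuate(speeds, distance, ly, profile)))
    }))
    class(down) <- c("anemometer_records", "data.frame")
    list(outlet = outlet, downstream = down)
  })
}

#' Simulate one wind-machine trial for a cultivar
#'
#' Each plant draws a mixture component and then a breaking threshold, in
#' plant-index order (the reproducibility contract). Levels are applied in
#' schedule order; a standing plant lodges at the first level whose
#' attenuated middle-layer speed at the plant's position reaches its
#' threshold, and is recorded against that level's generated speed. With a
#' positive `knockdown_prob`, each plant lodging at a level then knocks
#' down standing neighbours with that probability, at the same level.
#' Plants still standing after the last level are censored. Anemometer
#' logs are emitted at the outlet and at the far downstream station.
#'
#' @param spec A `cultivar_sim_spec`.
#' @param schedule A `wind_schedule`.
#' @param profile An `attenuation_profile`, or `NULL` for no attenuation
#'   (plants see the outlet speed directly).
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @param year Year label attached to the observations.
#' @return A list of class `simulated_trial`: `observations`
#'   (`lodging_observations`), `anemometer` (list of outlet/downstream
#'   records), `thresholds`, and `seed`.
#' @export
simulate_trial <- function(spec, schedule = build_wind_schedule(),
                           profile = attenuation_profile(), seed = 1,
                           year = 2016L) {
  stopifnot(inherits(spec, "cultivar_sim_spec"),
            inherits(schedule, "wind_schedule"))
  run_seeded(seed, {
    n <- spec$n_plants
    comp <- sample.int(nrow(spec$mixture), n, replace = TRUE,
                       prob = spec$mixture$weight)
    thresholds <- stats::rnorm(n, spec$mixture$mean[comp],
                               spec$mixture$sd[comp])
    local_speed <- function(level_speed) {
      if (is.null(profile)) rep(level_speed, n)
      else attenuate(level_speed, spec$row_positions, "middle", profile)
    }
    lodged_at <- rep(NA_real_, n)
    for (k in seq_len(nrow(schedule))) {
      standing <- is.na(lodged_at)
      hit <- standing & local_speed(schedule$speed[k]) >= thresholds
      lodged_at[hit] <- schedule$speed[k]
      if (spec$knockdown_prob > 0 && any(hit)) {
        standing <- is.na(lodged_at)
        knocked <- standing &
          stats::runif(n) < 1 - (1 - spec$knockdown_prob)^sum(hit)
        lodged_at[knocked] <- schedule$speed[k]
      }
    }
    counts <- table(factor(lodged_at, levels = schedule$speed))
    obs <- lodging_observations(
      cultivar = rep(spec$cultivar, nrow(schedule) + 1L),
      year = rep(year, nrow(schedule) + 1L),
      level_speed = c(schedule$speed, NA_real_),
      lodged_count = c(as.integer(counts), sum(is.na(lodged_at))))
    zero_profile <- attenuation_profile(bottom = c(0, 0), middle = c(0, 0),
                                        top = c(0, 0))
    anem <- simulate_anemometer_logs(
      schedule, profile %||% zero_profile,
      distance = max(spec$row_positions), noise_sd = spec$noise_sd,
      seed = seed + 1L)
    structure(list(observations = obs, anemometer = anem,
                   thresholds = thresholds, seed = seed),
              class = "simulated_trial")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset cultivar library
#'
#' Six simulation presets qualitatively mimicking the lodging-percentage
#' shapes observed across cultivars: unimodal peaks near 20 and near 26
#' m/s, bimodal mixtures at 12/24 and 20/30 m/s, and two
#' nearly-all-censored cultivars whose thresholds sit well above the
#' 30 m/s schedule maximum.
#'
#' @param n_plants Plants per trial for every preset.
#' @return Named list of `cultivar_sim_spec` objects.
#' @export
preset_cultivars <- function(n_plants = 84) {
  mix <- function(w, m, s) data.frame(weight = w, mean = m, sd = s)
  specs <- list(
    jk665_like = cultivar_sim_spec("JK665like", mix(1, 20, 2.5), n_plants),
    jk968_like = cultivar_sim_spec("JK968like", mix(1, 26, 2.5), n_plants),
    xd20_like = cultivar_sim_spec("XD20like",
                                  mix(c(0.55, 0.45), c(12, 24), c(1.5, 2)),
                                  n_plants),
    zd958_like = cultivar_sim_spec("ZD958like",
                                   mix(c(0.5, 0.5), c(20, 30), c(1.5, 2)),
                                   n_plants),
    jd38_like = cultivar_sim_spec("JD38like", mix(1, 38, 3), n_plants),
    xy335_like = cultivar_sim_spec("XY335like", mix(1, 36, 3), n_plants)
  )
  specs
}
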