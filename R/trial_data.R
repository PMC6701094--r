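# Domain types and CSV readers/writers for wind-machine lodging trials.
#
# Conventions shared by all tables:
#   * comma-separated, UTF-8, header row required, "NA" for not-applicable;
#   * decimal point only (locale-independent parsing via as.numeric);
#   * lodging percentages are stored as fractions in [0, 1], never 0-100.

CENSORED_TOKEN <- ">Smax"
ANEMOMETER_LAYERS <- c("outlet", "bottom", "middle", "top")

# Trait columns of the cultivar trait table (means and standard errors of
# stalk mechanical properties from three-point bending plus phenotypic traits).
TRAIT_NAMES <- c(
  "youngs_modulus", "max_bending_load", "max_transverse_displacement",
  "plant_height", "plant_azimuthal_deviation", "leaf_number",
  "leaf_inclination_angle", "ear_number", "ear_height", "ear_length"
)

num_or_na <- function(x) suppressWarnings(as.numeric(x))

stop_row <- function(row, msg) {
  stop(sprintf("row %d: %s", row, msg), call. = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Wind level
#'
#' A single step of a wind schedule: a generated wind speed held for a fixed
#' duration.
#'
#' @param speed Generated wind speed at the machine outlet (m/s), > 0.
#' @param hold_duration Seconds the level is maintained, > 0.
#' @return A list of class `wind_level`.
#' @export
wind_level <- function(speed, hold_duration) {
  stopifnot(is.numeric(speed), length(speed) == 1L, is.finite(speed),
            is.numeric(hold_duration), length(hold_duration) == 1L)
  if (speed <= 0) stop("wind level speed must be > 0", call. = FALSE)
  if (hold_duration <= 0) stop("hold_duration must be > 0", call. = FALSE)
  structure(list(speed = speed, hold_duration = hold_duration),
            class = "wind_level")
}

#' Wind schedule
#'
#' The ordered sequence of generated wind-speed levels used in a trial, each
#' held for a fixed duration. The machine steps through the levels back to
#' back, so level `i` occupies the time window starting at the sum of the
#' previous holds.
#'
#' @param speeds Strictly increasing generated speeds (m/s).
#' @param hold_durations Hold time per level (s), recycled if scalar.
#' @param s_max Maximum generated speed of the schedule (m/s); must equal the
#'   last level. Defaults to the last speed. The machine safety cap is
#'   30 m/s, so values above 30 trigger a warning.
#' @return An object of class `wind_schedule`: a data frame with columns
#'   `speed`, `hold_duration`, `t_start`, `t_end`, and attribute `s_max`.
#' @export
wind_schedule <- function(speeds, hold_durations, s_max = NULL) {
  stopifnot(is.numeric(speeds), length(speeds) >= 1L,
            all(is.finite(speeds)), is.numeric(hold_durations))
  if (length(hold_durations) == 1L) {
    hold_durations <- rep(hold_durations, length(speeds))
  }
  if (length(hold_durations) != length(speeds)) {
    stop("hold_durations must match speeds in length", call. = FALSE)
  }
  if (any(speeds <= 0) || any(hold_durations <= 0)) {
    stop("speeds and hold durations must be positive", call. = FALSE)
  }
  if (any(diff(speeds) <= 0)) {
    stop("schedule speeds must be strictly increasing", call. = FALSE)
  }
  if (is.null(s_max)) s_max <- speeds[length(speeds)]
  if (!isTRUE(all.equal(s_max, speeds[length(speeds)]))) {
    stop("s_max must equal the last schedule speed", call. = FALSE)
  }
  if (s_max > 30) {
    warning("schedule exceeds the 30 m/s machine safety cap", call. = FALSE)
  }
  t_end <- cumsum(hold_durations)
  out <- data.frame(speed = speeds, hold_duration = hold_durations,
                    t_start = t_end - hold_durations, t_end = t_end)
  structure(out, s_max = s_max, class = c("wind_schedule", "data.frame"))
}

#' @export
print.wind_schedule <- function(x, ...) {
  cat(sprintf("Wind schedule: %d levels up to S_m = %g m/s\n",
              nrow(x), attr(x, "s_max")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Schedule maximum speed
#' @param schedule A `wind_schedule`.
#' @return S_m in m/s.
#' @export
schedule_s_max <- function(schedule) {
  stopifnot(inherits(schedule, "wind_schedule"))
  attr(schedule, "s_max")
}

#' Lodging observations
#'
#' One row per (cultivar, year, wind level): the number of plants that lodged
#' when that generated level was reached. Plants that never lodged appear on
#' a censored row (`censored = TRUE`, `level_speed = NA`), the "> S_max" bin.
#'
#' @param cultivar Character cultivar identifiers.
#' @param year Integer years.
#' @param level_speed Generated speed (m/s) at which the plants lodged, or
#'   `NA` for the censored row.
#' @param lodged_count Non-negative integer plant counts.
#' @param censored Logical; `TRUE` marks the plants that survived the maximum
#'   generated speed.
#' @return A data frame of class `lodging_observations`.
#' @export
lodging_observations <- function(cultivar, year, level_speed, lodged_count,
                                 censored = is.na(level_speed)) {
  n <- length(cultivar)
  stopifnot(length(year) == n, length(level_speed) == n,
            length(lodged_count) == n, length(censored) == n)
  for (i in seq_len(n)) {
    if (!is.finite(lodged_count[i]) || lodged_count[i] < 0 ||
        lodged_count[i] != round(lodged_count[i])) {
      stop_row(i, "lodged_count must be a non-negative integer")
    }
    if (censored[i] && !is.na(level_speed[i])) {
      stop_row(i, "censored rows must not carry a level speed")
    }
    if (!censored[i] && (!is.finite(level_speed[i]) || level_speed[i] <= 0)) {
      stop_row(i, "level_speed must be a positive number or the censored marker")
    }
  }
  structure(
    data.frame(cultivar = as.character(cultivar), year = as.integer(year),
               level_speed = as.numeric(level_speed),
               lodged_count = as.integer(lodged_count),
               censored = as.logical(censored)),
    class = c("lodging_observations", "data.frame"))
}

#' Read a lodging-count CSV
#'
#' Expected columns: `cultivar,year,level_speed,lodged_count`, where
#' `level_speed` is numeric or the literal token `">Smax"` for plants that
#' never lodged.
#'
#' @param path Path to the CSV file.
#' @return A `lodging_observations` data frame.
#' @export
read_lodging_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  require_columns(raw, c("cultivar", "year", "level_speed", "lodged_count"),
                  basename(path))
  censored <- trimws(raw$level_speed) == CENSORED_TOKEN
  speed <- rep(NA_real_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (!censored[i]) {
      v <- num_or_na(raw$level_speed[i])
      if (is.na(v)) stop_row(i, paste0("unparseable level_speed '",
                                       raw$level_speed[i], "'"))
      speed[i] <- v
    }
    cnt <- num_or_na(raw$lodged_count[i])
    if (is.na(cnt)) stop_row(i, "unparseable lodged_count")
    if (cnt < 0) stop_row(i, "negative lodged_count")
  }
  lodging_observations(raw$cultivar, num_or_na(raw$year), speed,
                       num_or_na(raw$lodged_count), censored)
}

#' Write a lodging-count CSV
#' @param obs A `lodging_observations` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lodging_csv <- function(obs, path) {
  stopifnot(inherits(obs, "lodging_observations"))
  out <- data.frame(
    cultivar = obs$cultivar, year = obs$year,
    level_speed = ifelse(obs$censored, CENSORED_TOKEN,
                         format(obs$level_speed, trim = TRUE)),
    lodged_count = obs$lodged_count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Lodging distribution
#'
#' The discrete distribution of lodging over generated wind-speed levels for
#' one cultivar in one year: point masses p(v) at the observed levels plus a
#' right-censored mass for plants still standing at the schedule maximum S_m.
#' Masses are fractions and sum to one.
#'
#' @param cultivar Cultivar identifier.
#' @param year Integer year.
#' @param speeds Strictly increasing level speeds (m/s), all <= `s_max`.
#' @param masses Fractions p(v) in [0, 1], aligned with `speeds`.
#' @param censored_mass Fraction of plants that never lodged.
#' @param s_max Maximum generated speed S_m (m/s).
#' @return An object of class `lodging_distribution`.
#' @export
lodging_distribution <- function(cultivar, year, speeds, masses,
                                 censored_mass, s_max) {
  stopifnot(length(speeds) == length(masses), is.numeric(s_max), s_max > 0)
  if (length(speeds) > 0) {
    if (any(diff(speeds) <= 0)) {
      stop("bin speeds must be strictly increasing", call. = FALSE)
    }
    if (any(speeds <= 0) || any(speeds > s_max)) {
      stop("bin speeds must lie in (0, s_max]", call. = FALSE)
    }
  }
  if (any(masses < 0) || censored_mass < 0) {
    stop("masses must be non-negative", call. = FALSE)
  }
  total <- sum(masses) + censored_mass
  if (abs(total - 1) > 1e-9) {
    stop(sprintf("masses + censored_mass must sum to 1 (got %.12f)", total),
         call. = FALSE)
  }
  structure(list(cultivar = as.character(cultivar), year = as.integer(year),
                 speeds = as.numeric(speeds), masses = as.numeric(masses),
                 censored_mass = as.numeric(censored_mass),
                 s_max = as.numeric(s_max)),
            class = "lodging_distribution")
}

#' @export
print.lodging_distribution <- function(x, ...) {
  cat(sprintf("Lodging distribution: %s / %d (S_m = %g m/s)\n",
              x$cultivar, x$year, x$s_max))
  if (length(x$speeds) > 0) {
    print(data.frame(speed = x$speeds, mass = x$masses), row.names = FALSE)
  }
  cat(sprintf("censored (> %g m/s): %g\n", x$s_max, x$censored_mass))
  invisible(x)
}

#' Build a lodging distribution from counts
#'
#' Sums counts per level (duplicate level rows are pooled), then normalizes
#' by the total number of plants, censored survivors included.
#'
#' @param obs A `lodging_observations` data frame for a single cultivar and
#'   year.
#' @param s_max Maximum generated speed S_m (m/s); defaults to 30.
#' @return A `lodging_distribution`.
#' @export
build_distribution <- function(obs, s_max = 30) {
  stopifnot(inherits(obs, "lodging_observations"))
  if (length(unique(obs$cultivar)) != 1L || length(unique(obs$year)) != 1L) {
    stop("observations must share a single cultivar and year", call. = FALSE)
  }
  total <- sum(obs$lodged_count)
  if (total <= 0) stop("total plant count must be > 0", call. = FALSE)
  lodged <- obs[!obs$censored, , drop = FALSE]
  counts <- tapply(lodged$lodged_count, lodged$level_speed, sum)
  speeds <- as.numeric(names(counts))
  ord <- order(speeds)
  lodging_distribution(
    cultivar = obs$cultivar[1], year = obs$year[1],
    speeds = speeds[ord], masses = as.numeric(counts)[ord] / total,
    censored_mass = sum(obs$lodged_count[obs$censored]) / total,
    s_max = s_max)
}

#' Convert a distribution back to observation counts
#'
#' Inverse of [build_distribution()] for a known total plant count; used by
#' the simulator and round-trip serialization.
#'
#' @param dist A `lodging_distribution`.
#' @param n_plants Total plant count the masses refer to.
#' @return A `lodging_observations` data frame.
#' @export
distribution_to_observations <- function(dist, n_plants) {
  stopifnot(inherits(dist, "lodging_distribution"), n_plants >= 1)
  counts <- round(dist$masses * n_plants)
  cens <- n_plants - sum(counts)
  lodging_observations(
    cultivar = rep(dist$cultivar, length(dist$speeds) + 1L),
    year = rep(dist$year, length(dist$speeds) + 1L),
    level_speed = c(dist$speeds, NA_real_),
    lodged_count = c(counts, cens))
}

#' Anemometer records
#'
#' Timestamped wind-speed readings at a station. `layer` is `"outlet"` for
#' the machine outlet reference anemometer or one of `"bottom"` (0.2 m),
#' `"middle"` (1.2 m), `"top"` (2.2 m) for stations behind the canopy;
#' `distance` is meters from the outlet (`NA` for the outlet itself).
#'
#' @param time_s Seconds since forcing start.
#' @param layer One of `"outlet"`, `"bottom"`, `"middle"`, `"top"`.
#' @param distance_m Meters from the outlet, `NA` at the outlet.
#' @param speed_ms Wind speed (m/s), >= 0.
#' @return A data frame of class `anemometer_records`.
#' @export
anemometer_records <- function(time_s, layer, distance_m, speed_ms) {
  n <- length(time_s)
  stopifnot(length(layer) == n, length(distance_m) == n, length(speed_ms) == n)
  layer <- as.character(layer)
  for (i in seq_len(n)) {
    if (!layer[i] %in% ANEMOMETER_LAYERS) {
      stop_row(i, paste0("unknown layer '", layer[i], "'"))
    }
    if (!is.finite(speed_ms[i]) || speed_ms[i] < 0) {
      stop_row(i, "speed must be a non-negative number")
    }
  }
  structure(data.frame(time_s = as.numeric(time_s), layer = layer,
                       distance_m = as.numeric(distance_m),
                       speed_ms = as.numeric(speed_ms)),
            class = c("anemometer_records", "data.frame"))
}

#' Read an anemometer log CSV
#'
#' Expected columns: `time_s,layer,distance_m,speed_ms` with layer in
#' outlet|bottom|middle|top and `"NA"` allowed for the outlet distance.
#'
#' @param path Path to the CSV file.
#' @return An `anemometer_records` data frame.
#' @export
read_anemometer_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  require_columns(raw, c("time_s", "layer", "distance_m", "speed_ms"),
                  basename(path))
  spd <- num_or_na(raw$speed_ms)
  for (i in seq_len(nrow(raw))) {
    if (is.na(spd[i])) stop_row(i, paste0("unparseable speed '",
                                          raw$speed_ms[i], "'"))
  }
  anemometer_records(num_or_na(raw$time_s), raw$layer,
                     num_or_na(raw$distance_m), spd)
}

#' Write an anemometer log CSV
#' @param records An `anemometer_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anemometer_csv <- function(records, path) {
  stopifnot(inherits(records, "anemometer_records"))
  out <- data.frame(
    time_s = format(records$time_s, trim = TRUE),
    layer = records$layer,
    distance_m = ifelse(is.na(records$distance_m), "NA",
                        format(records$distance_m, trim = TRUE)),
    speed_ms = format(records$speed_ms, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cultivar trait table CSV
#'
#' One row per cultivar; for each trait a `<trait>_mean` and `<trait>_se`
#' column. The traits are Young's modulus (10^3 MPa), maximum bending load
#' (N) and maximum transverse displacement (mm) from three-point bending,
#' plus plant height (mm), plant azimuthal deviation (deg), leaf number,
#' leaf inclination angle (deg), ear number, ear height (mm) and ear length
#' (mm).
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `trait_table`.
#' @export
read_traits_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE)
  cols <- c("cultivar", paste0(rep(TRAIT_NAMES, each = 2), c("_mean", "_se")))
  require_columns(raw, cols, basename(path))
  for (nm in setdiff(cols, "cultivar")) {
    bad <- which(is.finite(raw[[nm]]) & raw[[nm]] < 0)
    if (length(bad) > 0) stop_row(bad[1], paste0(nm, " must be >= 0"))
  }
  structure(raw[cols], class = c("trait_table", "data.frame"))
}

#' Write a cultivar trait table CSV
#' @param traits A `trait_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(traits, path) {
  stopifnot(inherits(traits, "trait_table"))
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
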