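# End-to-end orchestration: lodging CSVs (or a simulation config) in,
# a per-cultivar index and reliability report out.

#' Evaluate lodging trials: FWS and CLI per cultivar/year, plus reliability
#'
#' Reads one or more lodging-count CSVs, builds the per-cultivar/year
#' lodging distributions, and computes the failure wind speed and the
#' cumulative lodging index for each. When exactly two years are present,
#' between-year reliability (RMSE, nRMSE, grade) is computed for each index
#' over the cultivars measured in both years; censored failure wind speeds
#' enter the reliability computation as S_m. With a single year the
#' reliability section is absent (not an error). Deterministic given its
#' inputs.
#'
#' @param lodging_csvs Paths of lodging CSVs (see [read_lodging_csv()]), or
#'   a `lodging_observations` object.
#' @param s_max Maximum generated speed S_m (m/s).
#' @param candidate_resolution Candidate grid resolution for the failure
#'   wind speed (m/s).
#' @param provenance Optional named list recorded verbatim in the report
#'   (input paths, seeds).
#' @return An object of class `evaluation_report`: list with `indices` (data
#'   frame cultivar, year, fws, fws_censored, cli), `reliability` (data
#'   frame index, n, rmse, nrmse_pct, grade, or `NULL`), and `provenance`.
#' @export
evaluate <- function(lodging_csvs, s_max = 30, candidate_resolution = 1,
                     provenance = list()) {
  if (inherits(lodging_csvs, "lodging_observations")) {
    obs <- lodging_csvs
    paths <- "<in-memory>"
  } else {
    stopifnot(length(lodging_csvs) >= 1)
    obs <- do.call(rbind, lapply(lodging_csvs, read_lodging_csv))
    class(obs) <- c("lodging_observations", "data.frame")
    paths <- as.character(lodging_csvs)
  }
  groups <- split(obs, list(obs$cultivar, obs$year), drop = TRUE)
  rows <- lapply(groups, function(g) {
    class(g) <- c("lodging_observations", "data.frame")
    dist <- build_distribution(g, s_max = s_max)
    fws <- failure_wind_speed(dist, candidate_resolution)
    data.frame(cultivar = dist$cultivar, year = dist$year,
               fws = if (fws$censored) s_max else fws$value,
               fws_censored = fws$censored,
               cli = cumulative_lodging_index(dist))
  })
  idx <- do.call(rbind, rows)
  idx <- idx[order(idx$year, idx$cultivar), , drop = FALSE]
  rownames(idx) <- NULL
  rel <- NULL
  years <- sort(unique(idx$year))
  if (length(years) == 2) {
    y1 <- idx[idx$year == years[1], ]
    y2 <- idx[idx$year == years[2], ]
    common <- intersect(y1$cultivar, y2$cultivar)
    if (length(common) >= 1) {
      i1 <- match(common, y1$cultivar)
      i2 <- match(common, y2$cultivar)
      reports <- list(
        reliability_report(paired_year_table(
          common, y1$fws[i1], y2$fws[i2],
          y1$fws_censored[i1], y2$fws_censored[i2]), index = "FWS"),
        reliability_report(paired_year_table(
          common, y1$cli[i1], y2$cli[i2]), index = "CLI"))
      rel <- do.call(rbind, lapply(reports, function(r) {
        data.frame(index = r$index, n = r$n, rmse = r$rmse,
                   nrmse_pct = r$nrmse, grade = r$grade)
      }))
    }
  }
  structure(list(
    indices = idx, reliability = rel,
    provenance = utils::modifyList(
      list(inputs = paths, s_max = s_max,
           candidate_resolution = candidate_resolution,
           tool_version = as.character(utils::packageVersion("windlodge"))),
      provenance)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n-----------------\n")
  print(x$indices, row.names = FALSE)
  if (!is.null(x$reliability)) {
    cat("\nBetween-year reliability:\n")
    print(x$reliability, row.names = FALSE)
  } else {
    cat("\nBetween-year reliability: absent (single year)\n")
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Tables go to CSV (`<stem>_indices.csv`, `<stem>_reliability.csv` when
#' present), provenance to JSON (`<stem>_provenance.json`).
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Character vector of the files written, invisibly.
#' @export
write_evaluation_report <- function(report, dir, stem = "report") {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, paste0(stem, "_indices.csv"))
  utils::write.csv(report$indices, files[1], row.names = FALSE, quote = FALSE)
  if (!is.null(report$reliability)) {
    f <- file.path(dir, paste0(stem, "_reliability.csv"))
    utils::write.csv(report$reliability, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, paste0(stem, "_provenance.json"))
  jsonlite::write_json(report$provenance, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Read back a written evaluation report
#' @param dir Directory holding the report files.
#' @param stem File-name stem used at write time.
#' @return An `evaluation_report`.
#' @export
read_evaluation_report <- function(dir, stem = "report") {
  idx <- utils::read.csv(file.path(dir, paste0(stem, "_indices.csv")))
  relf <- file.path(dir, paste0(stem, "_reliability.csv"))
  rel <- if (file.exists(relf)) utils::read.csv(relf) else NULL
  prov <- jsonlite::read_json(file.path(dir, paste0(stem, "_provenance.json")),
                              simplifyVector = TRUE)
  structure(list(indices = idx, reliability = rel, provenance = prov),
            class = "evaluation_report")
}

CONFIG_KEYS <- c("seed", "s_max", "years", "replicates", "schedule",
                 "profile", "cultivars", "n_plants")
SCHEDULE_KEYS <- c("max_speed", "coarse_step", "fine_step", "step_change_at",
                   "hold_coarse", "hold_fine")
CULTIVAR_KEYS <- c("preset", "cultivar", "mixture", "n_plants",
                   "noise_sd", "knockdown_prob")

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown %s config key(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

config_spec <- function(entry, default_n) {
  check_keys(entry, CULTIVAR_KEYS, "cultivar")
  if (!is.null(entry$preset)) {
    lib <- preset_cultivars(n_plants = entry$n_plants %||% default_n)
    if (!entry$preset %in% names(lib)) {
      stop("unknown preset: ", entry$preset, call. = FALSE)
    }
    return(lib[[entry$preset]])
  }
  mix <- do.call(rbind, lapply(entry$mixture, as.data.frame))
  cultivar_sim_spec(entry$cultivar, mix,
                    n_plants = entry$n_plants %||% default_n,
                    noise_sd = entry$noise_sd %||% 0.5,
                    knockdown_prob = entry$knockdown_prob %||% 0)
}

#' Run a simulation-and-evaluation pipeline from a YAML config
#'
#' Stages: parse config, simulate each cultivar for each year, write
#' per-year lodging and anemometer CSVs, evaluate, write the report.
#' Unknown config keys are an error naming the key. Re-running with the
#' same config and seed reproduces the outputs byte for byte.
#'
#' Config keys: `seed` (int), `s_max`, `years` (list, default 2016/2017),
#' `schedule` (overrides for [build_wind_schedule()]), `profile`
#' (`bottom`/`middle`/`top` RI anchor pairs), `n_plants` (default per
#' cultivar), `cultivars` (list of `preset:` names or full specs with
#' `cultivar`, `mixture`, `n_plants`, `noise_sd`, `knockdown_prob`).
#'
#' @param config_path Path to the YAML config.
#' @param output_dir Directory for the CSV/JSON outputs.
#' @return The `evaluation_report`, invisibly; files on disk as a side
#'   effect.
#' @export
run_config <- function(config_path, output_dir) {
  cfg <- tryCatch(yaml::read_yaml(config_path), error = function(e) {
    stop("config stage: cannot parse ", config_path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  check_keys(cfg, CONFIG_KEYS, "top-level")
  seed <- as.integer(cfg$seed %||% 1L)
  s_max <- cfg$s_max %||% 30
  years <- as.integer(unlist(cfg$years %||% list(2016L, 2017L)))
  sched_args <- cfg$schedule %||% list()
  check_keys(sched_args, SCHEDULE_KEYS, "schedule")
  sched_args$max_speed <- sched_args$max_speed %||% s_max
  schedule <- do.call(build_wind_schedule, sched_args)
  profile <- if (is.null(cfg$profile)) {
    attenuation_profile()
  } else {
    check_keys(cfg$profile, c("bottom", "middle", "top", "d_near", "d_far"),
               "profile")
    do.call(attenuation_profile, lapply(cfg$profile, unlist))
  }
  if (is.null(cfg$cultivars)) stop("config stage: no cultivars", call. = FALSE)
  specs <- lapply(cfg$cultivars, config_spec,
                  default_n = cfg$n_plants %||% 84)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  lodging_paths <- character(0)
  for (yi in seq_along(years)) {
    all_obs <- NULL
    for (ci in seq_along(specs)) {
      trial_seed <- seed + 1000L * yi + ci
      trial <- simulate_trial(specs[[ci]], schedule, profile,
                              seed = trial_seed, year = years[yi])
      all_obs <- rbind(all_obs, trial$observations)
      anem <- rbind(trial$anemometer$outlet, trial$anemometer$downstream)
      class(anem) <- c("anemometer_records", "data.frame")
      write_anemometer_csv(
        anem,
        file.path(output_dir, sprintf("anemometer_%d_%s.csv", years[yi],
                                      specs[[ci]]$cultivar)))
    }
    class(all_obs) <- c("lodging_observations", "data.frame")
    p <- file.path(output_dir, sprintf("lodging_%d.csv", years[yi]))
    write_lodging_csv(all_obs, p)
    lodging_paths <- c(lodging_paths, p)
  }
  report <- evaluate(lodging_paths, s_max = s_max,
                     provenance = list(config = config_path, seed = seed))
  write_evaluation_report(report, output_dir)
  invisible(report)
}
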