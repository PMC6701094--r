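test_that("default wind schedule reproduces the stepped field protocol", {
  s <- build_wind_schedule()
  expect_equal(s$speed, c(5, 10, 12, 14, 16, 18, 20, 22, 24, 26, 28, 30))
  expect_equal(nrow(s), 12)
  expect_equal(s$hold_duration[s$speed == 5], 30)
  expect_equal(s$hold_duration[s$speed == 12], 19)
  expect_equal(s$hold_duration, ifelse(s$speed < 10, 30, 19))
  expect_equal(schedule_s_max(s), 30)

  expect_equal(build_wind_schedule(max_speed = 10)$speed, c(5, 10))
  expect_warning(s2 <- build_wind_schedule(max_speed = 29), "clamped")
  expect_equal(max(s2$speed), 29)
})

test_that("attenuation interpolates the layer profiles linearly in distance", {
  prof <- attenuation_profile()
  expect_equal(attenuate(30, 7, "middle", prof), 30 * (1 - 0.65))
  expect_equal(attenuate(30, 4.5, "bottom", prof), 30 * (1 - (0.22 + 0.59) / 2))
  expect_equal(attenuate(30, 7, "top", prof), 30 * (1 - 0.66))
  # below the near anchor the near-anchor index applies
  expect_equal(attenuate(10, 1, "bottom", prof), 10 * (1 - 0.22))
  expect_equal(attenuate(12, 5, "middle", flat_profile()), 12)
  expect_error(attenuate(10, 8, "middle", prof), "\\(0, 7\\]")
  expect_error(attenuation_profile(bottom = c(0.5, 0.2)), ">= near")
})

test_that("trial simulation is deterministic and conserves plants", {
  spec <- cultivar_sim_spec("X", data.frame(weight = 1, mean = 20, sd = 2),
                            n_plants = 200)
  t1 <- simulate_trial(spec, seed = 7)
  t2 <- simulate_trial(spec, seed = 7)
  expect_identical(t1, t2)
  t3 <- simulate_trial(spec, seed = 8)
  expect_false(identical(t1$observations, t3$observations))
  expect_equal(sum(t1$observations$lodged_count), 200)
  # simulation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_trial(spec, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("deterministic threshold limits lodge at the first reaching level", {
  spec <- cultivar_sim_spec("X", data.frame(weight = 1, mean = 19.5,
                                            sd = 1e-9),
                            n_plants = 50, noise_sd = 0)
  tr <- simulate_trial(spec, profile = NULL, seed = 1)
  obs <- tr$observations
  expect_equal(obs$lodged_count[obs$level_speed == 20 & !obs$censored], 50)

  high <- cultivar_sim_spec("Y", data.frame(weight = 1, mean = 100, sd = 1),
                            n_plants = 50, noise_sd = 0)
  trh <- simulate_trial(high, profile = NULL, seed = 1)
  expect_equal(trh$observations$lodged_count[trh$observations$censored], 50)
})

test_that("lodged fractions by level match the threshold-CDF differences", {
  spec <- cultivar_sim_spec("X", data.frame(weight = 1, mean = 20, sd = 2),
                            n_plants = 1000, noise_sd = 0)
  tr <- simulate_trial(spec, profile = NULL, seed = 12)
  obs <- tr$observations[!tr$observations$censored, ]
  sched <- build_wind_schedule()
  lower <- c(-Inf, sched$speed[-nrow(sched)])
  for (k in seq_len(nrow(sched))) {
    p_exp <- stats::pnorm(sched$speed[k], 20, 2) - stats::pnorm(lower[k], 20, 2)
    p_obs <- obs$lodged_count[k] / 1000
    expect_lt(abs(p_obs - p_exp),
              3 * sqrt(max(p_exp * (1 - p_exp), 1e-6) / 1000) + 1e-3)
  }
})

test_that("anemometer logs sample 1 Hz and recover the profile RI exactly
           when noise-free", {
  sched <- build_wind_schedule()
  logs <- simulate_anemometer_logs(sched, attenuation_profile(),
                                   distance = 7, noise_sd = 0, seed = 1)
  expect_equal(nrow(logs$outlet), sum(sched$hold_duration))
  for (ly in c("bottom", "middle", "top")) {
    ri <- aggregate_reduction_index(logs$outlet, logs$downstream, ly, sched)
    expect_equal(ri$ri, rep(attenuation_profile()[[ly]][2], nrow(sched)))
  }
  # with noise, recovery within tolerance at a mid-row station
  logs4 <- simulate_anemometer_logs(sched, attenuation_profile(),
                                    distance = 4.5, noise_sd = 0.3, seed = 2)
  ri4 <- aggregate_reduction_index(logs4$outlet, logs4$downstream, "middle",
                                   sched)
  want <- 0.02 + (0.65 - 0.02) * (4.5 - 2) / 5
  expect_equal(mean(ri4$ri[ri4$speed >= 10]), want, tolerance = 0.05)
})

test_that("preset library covers the observed distribution shapes", {
  lib <- preset_cultivars(n_plants = 500)
  expect_named(lib, c("jk665_like", "jk968_like", "xd20_like", "zd958_like",
                      "jd38_like", "xy335_like"))
  dists <- lapply(seq_along(lib), function(i) {
    tr <- simulate_trial(lib[[i]], profile = NULL, seed = 100 + i)
    build_distribution(tr$observations)
  })
  names(dists) <- names(lib)
  for (d in dists) {
    expect_equal(sum(d$masses) + d$censored_mass, 1, tolerance = 1e-12)
  }
  expect_gt(dists$jd38_like$censored_mass, 0.9)
  expect_gt(dists$xy335_like$censored_mass, 0.75)
  # bimodal preset: at least two local maxima over the level masses
  m <- dists$xd20_like$masses
  local_max <- sum(vapply(seq_along(m), function(i) {
    left <- if (i == 1) 0 else m[i - 1]
    right <- if (i == length(m)) 0 else m[i + 1]
    m[i] > 1e-6 && m[i] >= left && m[i] >= right && (m[i] > left || m[i] > right)
  }, logical(1)))
  expect_gte(local_max, 2)
})

test_that("raising the threshold mean raises the mean CLI", {
  mean_cli <- function(mu) {
    vals <- vapply(1:30, function(r) {
      spec <- cultivar_sim_spec("X", data.frame(weight = 1, mean = mu, sd = 2),
                                n_plants = 200, noise_sd = 0)
      tr <- simulate_trial(spec, profile = NULL, seed = 5000 + r)
      cumulative_lodging_index(build_distribution(tr$observations))
    }, numeric(1))
    mean(vals)
  }
  expect_gt(mean_cli(24), mean_cli(18))
})
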