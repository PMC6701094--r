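dist2 <- lodging_distribution("XD20", 2016L, c(12, 24), c(0.6, 0.4), 0, 30)

test_that("reduction index arithmetic and guards", {
  expect_equal(reduction_index(30, 30), 0)
  expect_equal(reduction_index(30, 0), 1)
  expect_equal(reduction_index(20, 5), 0.75)
  expect_error(reduction_index(0, 5), "undefined")
  expect_error(reduction_index(20, -1), ">= 0")
})

test_that("per-level RI averages outlet and downstream records per window", {
  sched <- wind_schedule(c(10, 20), c(10, 10))
  mk <- function(t, layer, d, s) anemometer_records(t, layer, d, s)
  outlet <- mk(0:19, rep("outlet", 20), rep(NA_real_, 20),
               rep(c(10, 20), each = 10))
  # two stations in the second window reading 6 and 10 -> mean 8, RI 0.6
  down <- mk(c(0:9, 12, 14), rep("middle", 12), rep(7, 12),
             c(rep(10, 10), 6, 10))
  ri <- aggregate_reduction_index(outlet, down, "middle", sched)
  expect_equal(ri$ri, c(0, 1 - 8 / 20))
  expect_false(any(ri$flagged))

  # missing downstream records for a level is an error naming the level
  down1 <- mk(0:9, rep("middle", 10), rep(7, 10), rep(10, 10))
  expect_error(aggregate_reduction_index(outlet, down1, "middle", sched),
               "20 m/s")
  # downstream faster than outlet -> negative RI, flagged, not clamped
  gusty <- mk(c(0:9, 12), rep("middle", 11), rep(7, 11), c(rep(10, 10), 30))
  ri2 <- aggregate_reduction_index(outlet, gusty, "middle", sched)
  expect_lt(ri2$ri[2], 0)
  expect_true(ri2$flagged[2])
})

test_that("cumulative lodged fraction is a step sum excluding censored mass", {
  expect_equal(cumulative_lodged_fraction(dist2, 18), 0.6)
  expect_equal(cumulative_lodged_fraction(dist2, 11.9), 0)
  dc <- lodging_distribution("A", 2016L, c(10, 20), c(0.3, 0.2), 0.5, 30)
  expect_equal(cumulative_lodged_fraction(dc, 30), 0.5)
  expect_error(cumulative_lodged_fraction(dc, 31), "\\[0, 30\\]")
})

test_that("lodging resistance evaluates 1/(1 + cumulative fraction)", {
  dc <- lodging_distribution("A", 2016L, c(10, 20), c(0.3, 0.2), 0.5, 30)
  expect_equal(lodging_resistance(dc, 5), 1)
  expect_equal(lodging_resistance(dc, 15), 1 / 1.3)
  all_low <- lodging_distribution("B", 2016L, 1, 1, 0, 30)
  expect_equal(lodging_resistance(all_low, 10), 0.5)
})

test_that("LR curve is piecewise constant and matches pointwise evaluation", {
  empty <- lodging_distribution("A", 2016L, numeric(0), numeric(0), 1, 30)
  ce <- lodging_resistance_curve(empty)
  expect_equal(ce$lr, 1)
  expect_equal(c(ce$start, ce$end), c(0, 30))

  one <- lodging_distribution("B", 2016L, 15, 1, 0, 30)
  co <- lodging_resistance_curve(one)
  expect_equal(co$lr, c(1, 0.5))
  expect_equal(co$start, c(0, 15))

  dc <- lodging_distribution("C", 2016L, c(10, 20), c(0.3, 0.2), 0.5, 30)
  cc <- lodging_resistance_curve(dc)
  expect_equal(cc$lr, c(1, 1 / 1.3, 1 / 1.5))
  # dense-grid agreement with pointwise LR (right-continuity included)
  for (s in seq(0.5, 30, by = 0.5)) {
    seg <- which(cc$start <= s & (s < cc$end | s == 30))
    expect_equal(cc$lr[max(seg)], lodging_resistance(dc, s))
  }
})

test_that("failure wind speed minimizes the weighted L1 objective", {
  point <- lodging_distribution("A", 2016L, 20, 1, 0, 30)
  expect_equal(failure_wind_speed(point)$value, 20)

  expect_equal(failure_wind_speed(dist2)$value, 12)

  cens <- lodging_distribution("JD38", 2016L, numeric(0), numeric(0), 1, 30)
  r <- failure_wind_speed(cens)
  expect_true(r$censored)
  expect_equal(format(r), "> 30")

  # zero-slope tie region [12, 24]: smallest minimizer wins
  tie <- lodging_distribution("B", 2016L, c(12, 24), c(0.5, 0.5), 0, 30)
  expect_equal(failure_wind_speed(tie)$value, 12)
})

test_that("L1-median solver agrees with brute-force minimization", {
  set.seed(101)
  for (i in 1:200) {
    d <- rand_dist()
    got <- failure_wind_speed(d, candidate_resolution = 0.01)
    want <- fws_oracle(d, resolution = 0.01)
    expect_equal(got$censored, want$censored)
    if (!got$censored) {
      expect_lt(abs(got$value - want$value), 0.01 + 1e-9)
    }
  }
})

test_that("CLI closed-form integral matches the spec'd examples", {
  cens <- lodging_distribution("A", 2016L, numeric(0), numeric(0), 1, 30)
  expect_equal(cumulative_lodging_index(cens), 1)
  low <- lodging_distribution("B", 2016L, 0.001, 1, 0, 30)
  expect_equal(cumulative_lodging_index(low), 0.5, tolerance = 1e-4)
  one <- lodging_distribution("C", 2016L, 15, 1, 0, 30)
  expect_equal(cumulative_lodging_index(one), 0.75)
})

test_that("CLI closed form agrees with pointwise quadrature", {
  set.seed(202)
  for (i in 1:100) {
    d <- rand_dist()
    expect_equal(cumulative_lodging_index(d), cli_quadrature(d),
                 tolerance = 1e-4)
  }
})

test_that("LR is monotone non-increasing and LR/CLI stay in [0.5, 1]", {
  set.seed(303)
  for (i in 1:100) {
    d <- rand_dist()
    s <- sort(runif(20, 0, d$s_max))
    lr <- lodging_resistance(d, s)
    expect_true(all(diff(lr) <= 1e-12))
    expect_true(all(lr >= 0.5 - 1e-12 & lr <= 1 + 1e-12))
    cli <- cumulative_lodging_index(d)
    expect_gte(cli, 0.5)
    expect_lte(cli, 1)
  }
})

test_that("moving lodging mass to higher speeds never decreases CLI", {
  set.seed(404)
  for (i in 1:100) {
    d <- rand_dist(allow_empty = FALSE)
    if (length(d$speeds) < 2) next
    ij <- sort(sample(seq_along(d$speeds), 2))
    delta <- runif(1, 0, d$masses[ij[1]])
    m2 <- d$masses
    m2[ij[1]] <- m2[ij[1]] - delta
    m2[ij[2]] <- m2[ij[2]] + delta
    shifted <- lodging_distribution(d$cultivar, d$year, d$speeds, m2,
                                    d$censored_mass, d$s_max)
    expect_gte(cumulative_lodging_index(shifted),
               cumulative_lodging_index(d) - 1e-12)
  }
})

test_that("shrinking lodged mass toward the censored bin raises CLI", {
  set.seed(505)
  for (i in 1:50) {
    d <- rand_dist(allow_empty = FALSE)
    # mass exactly at S_m occupies a zero-width segment; needs mass below it
    if (sum(d$masses[d$speeds < d$s_max]) < 1e-6) next
    lam <- runif(1, 0.2, 0.8)
    shrunk <- lodging_distribution(
      d$cultivar, d$year, d$speeds, lam * d$masses,
      d$censored_mass + (1 - lam) * sum(d$masses), d$s_max)
    expect_gt(cumulative_lodging_index(shrunk), cumulative_lodging_index(d))
  }
})
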