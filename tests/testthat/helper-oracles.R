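# Independent oracles and random-input generators shared across tests.
# The oracles deliberately use different code paths (explicit loops, outer
# products, pointwise quadrature) than the implementation they check.

# Random lodging distribution: up to max_bins point masses on a half-m/s
# lattice plus a censored remainder. Uses the ambient RNG; callers seed.
rand_dist <- function(s_max = 30, max_bins = 6, allow_empty = TRUE) {
  k <- sample(if (allow_empty) 0:max_bins else 1:max_bins, 1)
  speeds <- sort(sample(seq(0.5, s_max, by = 0.5), k))
  w <- stats::runif(k + 1)
  if (k > 0 && stats::runif(1) < 0.5) w[k + 1] <- 0  # often no survivors
  w <- w / sum(w)
  lodging_distribution("sim", 2016L, speeds, w[seq_len(k)], w[k + 1], s_max)
}

# Brute-force minimization of the weighted L1 objective over a dense grid,
# via an outer product; censor handling follows the same stated convention.
fws_oracle <- function(dist, resolution = 0.01, censor_step = 2) {
  cand <- sort(unique(c(seq(resolution, dist$s_max, by = resolution),
                        dist$speeds, dist$s_max)))
  v <- c(dist$speeds, dist$s_max + censor_step)
  p <- c(dist$masses, dist$censored_mass)
  obj <- as.vector(abs(outer(cand, v, "-")) %*% p)
  tol <- 1e-9 * max(1, max(obj))
  mins <- cand[obj <= min(obj) + tol]
  if (any(abs(mins - dist$s_max) <= tol) &&
      dist$censored_mass > sum(dist$masses)) {
    list(value = NA_real_, censored = TRUE)
  } else {
    list(value = min(mins), censored = FALSE)
  }
}

# Pointwise quadrature of LR over (0, S_m]: evaluates lodging_resistance at
# interval midpoints of a 0.01 m/s grid refined with the breakpoints, never
# touching the closed-form segment integral.
cli_quadrature <- function(dist, ds = 0.01) {
  grid <- sort(unique(c(seq(0, dist$s_max, by = ds), dist$speeds,
                        dist$s_max)))
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  widths <- diff(grid)
  sum(widths * lodging_resistance(dist, mids)) / dist$s_max
}

# Loop-based RMSE/nRMSE over pairs.
rmse_oracle <- function(ref, val) {
  acc <- 0
  for (i in seq_along(ref)) acc <- acc + (val[i] - ref[i])^2
  sqrt(acc / length(ref))
}
nrmse_oracle <- function(ref, val) 100 * rmse_oracle(ref, val) / mean(ref)

# Flat attenuation (identity) profile for no-attenuation simulations.
flat_profile <- function() {
  attenuation_profile(bottom = c(0, 0), middle = c(0, 0), top = c(0, 0))
}

# In-code trait table (arbitrary plausible values) for I/O round-trips.
synthetic_trait_table <- function() {
  nms <- c("cultivar",
           paste0(rep(windlodge:::TRAIT_NAMES, each = 2), c("_mean", "_se")))
  set.seed(99)
  df <- data.frame(cultivar = paste0("CV", 1:4))
  for (nm in nms[-1]) df[[nm]] <- round(runif(4, 1, 100), 1)
  structure(df, class = c("trait_table", "data.frame"))
}
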