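# Shared fixtures built in code.

# A noiseless time-course sampled from a known Gompertz curve, wrapped as a
# single-replicate germination_time_course with integer-rounded counts
# avoided by using n_seeds = 1e6 (rounding error < 1e-6).
exact_gompertz_course <- function(A, k, tm, temperature = 20,
                                  times = seq(5, 150, by = 5),
                                  n_seeds = 1e6) {
  counts <- round(gompertz(times, A, k, tm) * n_seeds)
  germination_time_course(
    "temperature", temperature,
    data.frame(replicate = 1, time_h = times, cum_germinated = counts),
    seeds_per_replicate = n_seeds)
}

# Exactly linear percentile rates: rate(level) = slope * (level - base) for
# every percentile, as a named list of percentile_rates-shaped tables.
linear_rates <- function(levels, slope, base,
                         percentiles = c(20, 40, 50, 60, 80, 90)) {
  out <- lapply(levels, function(l) {
    r <- data.frame(percentile = percentiles,
                    time = 1 / (slope * (l - base)),
                    rate = slope * (l - base))
    class(r) <- c("percentile_rates", "data.frame")
    r
  })
  names(out) <- levels
  out
}

# A point-mass thermal-time distribution (every seed needs `tt` degree-days;
# the sliver sits at-or-below tt so an accrual of exactly tt triggers
# germination).
point_mass_tt <- function(tt) {
  thermal_time_classes(lower = tt - 1e-9, upper = tt, prob = 1)
}

# Non-limiting scenario pieces shared by engine tests.
no_stress_weather <- function(days = 35, temp = 20) {
  constant_weather(days, soil_temp_C = temp, rainfall_mm = 0, psi = -0.01)
}

bare_seedbed <- function(n_seeds, depth_cm = 3) {
  seedbed_config(n_seeds = n_seeds,
                 depth = list(mean = depth_cm, sd = 0, min = 1, max = 6),
                 aggregates = NULL, crusting_class = "non_crusting")
}
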