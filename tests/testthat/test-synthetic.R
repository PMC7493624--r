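test_that("incubation at the base temperature yields all-zero counts", {
  tp <- soybean_cultivar_params("Ecudor")  # Tb = 4
  tcs <- generate_time_courses(tp, temperatures = c(4), rng_seed = 1)
  expect_equal(sum(tcs[[1]]$observations$cum_germinated), 0)
})

test_that("a potential near the base strongly reduces final germination", {
  tp <- soybean_cultivar_params("Ecudor")
  # seed-lot base potentials spanning -0.75 MPa (fastest seeds) to just
  # above -0.45 MPa (slowest tail): at -0.50 MPa the slow tail cannot
  # germinate and the rest is slowed past the scoring window
  tcs <- generate_time_courses(tp, potentials = c(0, -0.5), rng_seed = 2,
                               n_seeds = 100,
                               psi_b_range = c(-0.75, -0.45))
  final <- vapply(tcs, function(tc) {
    p <- pool_replicates(tc)
    p$fraction[nrow(p)]
  }, numeric(1))
  expect_gt(final[1], 0.9)       # control germinates nearly fully
  expect_lt(final[2], 0.8)       # near-base potential cuts germination hard
})

test_that("generation is deterministic in the seed and courses validate", {
  tp <- soybean_cultivar_params("Santana")
  a <- generate_time_courses(tp, temperatures = c(15, 25), rng_seed = 9)
  b <- generate_time_courses(tp, temperatures = c(15, 25), rng_seed = 9)
  expect_identical(lapply(a, `[[`, "observations"),
                   lapply(b, `[[`, "observations"))
  for (tc in a) expect_s3_class(tc, "germination_time_course")
})

test_that("warm-wet 30-day rainfall stays in the observed field envelope", {
  cum <- vapply(1:400, function(i)
    sum(generate_weather("warm_wet", 30, rng_seed = i)$rainfall_mm),
    numeric(1))
  expect_gte(mean(cum >= 34 & cum <= 125), 0.9)
})

test_that("potentials dry down monotonically without rain", {
  w <- generate_weather("warm_dry_spell", 40, rng_seed = 3)
  after_rain <- 8:40  # the template is rain-free from day 8 on
  expect_equal(sum(w$rainfall_mm[after_rain]), 0)
  for (col in c("psi_0_3", "psi_3_5", "psi_5_10"))
    expect_true(all(diff(w[[col]][after_rain]) < 0))
  expect_true(all(w$psi_0_3 <= 0))
})

test_that("weather generation is deterministic and covers the horizon", {
  a <- generate_weather("cold_wet", 45, rng_seed = 7)
  b <- generate_weather("cold_wet", 45, rng_seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 45)
  expect_error(generate_weather("cold_wet", 20), ">= 30")
})

test_that("seedbed templates carry the expected crust sensitivity", {
  expect_equal(seedbed_template("clay")$crusting_class, "non_crusting")
  expect_equal(seedbed_template("silty_loam")$crusting_class,
               "highly_crusting")
  expect_equal(seedbed_template("silty_clay_loam")$crusting_class,
               "moderately_crusting")
  expect_equal(seedbed_template("clay_loam")$crusting_class,
               "moderately_crusting")
  for (nm in c("clay", "silty_loam", "silty_clay_loam", "clay_loam",
               "silty_clay"))
    expect_s3_class(seedbed_template(nm), "seedbed_config")
  expect_error(seedbed_template("peat"))
})

test_that("thermal-time classes match a brute-force histogram of the truth", {
  tp <- soybean_cultivar_params("Isidor")
  tcs <- generate_time_courses(tp, temperatures = c(15, 20, 25),
                               n_seeds = 100, rng_seed = 13)
  ttd <- derive_thermal_time_distribution(tcs, Tb = tp$Tb)
  # oracle: histogram a large direct sample from the generating distribution
  set.seed(99)
  draws <- draw_thermal_time(2e5, tp$thermal_time_distribution)
  breaks <- c(ttd$classes$lower[1], ttd$classes$upper)
  h <- hist(pmin(draws, max(breaks) - 1e-9), breaks = breaks, plot = FALSE)
  tv <- 0.5 * sum(abs(ttd$classes$prob - h$counts / length(draws)))
  expect_lt(tv, 0.05)
})

test_that("pooled thermal-time curves collapse and keep their median near 18", {
  tp <- soybean_cultivar_params("Ecudor")
  tcs <- generate_time_courses(tp, temperatures = c(15, 20, 25),
                               n_seeds = 100, rng_seed = 21)
  ttd <- derive_thermal_time_distribution(tcs, Tb = tp$Tb)
  expect_length(ttd$diagnostics, 0)     # curves collapse in thermal time
  expect_equal(sum(ttd$classes$prob), 1, tolerance = 1e-12)
  expect_gte(ttd$germinable_fraction, 0)
  expect_lte(ttd$germinable_fraction, 1)
  expect_equal(thermal_time_median(ttd), 18, tolerance = 0.15)
  below40 <- sum(ttd$classes$prob[ttd$classes$upper <= 40])
  expect_gt(below40, 0.97)
})

test_that("the lab CSV dialect round-trips through disk", {
  tp <- soybean_cultivar_params("Ecudor")
  tcs <- generate_time_courses(tp, temperatures = c(15, 25),
                               potentials = c(-0.1), rng_seed = 5)
  path <- file.path(tempdir(), "lab.csv")
  write_germination_csv(tcs, path, cultivar = "Ecudor")
  back <- read_germination_csv(path)
  expect_named(back, "Ecudor")
  expect_length(back$Ecudor$temperature, 2)
  expect_length(back$Ecudor$water_potential, 1)
  orig <- pool_replicates(tcs[[1]])
  expect_equal(pool_replicates(back$Ecudor$temperature[[1]]), orig)
})

test_that("cultivar parameters round-trip through JSON", {
  tp <- soybean_cultivar_params("Santana")
  path <- file.path(tempdir(), "santana.json")
  write_cultivar_params(tp, path)
  back <- read_cultivar_params(path)
  expect_equal(back$Tb, tp$Tb)
  expect_equal(back$psi_b_mean, tp$psi_b_mean)
  expect_equal(back$germinable_fraction, tp$germinable_fraction)
  expect_equal(back$thermal_time_distribution$classes,
               tp$thermal_time_distribution$classes)
  expect_equal(back$psi_b_by_percentile, tp$psi_b_by_percentile)
})

test_that("weather series round-trip through the CSV dialect", {
  w <- generate_weather("crust_prone", 32, rng_seed = 6)
  path <- file.path(tempdir(), "weather.csv")
  write_weather_csv(w, path)
  back <- read_weather_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(w), tolerance = 1e-12)
})
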