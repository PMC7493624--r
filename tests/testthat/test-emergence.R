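# Independent straight-line reimplementation of the per-seed daily rules,
# for deterministic scenarios (fixed thermal-time requirement, no
# aggregates). Used as the oracle for the engine.
trace_one_seed <- function(depth, tt_req, weather, Tb, psi_b, elong,
                           crust_state, horizon, window = 30) {
  acc <- 0; tt_growth <- 0; germ_day <- NA; emerge_day <- NA; cause <- NA
  layer <- if (depth < 3) 1 else if (depth < 5) 2 else 3
  psi <- cbind(weather$psi_0_3, weather$psi_3_5, weather$psi_5_10)
  for (d in 1:horizon) {
    if (is.na(germ_day)) {
      if (psi[d, layer] > psi_b) acc <- acc + max(0, weather$soil_temp_C[d] - Tb)
      if (acc >= tt_req && d <= window) germ_day <- d
    } else {
      if (d - germ_day <= 2) {
        rad <- depth + elong$radicle_rate * tt_growth
        rl <- if (rad < 3) 1 else if (rad < 5) 2 else 3
        if (psi[d, rl] < psi_b) { cause <- "post_germination_water_stress"; break }
      }
      tt_growth <- tt_growth + max(0, weather$soil_temp_C[d] - elong$Tb_growth)
      if (elong$shoot_Lmax * (1 - exp(-elong$shoot_rate * tt_growth)) >= depth) {
        if (crust_state[d] == "dry") {
          upto <- min(d + elong$crust_wait, horizon)
          wet <- if (upto > d) which(crust_state[(d + 1):upto] == "wet")[1] else NA
          if (is.na(wet)) { cause <- "blocked_crust" } else {
            emerge_day <- d + wet; cause <- "emerged"
          }
        } else { emerge_day <- d; cause <- "emerged" }
        break
      }
    }
  }
  if (is.na(cause)) cause <- if (is.na(germ_day)) "non_germination" else "not_emerged"
  list(germ_day = germ_day, emerge_day = emerge_day, cause = cause)
}

run_one_seed <- function(depth, tt_req, weather, germ, elong) {
  cfg <- seedbed_config(1, depth = list(mean = depth, sd = 0, min = 1, max = 6),
                        crusting_class = "non_crusting")
  sb <- update_crust(build_seedbed(cfg, 1), weather)
  run_simulation(sb, weather, germ, elong, rng_seed = 4)
}

det_params <- function(tt_req, Tb = 4, psi_b = -0.6) {
  cultivar_params(Tb = Tb, Topt = 30, psi_b_mean = psi_b,
                  thermal_time_distribution = point_mass_tt(tt_req),
                  germinable_fraction = 1)
}

test_that("a hand-traced seed germinates day 2 and emerges day 5 at 13 C", {
  # 9 Cd/day above Tb = 4: requirement 18 Cd is met on day 2; the default
  # elongation law then needs 3 more days to push the shoot 3 cm up
  w <- no_stress_weather(35, temp = 13)
  elong <- elongation_params()
  res <- run_one_seed(3, 18, w, det_params(18), elong)
  expect_equal(res$fates$germination_day, 2L)
  expect_equal(res$fates$emergence_day, 5L)
  expect_equal(as.character(res$fates$cause), "emerged")
})

test_that("the engine matches the straight-line oracle day by day", {
  elong <- elongation_params()
  scenarios <- list(
    list(depth = 2, tt = 12, temp = 10),
    list(depth = 3, tt = 18, temp = 13),
    list(depth = 4.5, tt = 30, temp = 16),
    list(depth = 5.5, tt = 45, temp = 22),
    list(depth = 3, tt = 600, temp = 18))  # requirement never met: window
  for (s in scenarios) {
    w <- no_stress_weather(40, temp = s$temp)
    res <- run_one_seed(s$depth, s$tt, w, det_params(s$tt), elong)
    oracle <- trace_one_seed(s$depth, s$tt, w, Tb = 4, psi_b = -0.6, elong,
                             crust_state = rep("absent", 40), horizon = 40)
    expect_equal(res$fates$germination_day,
                 if (is.na(oracle$germ_day)) NA_integer_ else as.integer(oracle$germ_day))
    expect_equal(res$fates$emergence_day,
                 if (is.na(oracle$emerge_day)) NA_integer_ else as.integer(oracle$emerge_day))
    expect_equal(as.character(res$fates$cause), oracle$cause)
  }
})

test_that("the oracle agrees on water-stress death and crust blocking", {
  elong <- elongation_params()
  # dries out right after typical germination (day 3 onward)
  psi <- c(-0.01, -0.01, rep(-0.9, 33))
  w_dry <- weather_series(rep(13, 35), rep(0, 35), psi, psi, psi)
  res <- run_one_seed(3, 18, w_dry, det_params(18), elong)
  oracle <- trace_one_seed(3, 18, w_dry, 4, -0.6, elong,
                           rep("absent", 35), 35)
  expect_equal(as.character(res$fates$cause), oracle$cause)
  expect_equal(oracle$cause, "post_germination_water_stress")

  # a crust formed by a single 20 mm rain on day 1, dry ever after
  rain <- c(20, rep(0, 34))
  w_cr <- weather_series(rep(13, 35), rain, rep(-0.05, 35), rep(-0.05, 35),
                         rep(-0.05, 35))
  cfg <- seedbed_config(1, depth = list(mean = 3, sd = 0, min = 1, max = 6),
                        crusting_class = "highly_crusting",
                        crust_rainfall_threshold = 15)
  sb <- update_crust(build_seedbed(cfg, 1), w_cr)
  res <- run_simulation(sb, w_cr, det_params(18), elong, rng_seed = 4)
  oracle <- trace_one_seed(3, 18, w_cr, 4, -0.6, elong, sb$crust_state, 35)
  expect_equal(as.character(res$fates$cause), oracle$cause)
  expect_equal(oracle$cause, "blocked_crust")
})

test_that("without any mortality pathway every seed emerges", {
  germ <- cultivar_params(Tb = 4, Topt = 30, psi_b_mean = -0.6,
                          thermal_time_distribution =
                            soybean_cultivar_params("Ecudor")$thermal_time_distribution,
                          germinable_fraction = 1)
  sb <- update_crust(build_seedbed(bare_seedbed(500), 1),
                     no_stress_weather(35))
  res <- run_simulation(sb, no_stress_weather(35), germ, rng_seed = 6)
  expect_equal(res$final_emergence_rate, 100)
  expect_equal(unname(res$cause_partition["emerged"]), 100)
})

test_that("fates are conserved and the emergence curve is monotone", {
  tp <- soybean_cultivar_params("Ecudor")
  w <- generate_weather("warm_wet", 35, rng_seed = 12)
  cfg <- seedbed_template("silty_clay_loam", n_seeds = 400)
  sb <- update_crust(build_seedbed(cfg, 3), w)
  res <- run_simulation(sb, w, tp, rng_seed = 5)
  expect_equal(nrow(res$fates), 400)
  expect_equal(sum(res$cause_partition), 100, tolerance = 1e-9)
  expect_true(all(diff(res$daily_emerged) >= 0))
  n_germ <- sum(!is.na(res$fates$germination_day))
  expect_lte(max(res$daily_emerged), n_germ)
  expect_lte(n_germ, 400)
  # emergence strictly after germination
  both <- !is.na(res$fates$emergence_day)
  expect_true(all(res$fates$emergence_day[both] >=
                    res$fates$germination_day[both] + 1))
})

test_that("cause partition equals an independent recount of the fate list", {
  tp <- soybean_cultivar_params("Santana")
  w <- generate_weather("crust_prone", 35, rng_seed = 2)
  cfg <- seedbed_template("silty_loam", n_seeds = 300)
  sb <- update_crust(build_seedbed(cfg, 7), w)
  res <- run_simulation(sb, w, tp, rng_seed = 8)
  recount <- vapply(fate_causes(), function(cz)
    100 * sum(res$fates$cause == cz) / nrow(res$fates), numeric(1))
  expect_equal(res$cause_partition, recount)
  expect_error(cause_partition(res$fates[0, ]), "empty")
})

test_that("absent pathways contribute exactly zero mortality", {
  tp <- soybean_cultivar_params("Ecudor")
  w <- no_stress_weather(35)
  # no aggregates, no crust, always wet
  sb <- update_crust(build_seedbed(bare_seedbed(800), 2), w)
  res <- run_simulation(sb, w, tp, rng_seed = 3)
  expect_equal(unname(res$cause_partition["blocked_aggregate"]), 0)
  expect_equal(unname(res$cause_partition["blocked_crust"]), 0)
  expect_equal(unname(res$cause_partition["post_germination_water_stress"]), 0)
})

test_that("a crusting silty loam under heavy rain blocks some seedlings", {
  tp <- soybean_cultivar_params("Ecudor")
  rain <- c(20, rep(0, 34))  # crust forms day 1 and stays dry
  w <- weather_series(rep(16, 35), rain, rep(-0.05, 35), rep(-0.05, 35),
                      rep(-0.05, 35))
  cfg <- seedbed_template("silty_loam", n_seeds = 500)
  sb <- update_crust(build_seedbed(cfg, 4), w)
  res <- run_simulation(sb, w, tp, rng_seed = 9)
  expect_gt(res$cause_partition["blocked_crust"], 0)
})

test_that("uniformly colder weather never speeds up 50% emergence", {
  tp <- soybean_cultivar_params("Isidor")
  t50 <- vapply(c(20, 16, 12, 9), function(temp) {
    w <- no_stress_weather(60, temp = temp)
    sb <- update_crust(build_seedbed(bare_seedbed(400), 5), w)
    res <- run_simulation(sb, w, tp, horizon_days = 60, rng_seed = 11)
    which(res$daily_emerged >= 0.5 * res$n_seeds)[1]
  }, numeric(1))
  expect_true(all(diff(t50) >= 0))
})

test_that("short horizons and short weather are rejected", {
  tp <- soybean_cultivar_params("Ecudor")
  sb <- build_seedbed(bare_seedbed(10), 1)
  expect_error(run_simulation(sb, no_stress_weather(20), tp, rng_seed = 1),
               ">= 30")
  expect_error(run_simulation(sb, no_stress_weather(35), tp,
                              horizon_days = 40, rng_seed = 1),
               "shorter")
})

test_that("replicate summaries are deterministic and binomially tight", {
  tp <- soybean_cultivar_params("Ecudor")  # germinable 0.97
  w <- no_stress_weather(35)
  cfg <- bare_seedbed(1000)
  a <- replicate_simulations(cfg, w, tp, n_replicates = 10, master_seed = 21)
  b <- replicate_simulations(cfg, w, tp, n_replicates = 10, master_seed = 21)
  expect_identical(a$summary, b$summary)
  fr <- a$summary[a$summary$quantity == "final_emergence_rate", ]
  # binomial scale: sd of the final rate ~ sqrt(.97*.03/1000) = 0.54 pp
  expect_lt(fr$sd, 1.5)
  expect_equal(fr$mean, 97, tolerance = 0.02)

  single <- replicate_simulations(cfg, w, tp, n_replicates = 1,
                                  master_seed = 5)
  expect_equal(single$summary$sd, rep(0, nrow(single$summary)))
  expect_equal(single$summary$mean[1],
               single$runs[[1]]$final_emergence_rate)
})
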