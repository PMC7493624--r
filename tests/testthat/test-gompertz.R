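test_that("fit recovers exact parameters from a noiseless curve", {
  tc <- exact_gompertz_course(A = 0.99, k = 0.1, tm = 30)
  f <- fit_gompertz(tc)
  expect_lt(abs(f$A - 0.99) / 0.99, 1e-6)
  expect_lt(abs(f$k - 0.1) / 0.1, 1e-6)
  expect_lt(abs(f$tm - 30) / 30, 1e-6)
})

test_that("a course plateauing at 99/100 seeds yields an asymptote near 0.99", {
  times <- seq(8, 200, by = 8)
  counts <- pmin(99, round(gompertz(times, 0.99, 0.08, 40) * 100))
  tc <- germination_time_course(
    "temperature", 25,
    data.frame(replicate = 1, time_h = times, cum_germinated = counts), 100)
  f <- fit_gompertz(tc)
  expect_equal(f$A, 0.99, tolerance = 0.01)
})

test_that("median fitted asymptote is unbiased under binomial dish sampling", {
  # 4 replicates x 25 seeds drawn binomially from a known curve; the
  # generating parameters are the oracle
  A_true <- 0.97; k_true <- 0.08; tm_true <- 40
  times <- seq(8, 200, by = 8)
  set.seed(101)
  A_hat <- replicate(200, {
    obs <- do.call(rbind, lapply(1:4, function(r) {
      # per-seed germination times: inverse-CDF of the Gompertz curve
      u <- runif(25)
      h <- ifelse(u < A_true, gompertz_inverse(u, A_true, k_true, tm_true), Inf)
      data.frame(replicate = r, time_h = times,
                 cum_germinated = vapply(times, function(t) sum(h <= t),
                                         numeric(1)))
    }))
    tc <- germination_time_course("temperature", 20, obs, 25)
    fit_gompertz(tc)$A
  })
  expect_lt(abs(median(A_hat) - A_true), 0.02)
})

test_that("degenerate inputs are rejected", {
  times <- seq(8, 80, by = 8)
  zero <- germination_time_course(
    "temperature", 3,
    data.frame(replicate = 1, time_h = times, cum_germinated = 0 * times), 25)
  expect_error(fit_gompertz(zero), "all counts are zero")
  short <- data.frame(time_h = c(1, 2, 3), fraction = c(0.1, 0.5, 0.9))
  expect_error(fit_gompertz(short), "4 distinct observation times")
})

test_that("forward and inverse Gompertz round-trip to 1e-9", {
  A <- 0.95; k <- 0.07; tm <- 33
  p <- seq(0.01, 0.94, by = 0.01)
  expect_equal(gompertz(gompertz_inverse(p, A, k, tm), A, k, tm), p,
               tolerance = 1e-9)
})

test_that("percentile times follow the closed-form inverse", {
  f <- structure(list(A = 1, k = 0.1, tm = 30, rss = 0, n_obs = 10,
                      converged = TRUE), class = "gompertz_fit")
  pr <- percentile_rates(f)
  t50 <- pr$time[pr$percentile == 50]
  expect_equal(t50, 30 - log(log(2)) / 0.1, tolerance = 1e-12)
  expect_equal(t50, 33.66513, tolerance = 1e-5)
  expect_equal(pr$rate, 1 / pr$time)
})

test_that("unreachable percentiles yield NA, not an error", {
  f <- structure(list(A = 0.85, k = 0.1, tm = 30, rss = 0, n_obs = 10,
                      converged = TRUE), class = "gompertz_fit")
  pr <- percentile_rates(f)
  expect_true(is.na(pr$rate[pr$percentile == 90]))
  expect_false(anyNA(pr$rate[pr$percentile <= 80]))
})

test_that("the offset of percentile times from tm scales as 1/k", {
  # doubling k halves (Tp - tm) for every percentile: steeper curves
  # contract the spread of percentile times around the inflection
  for (p in c(20, 40, 50, 60, 80, 90)) {
    off <- vapply(c(0.05, 0.1, 0.2), function(k) {
      f <- structure(list(A = 0.99, k = k, tm = 30, rss = 0, n_obs = 10,
                          converged = TRUE), class = "gompertz_fit")
      percentile_rates(f, p)$time - 30
    }, numeric(1))
    expect_equal(off[1] / off[2], 2, tolerance = 1e-9)
    expect_equal(off[2] / off[3], 2, tolerance = 1e-9)
  }
})

test_that("rates increase with k for percentiles past the inflection", {
  # brute-force grid: the germination rate 1/Tp grows with k wherever the
  # percentile lies above the curve's inflection fraction A/e
  ks <- seq(0.02, 0.3, by = 0.02)
  for (p in c(40, 50, 60, 80, 90)) {
    rates <- vapply(ks, function(k) {
      f <- structure(list(A = 0.99, k = k, tm = 30, rss = 0, n_obs = 10,
                          converged = TRUE), class = "gompertz_fit")
      percentile_rates(f, p)$rate
    }, numeric(1))
    expect_true(all(diff(rates) > 0))
  }
})

test_that("percentile times strictly increase with the percentile", {
  set.seed(5)
  for (i in 1:20) {
    f <- structure(list(A = runif(1, 0.91, 1), k = runif(1, 0.02, 0.3),
                        tm = runif(1, 10, 60), rss = 0, n_obs = 10,
                        converged = TRUE), class = "gompertz_fit")
    tp <- percentile_rates(f)$time
    tp <- tp[!is.na(tp)]
    expect_true(all(diff(tp) > 0))
  }
})

test_that("fitting does not disturb the caller's RNG stream", {
  tc <- exact_gompertz_course(A = 0.9, k = 0.1, tm = 30)
  set.seed(42); a <- runif(1)
  set.seed(42); invisible(fit_gompertz(tc)); b <- runif(1)
  expect_identical(a, b)
})
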