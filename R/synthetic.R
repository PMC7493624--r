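#' Generate synthetic laboratory germination time-courses
#'
#' Simulates the standard incubation design (replicated dishes of seeds
#' scored up to three times a day) from known generating parameters, so the
#' whole estimation stack can be exercised against a ground truth.
#'
#' Each seed draws one quantile \eqn{v \sim U(0,1)} that sets both its
#' thermal-time requirement (inverse CDF of the cultivar's thermal-time
#' distribution) and its base water potential (linear in \eqn{v} over
#' \code{psi_b_range}); fast-germinating seeds thus have the lowest base
#' water potential, matching the usual seed-lot ordering. A seed is
#' germinable with probability \code{germinable_fraction} (independent
#' Bernoulli). At a temperature level \eqn{T} the germination time is
#' \eqn{\theta / (T - T_b)} days; at a water-potential level \eqn{\psi}
#' (incubated at \code{ref_temp}) the thermal accumulation rate is scaled by
#' \eqn{\max(0, \psi - \psi_b) / (0 - \psi_b)}, a linear rate reduction
#' consistent with the x-intercept estimation model. Counts are recorded on
#' a fixed scoring grid, so binomial noise arises naturally from the
#' seed-level draws.
#'
#' @param true_params a \code{\link{cultivar_params}} holding the generating
#'   truth.
#' @param temperatures incubation temperatures (degrees C); a level at or
#'   below \code{Tb} validly yields all-zero counts.
#' @param potentials water potentials (MPa, <= 0) incubated at
#'   \code{ref_temp}.
#' @param n_seeds seeds per replicate dish (default 25).
#' @param n_replicates replicate dishes per level (default 4).
#' @param rng_seed integer seed.
#' @param psi_b_range range (MPa) over which per-seed base water potentials
#'   vary; default the range of \code{psi_b_by_percentile} when present,
#'   else \code{psi_b_mean} +/- 0.125 MPa.
#' @param ref_temp incubation temperature of the water-potential series
#'   (degrees C, default 20).
#' @param obs_per_day scorings per day (default 3).
#' @param max_days length of the scoring window (default 28 days).
#' @return list of \code{\link{germination_time_course}} objects, one per
#'   level (temperatures first, then potentials).
#' @export
generate_time_courses <- function(true_params, temperatures = NULL,
                                  potentials = NULL, n_seeds = 25,
                                  n_replicates = 4, rng_seed = 1L,
                                  psi_b_range = NULL, ref_temp = 20,
                                  obs_per_day = 3, max_days = 28) {
  stopifnot(inherits(true_params, "cultivar_params"))
  if (is.null(psi_b_range)) {
    psi_b_range <- if (!is.null(true_params$psi_b_by_percentile))
      range(true_params$psi_b_by_percentile)
    else true_params$psi_b_mean + c(-0.125, 0.125)
  }
  set.seed(rng_seed)
  obs_times <- seq(24 / obs_per_day, max_days * 24, by = 24 / obs_per_day)
  courses <- list()

  make_course <- function(level_type, level, hour_fun) {
    obs <- lapply(seq_len(n_replicates), function(r) {
      v <- stats::runif(n_seeds)
      germinable <- stats::runif(n_seeds) < true_params$germinable_fraction
      tt <- tt_quantile(v, true_params$thermal_time_distribution)
      psi_b <- psi_b_range[1] + diff(psi_b_range) * v
      hours <- hour_fun(tt, psi_b)
      hours[!germinable] <- Inf
      data.frame(replicate = r, time_h = obs_times,
                 cum_germinated = vapply(obs_times,
                                         function(t) sum(hours <= t),
                                         numeric(1)))
    })
    germination_time_course(level_type, level, do.call(rbind, obs), n_seeds)
  }

  for (T in temperatures) {
    courses[[length(courses) + 1L]] <- make_course(
      "temperature", T,
      function(tt, psi_b) {
        if (T <= true_params$Tb) rep(Inf, length(tt))
        else tt / (T - true_params$Tb) * 24
      })
  }
  for (psi in potentials) {
    courses[[length(courses) + 1L]] <- make_course(
      "water_potential", psi,
      function(tt, psi_b) {
        f <- pmax(0, psi - psi_b) / (0 - psi_b)
        ifelse(f > 0, tt / ((ref_temp - true_params$Tb) * f) * 24, Inf)
      })
  }
  courses
}

# Inverse CDF of a discrete thermal-time class distribution, uniform within
# classes.
tt_quantile <- function(v, ttd) {
  cl <- if (inherits(ttd, "thermal_time_distribution")) ttd$classes else ttd
  cum <- cumsum(cl$prob)
  idx <- findInterval(v, c(0, cum), rightmost.closed = TRUE,
                      all.inside = TRUE)
  prev <- c(0, cum)[idx]
  frac <- (v - prev) / cl$prob[idx]
  cl$lower[idx] + frac * (cl$upper[idx] - cl$lower[idx])
}

#' Reference germination parameter sets for three soybean cultivars
#'
#' Laboratory-measured germination parameters for cvs. Ecudor (maturity
#' group II), Isidor (MG I) and Santana (MG I/II): base temperature 4, 3 and
#' 3.5 degrees C; optimum temperature 28, 30 and 30 degrees C; mean base
#' water potential -0.58, -0.56 and -0.71 MPa (per-seed values spanning
#' roughly -0.75 to -0.50 MPa); final germination 97%, 99% and 97%. The
#' thermal-time distribution has its median at 18 degree-days with almost
#' all mass below 40 degree-days, shared by the three cultivars.
#'
#' @param cultivar one of \code{"Ecudor"}, \code{"Isidor"},
#'   \code{"Santana"}.
#' @return a \code{\link{cultivar_params}}.
#' @export
soybean_cultivar_params <- function(cultivar = c("Ecudor", "Isidor",
                                                 "Santana")) {
  cultivar <- match.arg(cultivar)
  p <- switch(cultivar,
    Ecudor = list(Tb = 4, Topt = 28, psi = -0.58, gf = 0.97),
    Isidor = list(Tb = 3, Topt = 30, psi = -0.56, gf = 0.99),
    Santana = list(Tb = 3.5, Topt = 30, psi = -0.71, gf = 0.97))
  # Gompertz-shaped requirement distribution in thermal time: median 18 Cd,
  # <1% of mass above 40 Cd
  lower <- seq(0, 55, by = 5)
  upper <- lower + 5
  cdf <- function(x) exp(-exp(-0.2 * (x - 16.2)))
  prob <- cdf(upper) - cdf(lower)
  pcts <- c(20, 40, 50, 60, 80, 90)
  psi_by_p <- stats::setNames(p$psi + c(-0.12, -0.05, 0, 0.02, 0.07, 0.08),
                              pcts)
  psi_by_p <- pmin(psi_by_p, 0)
  cultivar_params(Tb = p$Tb, Topt = p$Topt, psi_b_mean = p$psi,
                  thermal_time_distribution =
                    thermal_time_classes(lower, upper, prob),
                  germinable_fraction = p$gf,
                  psi_b_by_percentile = psi_by_p,
                  cultivar = cultivar)
}

#' Seedbed templates by soil type
#'
#' Ready-made \code{\link{seedbed_config}}s reflecting the crust sensitivity
#' of common seedbed soils: clay and silty clay resist crusting, silty loam
#' is highly crust-prone, silty clay loam and clay loam moderately so. All
#' templates carry a coarse aggregate structure typical of conventional
#' tillage; the clay template carries the coarsest one.
#'
#' @param name one of \code{"clay"}, \code{"silty_loam"},
#'   \code{"silty_clay_loam"}, \code{"clay_loam"}, \code{"silty_clay"}.
#' @param n_seeds number of seeds sown (default 1000).
#' @return a \code{\link{seedbed_config}}.
#' @export
seedbed_template <- function(name = c("clay", "silty_loam",
                                      "silty_clay_loam", "clay_loam",
                                      "silty_clay"),
                             n_seeds = 1000) {
  name <- match.arg(name)
  crusting <- switch(name,
                     clay = "non_crusting",
                     silty_clay = "non_crusting",
                     silty_loam = "highly_crusting",
                     silty_clay_loam = "moderately_crusting",
                     clay_loam = "moderately_crusting")
  coarse <- name %in% c("clay", "silty_clay")
  aggregates <- data.frame(
    diameter_cm = c(1, 2, 4, 2),
    count_per_m2 = if (coarse) c(400, 200, 60, 40) else c(300, 150, 40, 30),
    surface = c(FALSE, FALSE, FALSE, TRUE))
  seedbed_config(n_seeds = n_seeds,
                 depth = list(mean = 3, sd = 0.7, min = 1, max = 6),
                 aggregates = aggregates, crusting_class = crusting)
}
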