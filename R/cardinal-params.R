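#' Assemble percentile rates across incubation levels into a long table
#'
#' @param rates_by_level either a named list of
#'   \code{\link{percentile_rates}} tables (names are the numeric level:
#'   temperature in degrees C or water potential in MPa), or a data frame
#'   already holding columns \code{level}, \code{percentile}, \code{rate}.
#' @return data frame with columns \code{level}, \code{percentile},
#'   \code{rate}.
#' @export
rates_table <- function(rates_by_level) {
  if (is.data.frame(rates_by_level)) {
    stopifnot(all(c("level", "percentile", "rate") %in% names(rates_by_level)))
    return(rates_by_level[, c("level", "percentile", "rate")])
  }
  lv <- as.numeric(names(rates_by_level))
  if (any(is.na(lv))) stop("rates_by_level must be named by numeric level values")
  do.call(rbind, Map(function(pr, l) {
    data.frame(level = l, percentile = pr$percentile, rate = pr$rate)
  }, rates_by_level, lv))
}

# Per-percentile OLS of rate on level; returns x-intercepts and R^2.
xintercept_regressions <- function(tab, levels_used) {
  sub <- tab[tab$level %in% levels_used & !is.na(tab$rate), ]
  res <- lapply(split(sub, sub$percentile), function(g) {
    if (length(unique(g$level)) < 3) return(NULL)
    m <- stats::lm(rate ~ level, data = g)
    b <- stats::coef(m)
    tss <- sum((g$rate - mean(g$rate))^2)
    r2 <- if (tss > 0) 1 - sum(stats::resid(m)^2) / tss else NA_real_
    data.frame(percentile = g$percentile[1],
               slope = unname(b[2]), intercept = unname(b[1]),
               x_intercept = -unname(b[1]) / unname(b[2]),
               r_squared = r2)
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

#' Estimate the base temperature for germination
#'
#' The base temperature Tb is the temperature below which the germination
#' rate is zero. For each percentile (1/T20 ... 1/T90), the germination rate
#' is regressed on temperature over the sub-optimal range, and the
#' x-intercept of that regression is the per-percentile base temperature; Tb
#' is their unweighted mean.
#'
#' The sub-optimal range is chosen automatically as the largest contiguous
#' set (in sorted temperature order, ending at the fastest temperature) of
#' temperatures at or below the rate peak for which every percentile
#' regression attains R-squared at least \code{r2_min}; if no window of at
#' least three temperatures qualifies, the window with the highest mean
#' R-squared is used and a warning is recorded in the diagnostics. An
#' explicit \code{temperatures} argument overrides the automatic selection.
#'
#' @param rates_by_temperature named list of \code{\link{percentile_rates}}
#'   (names = incubation temperature, degrees C) or a long data frame; see
#'   \code{\link{rates_table}}.
#' @param r2_min minimum per-percentile R-squared for the automatic linear
#'   range selection (default 0.95).
#' @param temperatures optional explicit vector of temperatures to regress
#'   over, bypassing automatic selection.
#' @return list of class \code{base_temperature_fit}: \code{Tb} (degrees C),
#'   \code{x_intercepts} (per-percentile data frame with slopes and
#'   R-squared), \code{linear_range} (temperatures used),
#'   \code{diagnostics} (character vector of warnings, possibly empty).
#' @export
estimate_base_temperature <- function(rates_by_temperature, r2_min = 0.95,
                                      temperatures = NULL) {
  tab <- rates_table(rates_by_temperature)
  est <- estimate_base_level(tab, r2_min, levels_used = temperatures,
                             what = "temperature")
  structure(list(Tb = est$value, x_intercepts = est$per_percentile,
                 linear_range = est$levels_used,
                 diagnostics = est$diagnostics),
            class = "base_temperature_fit")
}

#' Estimate the base water potential for germination
#'
#' Analogous to \code{\link{estimate_base_temperature}}: per-percentile OLS
#' of germination rate on water potential (all levels measured at one fixed
#' temperature), x-intercept = per-percentile base water potential. The mean
#' over percentiles is reported together with the full per-percentile set;
#' the spread between the fastest and slowest percentiles reflects seed-lot
#' variation in the base water potential.
#'
#' @param rates_by_potential named list of \code{\link{percentile_rates}}
#'   (names = water potential, MPa, non-positive) or a long data frame.
#' @param r2_min minimum R-squared for automatic level selection.
#' @param potentials optional explicit vector of potentials to use.
#' @return list of class \code{base_psi_fit}: \code{psi_b_mean} (MPa),
#'   \code{psi_b_by_percentile} (named numeric vector), \code{x_intercepts},
#'   \code{levels_used}, \code{diagnostics}.
#' @export
estimate_base_water_potential <- function(rates_by_potential, r2_min = 0.95,
                                          potentials = NULL) {
  tab <- rates_table(rates_by_potential)
  if (any(tab$level > 0)) stop("water potentials must be <= 0 MPa")
  est <- estimate_base_level(tab, r2_min, levels_used = potentials,
                             what = "water potential")
  psi_by_p <- stats::setNames(est$per_percentile$x_intercept,
                              est$per_percentile$percentile)
  structure(list(psi_b_mean = est$value, psi_b_by_percentile = psi_by_p,
                 x_intercepts = est$per_percentile,
                 levels_used = est$levels_used,
                 diagnostics = est$diagnostics),
            class = "base_psi_fit")
}

# Shared x-intercept machinery for Tb and psi_b.
estimate_base_level <- function(tab, r2_min, levels_used, what) {
  diagnostics <- character()
  lv <- sort(unique(tab$level[!is.na(tab$rate)]))
  if (is.null(levels_used)) {
    # restrict to the sub-peak branch: levels up to the argmax of median rate
    med_rate <- vapply(lv, function(l)
      stats::median(tab$rate[tab$level == l], na.rm = TRUE), numeric(1))
    sub <- lv[seq_len(which.max(med_rate))]
    if (length(sub) < 3) {
      # no rising branch (rates peak at the lowest level): fall through to
      # the full set so the slope sign check can diagnose the response
      if (length(lv) >= 3) sub <- lv
      else stop("need at least 3 sub-optimal ", what,
                " levels with defined rates")
    }
    # contiguous windows ending anywhere, >= 3 levels; prefer longest passing
    wins <- list()
    for (i in seq_along(sub)) for (j in seq_along(sub)) {
      if (j - i + 1 >= 3) wins[[length(wins) + 1L]] <- sub[i:j]
    }
    scores <- lapply(wins, function(w) {
      reg <- xintercept_regressions(tab, w)
      if (is.null(reg) || nrow(reg) == 0) return(NULL)
      list(w = w, min_r2 = min(reg$r_squared), mean_r2 = mean(reg$r_squared))
    })
    scores <- scores[!vapply(scores, is.null, logical(1))]
    if (!length(scores)) stop("insufficient data: no usable ", what, " window")
    pass <- Filter(function(s) s$min_r2 >= r2_min, scores)
    if (length(pass)) {
      lens <- vapply(pass, function(s) length(s$w), numeric(1))
      best <- pass[lens == max(lens)]
      levels_used <- best[[which.max(vapply(best, `[[`, numeric(1), "mean_r2"))]]$w
    } else {
      levels_used <- scores[[which.max(vapply(scores, `[[`, numeric(1), "mean_r2"))]]$w
      diagnostics <- c(diagnostics, sprintf(
        "no %s window reached R^2 >= %.2f on every percentile; using best window",
        what, r2_min))
    }
  } else if (length(levels_used) < 3) {
    stop("need at least 3 ", what, " levels")
  }
  reg <- xintercept_regressions(tab, levels_used)
  if (is.null(reg) || nrow(reg) == 0)
    stop("insufficient data: fewer than 3 usable ", what, " levels per percentile")
  if (any(reg$slope <= 0))
    stop("no thermal response: non-positive slope of rate vs ", what)
  list(value = mean(reg$x_intercept), per_percentile = reg,
       levels_used = levels_used, diagnostics = diagnostics)
}

#' Estimate the optimum temperature for germination
#'
#' Fits a unimodal beta-type temperature-response function to the median
#' germination rate at each temperature:
#' \deqn{r(T) = r_{max} \frac{T_{max}-T}{T_{max}-T_{opt}}
#'   \left(\frac{T-T_{min}}{T_{opt}-T_{min}}\right)^{(T_{opt}-T_{min})/(T_{max}-T_{opt})}}
#' for \eqn{T_{min} < T < T_{max}} and 0 outside. The optimum temperature is
#' the fitted \eqn{T_{opt}} (the argmax of the curve); the fitted
#' \eqn{T_{min}}, \eqn{T_{max}} bounds are reported alongside. If the fit
#' fails or places the optimum on the data boundary, the temperature with the
#' highest observed rate is returned with a boundary warning.
#'
#' @param rates_by_temperature as in \code{\link{estimate_base_temperature}};
#'   must span both sides of the rate peak (>= 5 temperatures).
#' @param percentile which percentile's rate to use as the germination speed
#'   (default 50, i.e. 1/T50).
#' @return list of class \code{optimum_temperature_fit}: \code{Topt},
#'   \code{Tmax_fit}, \code{Tmin_fit}, \code{rmax}, \code{boundary}
#'   (logical), \code{diagnostics}.
#' @export
estimate_optimum_temperature <- function(rates_by_temperature, percentile = 50) {
  tab <- rates_table(rates_by_temperature)
  d <- tab[tab$percentile == percentile & !is.na(tab$rate), c("level", "rate")]
  d <- d[order(d$level), ]
  if (nrow(d) < 5)
    stop("need rates at >= 5 temperatures spanning both sides of the peak")
  t_peak <- d$level[which.max(d$rate)]
  diagnostics <- character()
  start <- list(rmax = max(d$rate), Tmin = min(d$level) - 2,
                Topt = t_peak, Tmax = max(d$level) + 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ beta_response(level, rmax, Tmin, Topt, Tmax), data = d,
      start = start,
      lower = c(rmax = 0, Tmin = -20, Topt = min(d$level), Tmax = t_peak),
      upper = c(rmax = Inf, Tmin = t_peak, Topt = max(d$level), Tmax = 90),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    diagnostics <- "beta-response fit failed; optimum taken at the data argmax"
    return(structure(list(Topt = t_peak, Tmax_fit = NA_real_,
                          Tmin_fit = NA_real_, rmax = max(d$rate),
                          boundary = TRUE, diagnostics = diagnostics),
                     class = "optimum_temperature_fit"))
  }
  cf <- stats::coef(fit)
  boundary <- cf["Topt"] <= min(d$level) + 1e-6 || cf["Topt"] >= max(d$level) - 1e-6
  if (boundary)
    diagnostics <- "fitted optimum on the data boundary; interpret with care"
  structure(list(Topt = unname(cf["Topt"]), Tmax_fit = unname(cf["Tmax"]),
                 Tmin_fit = unname(cf["Tmin"]), rmax = unname(cf["rmax"]),
                 boundary = boundary, diagnostics = diagnostics),
            class = "optimum_temperature_fit")
}

#' Beta-type cardinal-temperature response function
#'
#' @param T temperature (degrees C).
#' @param rmax rate at the optimum.
#' @param Tmin,Topt,Tmax cardinal temperatures, \code{Tmin < Topt < Tmax}.
#' @return response, zero outside (Tmin, Tmax).
#' @export
beta_response <- function(T, rmax, Tmin, Topt, Tmax) {
  out <- numeric(length(T))
  ok <- T > Tmin & T < Tmax & Topt > Tmin & Topt < Tmax
  ex <- (Topt - Tmin) / (Tmax - Topt)
  out[ok] <- rmax * ((Tmax - T[ok]) / (Tmax - Topt)) *
    ((T[ok] - Tmin) / (Topt - Tmin))^ex
  out
}
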