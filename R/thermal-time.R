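#' Derive the thermal-time-to-germination distribution
#'
#' Converts each sub/near-optimal time-course's time axis to thermal time
#' \eqn{(T - T_b) \cdot t} in degree-days (the incubator temperature is
#' constant within a course), pools the courses by summing counts at the
#' union of thermal times, fits a single Gompertz curve in thermal time, and
#' discretizes it into fixed-width classes whose probabilities sum to one.
#' The pooled asymptote is the germinable fraction of the seed lot.
#'
#' A diagnostic records whether the courses collapse onto one curve in
#' thermal time: the between-level root-mean-square difference of cumulative
#' fractions at matched thermal times is reported, with a warning entry if it
#' exceeds \code{collapse_tol}.
#'
#' @param courses list of \code{\link{germination_time_course}} objects at
#'   temperatures within the pooled linear range (temperature levels only).
#' @param Tb base temperature (degrees C), from
#'   \code{\link{estimate_base_temperature}}.
#' @param class_width thermal-time class width in degree-days (default 5).
#' @param tt_max upper bound of the discretization in degree-days
#'   (default 60).
#' @param collapse_tol tolerance on the between-level RMS of fractions
#'   (default 0.1).
#' @return list of class \code{thermal_time_distribution}: \code{classes}
#'   (data frame \code{lower}, \code{upper}, \code{prob} summing to 1),
#'   \code{germinable_fraction}, \code{fit} (the pooled
#'   \code{gompertz_fit} in degree-days), \code{collapse_rms},
#'   \code{diagnostics}.
#' @export
derive_thermal_time_distribution <- function(courses, Tb, class_width = 5,
                                             tt_max = 60, collapse_tol = 0.1) {
  stopifnot(length(courses) >= 1, is.numeric(Tb))
  pooled <- lapply(courses, function(tc) {
    if (tc$level_type != "temperature")
      stop("thermal-time pooling needs temperature-level courses")
    if (tc$level_value <= Tb)
      stop("course temperature must exceed the base temperature")
    p <- pool_replicates(tc)
    p$tt <- (tc$level_value - Tb) * p$time_h / 24
    p
  })

  # between-level collapse diagnostic: compare fractions on a common tt grid
  diagnostics <- character()
  collapse_rms <- NA_real_
  if (length(pooled) >= 2) {
    grid <- seq(0, min(vapply(pooled, function(p) max(p$tt), numeric(1))),
                length.out = 25)[-1]
    fr <- vapply(pooled, function(p) {
      stats::stepfun(p$tt, c(0, p$fraction), right = FALSE)(grid)
    }, numeric(length(grid)))
    collapse_rms <- sqrt(mean((fr - rowMeans(fr))^2))
    if (collapse_rms > collapse_tol)
      diagnostics <- c(diagnostics, sprintf(
        "courses do not collapse in thermal time (RMS %.3f > %.3f)",
        collapse_rms, collapse_tol))
  }

  # pool by stacking each course's own (thermal time, fraction) points:
  # every point is an exact empirical CDF value at that course's scoring
  # time, so no course is evaluated between its own observations
  stacked <- do.call(rbind, lapply(pooled, function(p)
    data.frame(time_h = p$tt, fraction = p$fraction)))
  fit <- fit_gompertz(stacked)

  lower <- seq(0, tt_max - class_width, by = class_width)
  upper <- lower + class_width
  mass <- gompertz(upper, fit$A, fit$k, fit$tm) -
    gompertz(lower, fit$A, fit$k, fit$tm)
  mass[mass < 0] <- 0
  if (sum(mass) <= 0) stop("no probability mass within the thermal-time range")
  classes <- data.frame(lower = lower, upper = upper, prob = mass / sum(mass))

  structure(list(classes = classes, germinable_fraction = fit$A, fit = fit,
                 collapse_rms = collapse_rms, diagnostics = diagnostics),
            class = "thermal_time_distribution")
}

#' Construct a thermal-time distribution from explicit class probabilities
#'
#' Convenience constructor used by the synthetic-data generator and in
#' tests: fixed-width classes in degree-days with given probabilities
#' (renormalized to sum to one).
#'
#' @param lower,upper class bounds in degree-days.
#' @param prob class probabilities (any non-negative weights).
#' @return a \code{thermal_time_distribution} (without a pooled fit).
#' @export
thermal_time_classes <- function(lower, upper, prob) {
  stopifnot(length(lower) == length(upper), length(prob) == length(lower),
            all(upper > lower), all(prob >= 0), sum(prob) > 0)
  structure(list(classes = data.frame(lower = lower, upper = upper,
                                      prob = prob / sum(prob)),
                 germinable_fraction = NA_real_, fit = NULL,
                 collapse_rms = NA_real_, diagnostics = character()),
            class = "thermal_time_distribution")
}

#' Sample per-seed thermal-time requirements
#'
#' Draws a thermal-time class by its probability and a uniform position
#' within the class.
#'
#' @param n number of draws.
#' @param ttd a \code{thermal_time_distribution} (its \code{classes} table is
#'   used).
#' @return numeric vector of thermal-time requirements in degree-days.
#' @export
draw_thermal_time <- function(n, ttd) {
  cl <- if (inherits(ttd, "thermal_time_distribution")) ttd$classes else ttd
  idx <- sample.int(nrow(cl), n, replace = TRUE, prob = cl$prob)
  stats::runif(n, cl$lower[idx], cl$upper[idx])
}

#' Median of a thermal-time distribution
#'
#' Linear interpolation within the class containing the 50% point of the
#' discretized cumulative distribution.
#'
#' @param ttd a \code{thermal_time_distribution}.
#' @return median thermal time in degree-days.
#' @export
thermal_time_median <- function(ttd) {
  cl <- ttd$classes
  cum <- cumsum(cl$prob)
  i <- which(cum >= 0.5)[1]
  prev <- if (i == 1) 0 else cum[i - 1]
  cl$lower[i] + (0.5 - prev) / cl$prob[i] * (cl$upper[i] - cl$lower[i])
}

#' Cultivar germination parameter set
#'
#' Bundles everything the emergence simulator needs about a cultivar's
#' germination biology: base temperature \code{Tb} (degrees C), optimum
#' temperature \code{Topt} (degrees C), mean base water potential
#' \code{psi_b_mean} (MPa) with its per-percentile values, the germinable
#' fraction of the seed lot, and the discrete distribution of thermal-time
#' requirements (degree-days).
#'
#' @param Tb base temperature for germination (degrees C).
#' @param Topt optimum temperature (degrees C); must exceed \code{Tb}.
#' @param psi_b_mean mean base water potential (MPa, <= 0).
#' @param thermal_time_distribution a
#'   \code{\link{thermal_time_classes}}/\code{\link{derive_thermal_time_distribution}}
#'   object.
#' @param germinable_fraction fraction of seeds capable of germinating, in
#'   [0, 1]; defaults to the distribution's pooled asymptote when available.
#' @param psi_b_by_percentile optional named vector of per-percentile base
#'   water potentials (MPa, <= 0).
#' @param Tmax_fit,Tmin_fit optional fitted bounds of the temperature
#'   response (degrees C).
#' @param cultivar optional cultivar label.
#' @return object of class \code{cultivar_params}.
#' @export
cultivar_params <- function(Tb, Topt, psi_b_mean, thermal_time_distribution,
                            germinable_fraction = NULL,
                            psi_b_by_percentile = NULL,
                            Tmax_fit = NA_real_, Tmin_fit = NA_real_,
                            cultivar = NA_character_) {
  stopifnot(Tb < Topt, psi_b_mean <= 0)
  if (!is.null(psi_b_by_percentile) && any(psi_b_by_percentile > 0))
    stop("per-percentile base water potentials must be <= 0 MPa")
  ttd <- thermal_time_distribution
  stopifnot(inherits(ttd, "thermal_time_distribution"))
  if (abs(sum(ttd$classes$prob) - 1) > 1e-9)
    stop("thermal-time class probabilities must sum to 1")
  if (is.null(germinable_fraction)) germinable_fraction <- ttd$germinable_fraction
  if (is.na(germinable_fraction) || germinable_fraction < 0 || germinable_fraction > 1)
    stop("germinable_fraction must be in [0, 1]")
  structure(list(cultivar = cultivar, Tb = Tb, Topt = Topt,
                 Tmax_fit = Tmax_fit, Tmin_fit = Tmin_fit,
                 psi_b_mean = psi_b_mean,
                 psi_b_by_percentile = psi_b_by_percentile,
                 germinable_fraction = germinable_fraction,
                 thermal_time_distribution = ttd),
            class = "cultivar_params")
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat(sprintf("Cultivar germination parameters%s\n",
              if (is.na(x$cultivar)) "" else paste0(" (", x$cultivar, ")")))
  cat(sprintf("  Tb = %.2f C, Topt = %.2f C, psi_b = %.3f MPa, germinable = %.3f\n",
              x$Tb, x$Topt, x$psi_b_mean, x$germinable_fraction))
  cat(sprintf("  thermal-time median = %.1f Cd over %d classes\n",
              thermal_time_median(x$thermal_time_distribution),
              nrow(x$thermal_time_distribution$classes)))
  invisible(x)
}

#' Serialize cultivar parameters to and from JSON
#'
#' The JSON schema is versioned (\code{schema: "cultivar_params/1"}) so files
#' remain readable across releases.
#'
#' @param params a \code{\link{cultivar_params}} object.
#' @param path file path.
#' @return \code{write_cultivar_params}: the path, invisibly;
#'   \code{read_cultivar_params}: a \code{cultivar_params} object.
#' @export
write_cultivar_params <- function(params, path) {
  stopifnot(inherits(params, "cultivar_params"))
  obj <- list(schema = "cultivar_params/1",
              cultivar = params$cultivar, Tb = params$Tb, Topt = params$Topt,
              Tmax_fit = params$Tmax_fit, Tmin_fit = params$Tmin_fit,
              psi_b_mean = params$psi_b_mean,
              psi_b_by_percentile = as.list(params$psi_b_by_percentile),
              germinable_fraction = params$germinable_fraction,
              thermal_time_classes = params$thermal_time_distribution$classes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_cultivar_params
#' @export
read_cultivar_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "cultivar_params/"))
    stop("not a cultivar_params JSON file")
  psi_p <- if (length(obj$psi_b_by_percentile)) unlist(obj$psi_b_by_percentile) else NULL
  cl <- obj$thermal_time_classes
  cultivar_params(
    Tb = obj$Tb, Topt = obj$Topt, psi_b_mean = obj$psi_b_mean,
    thermal_time_distribution = thermal_time_classes(cl$lower, cl$upper, cl$prob),
    germinable_fraction = obj$germinable_fraction,
    psi_b_by_percentile = psi_p,
    Tmax_fit = if (is.null(obj$Tmax_fit)) NA_real_ else obj$Tmax_fit,
    Tmin_fit = if (is.null(obj$Tmin_fit)) NA_real_ else obj$Tmin_fit,
    cultivar = if (is.null(obj$cultivar)) NA_character_ else obj$cultivar)
}

#' Fit all germination parameters for one cultivar from lab time-courses
#'
#' End-to-end estimation: Gompertz fits per incubation level, percentile
#' rates, base and optimum temperature, base water potential (when
#' water-potential courses are supplied), and the thermal-time distribution
#' pooled over the Tb linear range.
#'
#' @param temperature_courses list of \code{\link{germination_time_course}}
#'   objects at temperature levels.
#' @param potential_courses optional list of courses at water-potential
#'   levels (single fixed temperature).
#' @param percentiles percentiles used for rate regressions.
#' @param cultivar cultivar label.
#' @param ... passed to \code{\link{derive_thermal_time_distribution}}.
#' @return list of class \code{germination_lab_fit}: \code{params} (a
#'   \code{\link{cultivar_params}}), \code{Tb_fit}, \code{Topt_fit},
#'   \code{psi_fit} (or NULL), \code{fits} (per-level Gompertz fits),
#'   \code{diagnostics} data frame (level, A, k, tm, rss).
#' @export
fit_germination_lab <- function(temperature_courses, potential_courses = NULL,
                                percentiles = c(20, 40, 50, 60, 80, 90),
                                cultivar = NA_character_, ...) {
  fits <- lapply(temperature_courses, fit_gompertz)
  temps <- vapply(temperature_courses, `[[`, numeric(1), "level_value")
  names(fits) <- temps
  rates <- lapply(fits, percentile_rates, percentiles = percentiles)
  names(rates) <- temps

  tb_fit <- estimate_base_temperature(rates)
  # with fewer than 5 temperature levels the beta-response fit is not
  # identifiable; fall back to the temperature with the fastest rate
  topt_fit <- tryCatch(estimate_optimum_temperature(rates), error = function(e) {
    tab <- rates_table(rates)
    tab <- tab[tab$percentile == 50 & !is.na(tab$rate), ]
    structure(list(Topt = tab$level[which.max(tab$rate)],
                   Tmax_fit = NA_real_, Tmin_fit = NA_real_,
                   rmax = max(tab$rate), boundary = TRUE,
                   diagnostics = conditionMessage(e)),
              class = "optimum_temperature_fit")
  })

  psi_fit <- NULL
  # without water-potential data germination is treated as never
  # water-limited (any soil psi exceeds this)
  psi_b_mean <- -100
  psi_b_by_p <- NULL
  if (!is.null(potential_courses)) {
    pfits <- lapply(potential_courses, fit_gompertz)
    psis <- vapply(potential_courses, `[[`, numeric(1), "level_value")
    prates <- lapply(pfits, percentile_rates, percentiles = percentiles)
    names(prates) <- psis
    psi_fit <- estimate_base_water_potential(prates)
    psi_b_mean <- psi_fit$psi_b_mean
    psi_b_by_p <- psi_fit$psi_b_by_percentile
  }

  pooled_courses <- temperature_courses[temps %in% tb_fit$linear_range]
  ttd <- derive_thermal_time_distribution(pooled_courses, tb_fit$Tb, ...)

  params <- cultivar_params(
    Tb = tb_fit$Tb, Topt = topt_fit$Topt, psi_b_mean = psi_b_mean,
    thermal_time_distribution = ttd,
    psi_b_by_percentile = psi_b_by_p,
    Tmax_fit = topt_fit$Tmax_fit, Tmin_fit = topt_fit$Tmin_fit,
    cultivar = cultivar)

  diag <- data.frame(
    level = temps,
    A = vapply(fits, `[[`, numeric(1), "A"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    tm = vapply(fits, `[[`, numeric(1), "tm"),
    rss = vapply(fits, `[[`, numeric(1), "rss"))
  structure(list(params = params, Tb_fit = tb_fit, Topt_fit = topt_fit,
                 psi_fit = psi_fit, fits = fits, diagnostics = diag),
            class = "germination_lab_fit")
}
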