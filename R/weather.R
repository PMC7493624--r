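#' Daily seedbed weather series
#'
#' One row per day since sowing: soil temperature at sowing depth, rainfall,
#' and soil water potential in the 0-3, 3-5 and 5-10 cm layers.
#'
#' @param soil_temp_C daily soil temperature at sowing depth (degrees C).
#' @param rainfall_mm daily rainfall (mm, >= 0).
#' @param psi_0_3,psi_3_5,psi_5_10 daily soil water potential per layer
#'   (MPa, <= 0).
#' @return object of class \code{weather_series} (a data frame with columns
#'   \code{day}, \code{soil_temp_C}, \code{rainfall_mm}, \code{psi_0_3},
#'   \code{psi_3_5}, \code{psi_5_10}).
#' @export
weather_series <- function(soil_temp_C, rainfall_mm, psi_0_3, psi_3_5,
                           psi_5_10) {
  n <- length(soil_temp_C)
  stopifnot(length(rainfall_mm) == n, length(psi_0_3) == n,
            length(psi_3_5) == n, length(psi_5_10) == n)
  if (any(is.na(c(soil_temp_C, rainfall_mm, psi_0_3, psi_3_5, psi_5_10))))
    stop("weather series must have no missing days or values")
  if (any(rainfall_mm < 0)) stop("rainfall cannot be negative")
  if (any(c(psi_0_3, psi_3_5, psi_5_10) > 0))
    stop("soil water potentials must be <= 0 MPa")
  structure(data.frame(day = seq_len(n), soil_temp_C = soil_temp_C,
                       rainfall_mm = rainfall_mm, psi_0_3 = psi_0_3,
                       psi_3_5 = psi_3_5, psi_5_10 = psi_5_10),
            class = c("weather_series", "data.frame"))
}

#' Constant (scenario) weather
#'
#' Convenience builder for controlled scenarios: every day identical.
#'
#' @param horizon_days number of days.
#' @param soil_temp_C soil temperature (degrees C).
#' @param rainfall_mm daily rainfall (mm).
#' @param psi water potential applied to all three layers (MPa).
#' @return a \code{\link{weather_series}}.
#' @export
constant_weather <- function(horizon_days, soil_temp_C = 20,
                             rainfall_mm = 0, psi = -0.01) {
  one <- function(v) rep(v, horizon_days)
  weather_series(one(soil_temp_C), one(rainfall_mm), one(psi), one(psi),
                 one(psi))
}

#' Read and write the daily weather CSV dialect
#'
#' Columns: \code{day}, \code{soil_temp_sowing_depth_C}, \code{rainfall_mm},
#' \code{psi_0_3_MPa}, \code{psi_3_5_MPa}, \code{psi_5_10_MPa}.
#'
#' @param path CSV file path.
#' @param weather a \code{\link{weather_series}}.
#' @return \code{read_weather_csv}: a \code{weather_series};
#'   \code{write_weather_csv}: the path, invisibly.
#' @export
read_weather_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("day", "soil_temp_sowing_depth_C", "rainfall_mm", "psi_0_3_MPa",
           "psi_3_5_MPa", "psi_5_10_MPa")
  if (!all(req %in% names(d)))
    stop("weather CSV must have columns ", paste(req, collapse = ", "))
  d <- d[order(d$day), ]
  if (!identical(as.integer(d$day), seq_len(nrow(d))))
    stop("weather CSV must cover days 1..n with no gaps")
  weather_series(d$soil_temp_sowing_depth_C, d$rainfall_mm, d$psi_0_3_MPa,
                 d$psi_3_5_MPa, d$psi_5_10_MPa)
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  stopifnot(inherits(weather, "weather_series"))
  out <- data.frame(day = weather$day,
                    soil_temp_sowing_depth_C = weather$soil_temp_C,
                    rainfall_mm = weather$rainfall_mm,
                    psi_0_3_MPa = weather$psi_0_3,
                    psi_3_5_MPa = weather$psi_3_5,
                    psi_5_10_MPa = weather$psi_5_10)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic daily weather scenario
#'
#' Emulates spring seedbed weather in a temperate oceanic climate. Daily
#' soil temperature is a template mean plus AR(1) noise; rainfall is a
#' Bernoulli-gamma process; layer water potentials are driven by rainfall
#' (a wetting event resets a layer towards saturation, deeper layers more
#' slowly) and decay exponentially towards dryness between events.
#'
#' Templates:
#' \describe{
#'   \item{warm_wet}{mean 17 C, frequent rain; a non-limiting seedbed.}
#'   \item{cold_wet}{mean 11 C, frequent rain; slow but unstressed.}
#'   \item{warm_dry_spell}{mean 16 C, rain only during the first week, then
#'     a drying spell that can push potentials below typical base values.}
#'   \item{crust_prone}{mean 14 C, heavy early rain (crust threshold reached
#'     quickly) followed by mostly dry days that keep the crust dry.}
#' }
#'
#' @param template template name, see Details.
#' @param horizon_days number of days (>= 30).
#' @param rng_seed integer seed; the series is deterministic given
#'   (template, horizon, seed).
#' @return a \code{\link{weather_series}}.
#' @export
generate_weather <- function(template = c("warm_wet", "cold_wet",
                                          "warm_dry_spell", "crust_prone"),
                             horizon_days = 30, rng_seed = 1L) {
  template <- match.arg(template)
  stopifnot(horizon_days >= 30)
  set.seed(rng_seed)
  n <- horizon_days
  # two-phase Bernoulli-gamma rainfall: an early phase (first week or the
  # crust-forming burst) and a late phase covering the rest of the horizon
  p <- switch(template,
    warm_wet = list(tmean = 17, early_days = 7, p1 = 0.40, sh1 = 2.0,
                    sc1 = 3.125, p2 = 0.40, sh2 = 2.0, sc2 = 3.125),
    cold_wet = list(tmean = 11, early_days = 7, p1 = 0.40, sh1 = 2.0,
                    sc1 = 3.125, p2 = 0.40, sh2 = 2.0, sc2 = 3.125),
    warm_dry_spell = list(tmean = 16, early_days = 7, p1 = 0.5, sh1 = 2.0,
                          sc1 = 2.5, p2 = 0, sh2 = 2.0, sc2 = 2.5),
    crust_prone = list(tmean = 14, early_days = 4, p1 = 0.9, sh1 = 3.0,
                       sc1 = 4, p2 = 0.15, sh2 = 2.0, sc2 = 2.5))
  # AR(1) temperature noise, sd ~1.5 C, autocorrelation 0.7
  eps <- stats::rnorm(n, 0, 1.5 * sqrt(1 - 0.7^2))
  noise <- Reduce(function(prev, e) 0.7 * prev + e, eps, accumulate = TRUE)
  temp <- p$tmean + noise
  rain <- numeric(n)
  early <- seq_len(min(p$early_days, n))
  late <- setdiff(seq_len(n), early)
  wet1 <- stats::runif(length(early)) < p$p1
  rain[early[wet1]] <- stats::rgamma(sum(wet1), shape = p$sh1, scale = p$sc1)
  if (length(late) && p$p2 > 0) {
    wet2 <- stats::runif(length(late)) < p$p2
    rain[late[wet2]] <- stats::rgamma(sum(wet2), shape = p$sh2, scale = p$sc2)
  }
  psi <- rainfall_to_potentials(rain)
  weather_series(temp, rain, psi[, 1], psi[, 2], psi[, 3])
}

# Layer water potentials from daily rainfall: wetting events (>= 2 mm) reset
# a layer towards saturation (deeper layers respond more slowly and less
# completely); between events each layer dries exponentially (shallow layers
# fastest). Returns an n x 3 matrix (MPa, <= 0).
rainfall_to_potentials <- function(rain, psi_sat = -0.01, psi_floor = -2,
                                   dry_rate = c(0.10, 0.06, 0.03),
                                   wet_response = c(1, 0.8, 0.6),
                                   wet_event_mm = 2) {
  n <- length(rain)
  psi <- matrix(NA_real_, n, 3)
  prev <- rep(-0.05, 3)  # moist seedbed at sowing
  for (d in seq_len(n)) {
    cur <- prev
    for (l in 1:3) {
      # drying: potential decays geometrically towards the dry floor
      cur[l] <- psi_floor + (cur[l] - psi_floor) * exp(-dry_rate[l])
      if (rain[d] >= wet_event_mm)
        cur[l] <- cur[l] + wet_response[l] * (psi_sat - cur[l])
    }
    psi[d, ] <- pmin(cur, 0)
    prev <- cur
  }
  psi
}
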