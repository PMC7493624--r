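#' Seedbed configuration
#'
#' Describes how a virtual seedbed is built: how many seeds are sown, the
#' sowing-depth distribution, the aggregate (clod) population, and the
#' crusting behaviour of the soil surface.
#'
#' The depth distribution is either a truncated normal
#' (\code{depth = list(mean =, sd =, min =, max =)}, cm; a zero \code{sd}
#' gives a point mass at \code{mean}) or a discrete table
#' (\code{depth = data.frame(depth_cm =, prob =)} with probabilities summing
#' to one).
#'
#' Crust formation is a single threshold event on cumulative rainfall since
#' sowing; the per-class default thresholds (non-crusting: never;
#' moderately crusting: 25 mm; highly crusting: 15 mm) are calibration knobs
#' and can be overridden.
#'
#' @param n_seeds number of seeds sown.
#' @param depth depth distribution, see Details. Default truncated normal
#'   (mean 3 cm, sd 0.7 cm, truncated to [1, 6] cm).
#' @param aggregates data frame with columns \code{diameter_cm},
#'   \code{count_per_m2}, \code{surface} (logical); \code{NULL} or an empty
#'   frame means an aggregate-free seedbed.
#' @param crusting_class one of \code{"non_crusting"},
#'   \code{"moderately_crusting"}, \code{"highly_crusting"}.
#' @param crust_rainfall_threshold cumulative rainfall (mm) since sowing at
#'   which a crust forms; default set by \code{crusting_class}.
#' @param crust_wet_threshold same-day rainfall (mm) at or above which a
#'   crust day is labelled wet (default 2 mm).
#' @param tilled_depth_cm depth of the tilled layer holding buried
#'   aggregates (default 5 cm).
#' @return object of class \code{seedbed_config}.
#' @export
seedbed_config <- function(n_seeds,
                           depth = list(mean = 3, sd = 0.7, min = 1, max = 6),
                           aggregates = NULL,
                           crusting_class = c("non_crusting",
                                              "moderately_crusting",
                                              "highly_crusting"),
                           crust_rainfall_threshold = NULL,
                           crust_wet_threshold = 2,
                           tilled_depth_cm = 5) {
  crusting_class <- match.arg(crusting_class)
  stopifnot(is.numeric(n_seeds), n_seeds >= 1)
  if (is.data.frame(depth)) {
    stopifnot(all(c("depth_cm", "prob") %in% names(depth)),
              nrow(depth) >= 1, all(depth$prob >= 0), sum(depth$prob) > 0)
    if (abs(sum(depth$prob) - 1) > 1e-9)
      stop("discrete depth-class probabilities must sum to 1")
    if (any(depth$depth_cm < 0.5 | depth$depth_cm > 10))
      stop("sowing depths must lie within [0.5, 10] cm")
  } else {
    stopifnot(all(c("mean", "sd", "min", "max") %in% names(depth)),
              depth$sd >= 0, depth$min <= depth$max)
    if (depth$min < 0.5 || depth$max > 10)
      stop("sowing depths must lie within [0.5, 10] cm")
  }
  if (is.null(aggregates))
    aggregates <- data.frame(diameter_cm = numeric(), count_per_m2 = numeric(),
                             surface = logical())
  stopifnot(all(c("diameter_cm", "count_per_m2", "surface") %in%
                  names(aggregates)),
            all(aggregates$count_per_m2 >= 0),
            all(aggregates$diameter_cm > 0))
  if (is.null(crust_rainfall_threshold))
    crust_rainfall_threshold <- switch(crusting_class,
                                       non_crusting = Inf,
                                       moderately_crusting = 25,
                                       highly_crusting = 15)
  if (crusting_class == "non_crusting") crust_rainfall_threshold <- Inf
  structure(list(n_seeds = as.integer(n_seeds), depth = depth,
                 aggregates = aggregates, crusting_class = crusting_class,
                 crust_rainfall_threshold = crust_rainfall_threshold,
                 crust_wet_threshold = crust_wet_threshold,
                 tilled_depth_cm = tilled_depth_cm,
                 layer_bounds = c(0, 3, 5, 10)),
            class = "seedbed_config")
}

#' @export
print.seedbed_config <- function(x, ...) {
  cat(sprintf("Seedbed config: %d seeds, %s soil, %d aggregate classes\n",
              x$n_seeds, gsub("_", " ", x$crusting_class), nrow(x$aggregates)))
  invisible(x)
}

#' Read or write a seedbed configuration (YAML or JSON)
#'
#' @param path file path; format chosen by extension (\code{.yaml},
#'   \code{.yml} or \code{.json}).
#' @param cfg a \code{\link{seedbed_config}}.
#' @return \code{read_seedbed_config}: a \code{seedbed_config};
#'   \code{write_seedbed_config}: the path, invisibly.
#' @export
read_seedbed_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  depth <- if (!is.null(obj$depth$depth_cm)) as.data.frame(obj$depth) else obj$depth
  agg <- if (length(obj$aggregates)) as.data.frame(obj$aggregates) else NULL
  thr <- obj$crust_rainfall_threshold
  if (is.character(thr)) thr <- as.numeric(thr)  # "Inf" round-trips as text
  seedbed_config(n_seeds = obj$n_seeds, depth = depth, aggregates = agg,
                 crusting_class = obj$crusting_class,
                 crust_rainfall_threshold = thr,
                 crust_wet_threshold = obj$crust_wet_threshold %||% 2,
                 tilled_depth_cm = obj$tilled_depth_cm %||% 5)
}

#' @rdname read_seedbed_config
#' @export
write_seedbed_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "seedbed_config"))
  obj <- unclass(cfg)
  obj$layer_bounds <- NULL
  if (grepl("\\.ya?ml$", path)) {
    obj$crust_rainfall_threshold <- as.character(obj$crust_rainfall_threshold)
    yaml::write_yaml(obj, path)
  } else {
    obj$crust_rainfall_threshold <-
      if (is.finite(obj$crust_rainfall_threshold))
        obj$crust_rainfall_threshold else "Inf"
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a virtual seedbed
#'
#' Places \code{n_seeds} seeds at depths drawn i.i.d. from the configured
#' sowing-depth distribution and realizes the aggregate population over a
#' reference square metre: buried aggregates at uniform depths within the
#' tilled layer, surface aggregates at depth zero. The seed-aggregate
#' encounter process during shoot growth is statistical (areal densities),
#' so aggregate positions serve inspection and plotting.
#'
#' @param cfg a \code{\link{seedbed_config}}.
#' @param rng_seed integer seed; the same (cfg, seed) pair always yields the
#'   identical seedbed.
#' @return object of class \code{seedbed}: \code{seeds} (data frame
#'   \code{seed_id}, \code{depth_cm}), \code{aggregates} (data frame
#'   \code{diameter_cm}, \code{depth_cm}, \code{surface}), \code{config},
#'   and an empty \code{crust_state} to be filled by
#'   \code{\link{update_crust}}.
#' @export
build_seedbed <- function(cfg, rng_seed = 1L) {
  stopifnot(inherits(cfg, "seedbed_config"))
  set.seed(rng_seed)
  depths <- sample_depths(cfg$n_seeds, cfg$depth)
  agg_rows <- lapply(seq_len(nrow(cfg$aggregates)), function(i) {
    a <- cfg$aggregates[i, ]
    n <- stats::rpois(1, a$count_per_m2)
    if (n == 0) return(NULL)
    data.frame(diameter_cm = rep(a$diameter_cm, n),
               depth_cm = if (a$surface) rep(0, n)
                          else stats::runif(n, 0, cfg$tilled_depth_cm),
               surface = rep(a$surface, n))
  })
  aggregates <- do.call(rbind, agg_rows)
  if (is.null(aggregates))
    aggregates <- data.frame(diameter_cm = numeric(), depth_cm = numeric(),
                             surface = logical())
  structure(list(seeds = data.frame(seed_id = seq_len(cfg$n_seeds),
                                    depth_cm = depths),
                 aggregates = aggregates, config = cfg,
                 crust_state = character()),
            class = "seedbed")
}

sample_depths <- function(n, depth) {
  if (is.data.frame(depth))
    return(sample(depth$depth_cm, n, replace = TRUE, prob = depth$prob))
  if (depth$sd == 0) return(rep(depth$mean, n))
  # inverse-CDF truncated normal
  plo <- stats::pnorm(depth$min, depth$mean, depth$sd)
  phi <- stats::pnorm(depth$max, depth$mean, depth$sd)
  stats::qnorm(stats::runif(n, plo, phi), depth$mean, depth$sd)
}

#' @export
print.seedbed <- function(x, ...) {
  cat(sprintf("Seedbed: %d seeds (depth %.1f-%.1f cm), %d aggregates, %s\n",
              nrow(x$seeds), min(x$seeds$depth_cm), max(x$seeds$depth_cm),
              nrow(x$aggregates), gsub("_", " ", x$config$crusting_class)))
  if (length(x$crust_state))
    cat(sprintf("  crust: %s\n", paste0(table(x$crust_state)[unique(x$crust_state)],
                                        " ", unique(x$crust_state), collapse = ", ")))
  invisible(x)
}

#' Fill the daily crust state of a seedbed from weather
#'
#' A crust forms on the first day cumulative rainfall since sowing reaches
#' the configured threshold (crusting soils only; non-crusting soils never
#' leave \code{"absent"}). Once present the crust persists; each crust day
#' is labelled \code{"wet"} if that day's rainfall is at or above the wet
#' threshold, else \code{"dry"}.
#'
#' @param seedbed a \code{\link{build_seedbed}} result.
#' @param weather a \code{\link{weather_series}} covering the horizon.
#' @return the seedbed with \code{crust_state} filled (one of
#'   \code{"absent"}, \code{"wet"}, \code{"dry"} per day).
#' @export
update_crust <- function(seedbed, weather) {
  stopifnot(inherits(seedbed, "seedbed"), inherits(weather, "weather_series"))
  cfg <- seedbed$config
  rain <- weather$rainfall_mm
  state <- rep("absent", length(rain))
  if (is.finite(cfg$crust_rainfall_threshold)) {
    present <- cumsum(rain) >= cfg$crust_rainfall_threshold
    state[present] <- ifelse(rain[present] >= cfg$crust_wet_threshold,
                             "wet", "dry")
  }
  seedbed$crust_state <- state
  seedbed
}

#' Weekly-rainfall water-stress indicator for a seedbed
#'
#' Classifies seedbed water status from cumulative weekly rainfall: at least
#' 10 mm in the week means no water stress at and following sowing.
#'
#' @param weekly_rainfall_mm cumulative rainfall over the week (mm, >= 0).
#' @return \code{"no_stress"} or \code{"possible_stress"} (vectorized).
#' @export
seedbed_water_status <- function(weekly_rainfall_mm) {
  if (any(weekly_rainfall_mm < 0)) stop("rainfall cannot be negative")
  ifelse(weekly_rainfall_mm >= 10, "no_stress", "possible_stress")
}

#' Soil layer index for a depth
#'
#' Maps a depth in cm to the weather layers 0-3, 3-5 and 5-10 cm (1, 2, 3).
#' Depths beyond 10 cm stay in layer 3.
#'
#' @param depth_cm depth below the surface (cm, >= 0).
#' @return integer layer index in 1..3.
#' @export
depth_layer <- function(depth_cm) {
  ifelse(depth_cm < 3, 1L, ifelse(depth_cm < 5, 2L, 3L))
}
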