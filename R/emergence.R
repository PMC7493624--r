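#' Seedling elongation and mechanical-obstacle parameters
#'
#' Parameters of early heterotrophic growth and of the encounter/blocking
#' process with soil aggregates. Shoot (hypocotyl) length grows with thermal
#' time above the growth base temperature as a saturating exponential,
#' \deqn{L(\theta) = L_{max} (1 - e^{-r \theta})}
#' with \eqn{\theta} in degree-days; the radicle elongates downward linearly
#' in thermal time. Defaults are soybean-scale values.
#'
#' Aggregate blocking is a statistical encounter process: the number of
#' buried aggregates a shoot meets on its way up is Poisson with mean
#' (areal density) x (encounter cross-section) x (fraction of the tilled
#' layer traversed); every encounter blocks the seedling permanently with
#' the class blocking probability, and every circumvented aggregate adds
#' \code{pathway_detour} cm to the path. Aggregates lying on the surface
#' are tested once when the shoot reaches the surface, with encounter
#' probability equal to their areal cover.
#'
#' @param shoot_Lmax maximum hypocotyl length (cm); must exceed the sowing
#'   depth for emergence to be possible.
#' @param shoot_rate shape parameter of the elongation curve (1/degree-day).
#' @param radicle_rate downward radicle elongation (cm per degree-day).
#' @param Tb_growth base temperature for elongation (degrees C).
#' @param pathway_detour extra path length per circumvented buried aggregate
#'   (cm).
#' @param shoot_width_cm effective shoot width for the encounter
#'   cross-section (cm).
#' @param p_block optional data frame (\code{diameter_cm}, \code{surface},
#'   \code{p_block}) giving the per-encounter blocking probability by
#'   aggregate class; classes not listed fall back to
#'   \code{default_p_block}.
#' @param crust_wait days a seedling arriving under a dry crust survives
#'   while waiting for a wet-crust day (default 7).
#' @return object of class \code{elongation_params}.
#' @export
elongation_params <- function(shoot_Lmax = 9, shoot_rate = 0.02,
                              radicle_rate = 0.06, Tb_growth = 4,
                              pathway_detour = 0.5, shoot_width_cm = 0.5,
                              p_block = NULL, crust_wait = 7) {
  stopifnot(shoot_Lmax > 0, shoot_rate > 0, radicle_rate >= 0,
            pathway_detour >= 0, crust_wait >= 0)
  if (!is.null(p_block)) {
    stopifnot(all(c("diameter_cm", "surface", "p_block") %in% names(p_block)),
              all(p_block$p_block >= 0 & p_block$p_block <= 1))
  }
  structure(list(shoot_Lmax = shoot_Lmax, shoot_rate = shoot_rate,
                 radicle_rate = radicle_rate, Tb_growth = Tb_growth,
                 pathway_detour = pathway_detour,
                 shoot_width_cm = shoot_width_cm, p_block = p_block,
                 crust_wait = crust_wait),
            class = "elongation_params")
}

# Per-encounter blocking probability for an aggregate class; table lookup
# with a diameter-proportional fallback.
default_p_block <- function(diameter_cm, surface) {
  pmin(0.9, ifelse(surface, 0.12, 0.08) * diameter_cm)
}

lookup_p_block <- function(elong, diameter_cm, surface) {
  if (!is.null(elong$p_block)) {
    hit <- which(elong$p_block$diameter_cm == diameter_cm &
                   elong$p_block$surface == surface)
    if (length(hit)) return(elong$p_block$p_block[hit[1]])
  }
  default_p_block(diameter_cm, surface)
}

#' Shoot length at a given thermal time
#'
#' @param tt thermal time above the growth base temperature (degree-days).
#' @param elong an \code{\link{elongation_params}}.
#' @return shoot length (cm).
#' @export
shoot_length <- function(tt, elong) {
  elong$shoot_Lmax * (1 - exp(-elong$shoot_rate * tt))
}

#' Simulate germination and emergence seed by seed
#'
#' Daily-time-step stochastic simulation of every seed in the seedbed.
#' Each day, in order: (1) hydrothermal time for germination accrues by
#' \eqn{\max(0, T_d - T_b)} degree-days, but only on days when the water
#' potential of the seed's depth layer exceeds the base water potential;
#' (2) a seed germinates the first day its accrual reaches its thermal-time
#' requirement (drawn at sowing from the cultivar's thermal-time
#' distribution), within the germination window; (3) on the two days
#' following germination the seedling dies of water stress if the potential
#' of the layer its radicle has reached is below the base water potential;
#' (4) shoot thermal time accrues and the hypocotyl elongates; (5) when the
#' shoot length reaches the seed's path to the surface (sowing depth plus
#' detours around circumvented aggregates) the seedling emerges — unless it
#' was blocked by an aggregate, or a dry surface crust is present, in which
#' case it waits up to \code{crust_wait} days for a wet-crust day and
#' otherwise remains blocked under the crust.
#'
#' Seeds that are intrinsically non-germinable (Bernoulli with probability
#' 1 - germinable fraction, drawn at sowing) and seeds whose accrual never
#' reaches the requirement within the window are both recorded under cause
#' \code{non_germination}.
#'
#' @param seedbed a \code{\link{build_seedbed}} result; its crust state is
#'   filled from \code{weather} if not already.
#' @param weather a \code{\link{weather_series}} covering the horizon.
#' @param germ a \code{\link{cultivar_params}}.
#' @param elong an \code{\link{elongation_params}}.
#' @param horizon_days simulation horizon (default the weather length);
#'   must be >= 30.
#' @param rng_seed integer seed; the run is deterministic given it.
#' @param germination_window days after sowing within which a seed must
#'   germinate (default 30).
#' @return object of class \code{simulation_result}: \code{fates} (data
#'   frame \code{seed_id}, \code{depth_cm}, \code{germination_day},
#'   \code{emergence_day}, \code{cause}), \code{daily_emerged} (cumulative
#'   emerged count per day), \code{final_emergence_rate} (% of sown seeds),
#'   \code{cause_partition}, \code{n_seeds}, \code{rng_seed}.
#' @export
run_simulation <- function(seedbed, weather, germ, elong = elongation_params(),
                           horizon_days = nrow(weather), rng_seed = 1L,
                           germination_window = 30) {
  stopifnot(inherits(seedbed, "seedbed"), inherits(weather, "weather_series"),
            inherits(germ, "cultivar_params"),
            inherits(elong, "elongation_params"))
  if (horizon_days < 30) stop("simulation horizon must be >= 30 days")
  if (nrow(weather) < horizon_days)
    stop("weather series shorter than the simulation horizon")
  if (!length(seedbed$crust_state)) seedbed <- update_crust(seedbed, weather)
  crust <- seedbed$crust_state

  n <- nrow(seedbed$seeds)
  depth <- seedbed$seeds$depth_cm
  psi_mat <- cbind(weather$psi_0_3, weather$psi_3_5, weather$psi_5_10)
  temp <- weather$soil_temp_C

  set.seed(rng_seed)
  non_germinable <- stats::runif(n) > germ$germinable_fraction
  tt_req <- draw_thermal_time(n, germ$thermal_time_distribution)

  # aggregate encounters, resolved at sowing (blocking is permanent)
  agg <- seedbed$config$aggregates
  buried_cl <- agg[!agg$surface & agg$count_per_m2 > 0, ]
  n_detour <- integer(n)
  blocked_buried <- rep(FALSE, n)
  tilled <- seedbed$config$tilled_depth_cm
  if (nrow(buried_cl)) {
    for (i in seq_len(nrow(buried_cl))) {
      d_cm <- buried_cl$diameter_cm[i]
      xsec <- pi * ((d_cm + elong$shoot_width_cm) / 200)^2  # m^2
      lam <- buried_cl$count_per_m2[i] * xsec * pmin(depth / tilled, 1)
      n_enc <- stats::rpois(n, lam)
      pb <- lookup_p_block(elong, d_cm, surface = FALSE)
      n_block <- stats::rbinom(n, n_enc, pb)
      blocked_buried <- blocked_buried | n_block > 0
      n_detour <- n_detour + n_enc
    }
  }
  surface_cl <- agg[agg$surface & agg$count_per_m2 > 0, ]
  blocked_surface <- rep(FALSE, n)
  if (nrow(surface_cl)) {
    for (i in seq_len(nrow(surface_cl))) {
      d_cm <- surface_cl$diameter_cm[i]
      cover <- min(1, surface_cl$count_per_m2[i] * pi * (d_cm / 200)^2)
      enc <- stats::runif(n) < cover
      pb <- lookup_p_block(elong, d_cm, surface = TRUE)
      blocked_surface <- blocked_surface |
        (enc & stats::runif(n) < pb)
    }
  }
  blocked <- blocked_buried | blocked_surface
  path <- depth + elong$pathway_detour * n_detour

  seed_layer <- depth_layer(depth)
  acc <- numeric(n)             # hydrothermal accrual for germination (Cd)
  tt_growth <- numeric(n)       # thermal time since germination (Cd)
  germ_day <- rep(NA_integer_, n)
  emerge_day <- rep(NA_integer_, n)
  dead_ws <- rep(FALSE, n)
  blocked_crust <- rep(FALSE, n)
  arrived <- rep(FALSE, n)
  window <- min(germination_window, horizon_days)

  for (d in seq_len(horizon_days)) {
    germinated <- !is.na(germ_day)
    # water stress is checked before obstacle resolution, so a seedling
    # headed for an aggregate can still die of drought first
    active <- germinated & !dead_ws & !arrived & is.na(emerge_day) &
      !blocked_crust

    # (1) germination accrual, gated by the seed layer's water potential
    pending <- !germinated & !non_germinable
    gate <- psi_mat[d, seed_layer] > germ$psi_b_mean
    acc[pending & gate] <- acc[pending & gate] + max(0, temp[d] - germ$Tb)

    # (2) germination check, within the window
    if (d <= window) {
      newly <- pending & acc >= tt_req
      germ_day[newly] <- d
    }

    # (3) post-germination water stress on days g+1 and g+2; the radicle's
    # layer is taken at its position before today's growth
    chk <- active & (d - germ_day == 1L | d - germ_day == 2L)
    if (any(chk)) {
      rad_layer <- depth_layer(depth[chk] + elong$radicle_rate * tt_growth[chk])
      dies <- psi_mat[d, rad_layer] < germ$psi_b_mean
      dead_ws[which(chk)[dies]] <- TRUE
    }

    # (4) shoot thermal time accrues from the day after germination
    grow <- germinated & !dead_ws & !arrived & is.na(emerge_day) &
      !blocked_crust & d > germ_day
    tt_growth[grow] <- tt_growth[grow] + max(0, temp[d] - elong$Tb_growth)

    # (5) surface arrival and obstacle/crust resolution
    arriving <- grow & !blocked & shoot_length(tt_growth, elong) >= path
    if (any(arriving)) {
      idx <- which(arriving)
      arrived[idx] <- TRUE
      if (crust[d] %in% c("absent", "wet")) {
        emerge_day[idx] <- d
      } else {
        last <- min(d + elong$crust_wait, horizon_days)
        first_wet <- if (last > d) which(crust[(d + 1):last] == "wet")[1]
                     else NA_integer_
        if (!is.na(first_wet)) {
          emerge_day[idx] <- d + first_wet
        } else {
          blocked_crust[idx] <- TRUE
        }
      }
    }
  }

  cause <- rep("not_emerged", n)
  cause[non_germinable | is.na(germ_day)] <- "non_germination"
  cause[dead_ws] <- "post_germination_water_stress"
  cause[!is.na(germ_day) & !dead_ws & blocked] <- "blocked_aggregate"
  cause[blocked_crust] <- "blocked_crust"
  cause[!is.na(emerge_day)] <- "emerged"

  fates <- data.frame(seed_id = seedbed$seeds$seed_id, depth_cm = depth,
                      germination_day = germ_day, emergence_day = emerge_day,
                      cause = factor(cause, levels = fate_causes()))
  daily <- vapply(seq_len(horizon_days),
                  function(d) sum(!is.na(emerge_day) & emerge_day <= d),
                  numeric(1))
  structure(list(fates = fates, daily_emerged = daily,
                 final_emergence_rate = daily[horizon_days] / n * 100,
                 cause_partition = cause_partition(fates),
                 n_seeds = n, rng_seed = rng_seed),
            class = "simulation_result")
}

#' Fate categories recognized by the simulator
#'
#' The four non-emergence causes plus \code{emerged}; \code{not_emerged}
#' covers the rare seedling still underground, alive and unblocked when the
#' horizon ends (possible only under cold or very deep-sown scenarios).
#'
#' @return character vector of fate levels.
#' @export
fate_causes <- function() {
  c("emerged", "non_germination", "post_germination_water_stress",
    "blocked_aggregate", "blocked_crust", "not_emerged")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Emergence simulation: %d seeds, final emergence %.1f%%\n",
              x$n_seeds, x$final_emergence_rate))
  cp <- x$cause_partition
  for (nm in names(cp)) if (cp[[nm]] > 0)
    cat(sprintf("  %-30s %6.1f%%\n", nm, cp[[nm]]))
  invisible(x)
}

#' Partition seeds among emergence and non-emergence causes
#'
#' @param fates the \code{fates} data frame of a
#'   \code{\link{run_simulation}} result (or the result itself).
#' @return named numeric vector of percentages of sown seeds per cause,
#'   summing to 100.
#' @export
cause_partition <- function(fates) {
  if (inherits(fates, "simulation_result")) fates <- fates$fates
  if (!nrow(fates)) stop("empty fate list")
  tab <- table(factor(fates$cause, levels = fate_causes()))
  stats::setNames(100 * as.numeric(tab) / nrow(fates), names(tab))
}

#' Replicate emergence simulations and summarize
#'
#' Runs \code{n_replicates} independent simulations; each replicate rebuilds
#' the seedbed (new seed placement and aggregate realization) and runs the
#' engine with its own RNG substream derived from the master seed.
#'
#' @param cfg a \code{\link{seedbed_config}}.
#' @param weather a \code{\link{weather_series}}.
#' @param germ a \code{\link{cultivar_params}}.
#' @param elong an \code{\link{elongation_params}}.
#' @param n_replicates number of replicate runs (default 10).
#' @param master_seed master RNG seed from which replicate substreams are
#'   derived.
#' @param ... passed to \code{\link{run_simulation}}.
#' @return object of class \code{replicate_summary}: \code{runs} (list of
#'   \code{simulation_result}), \code{summary} (data frame with mean and sd
#'   of the final emergence rate and of each cause percentage),
#'   \code{replicate_seeds}.
#' @export
replicate_simulations <- function(cfg, weather, germ,
                                  elong = elongation_params(),
                                  n_replicates = 10, master_seed = 1L, ...) {
  stopifnot(n_replicates >= 1)
  set.seed(master_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n_replicates)
  runs <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    sb <- build_seedbed(cfg, rng_seed = sub_seeds[2 * i - 1])
    sb <- update_crust(sb, weather)
    runs[[i]] <- run_simulation(sb, weather, germ, elong,
                                rng_seed = sub_seeds[2 * i], ...)
  }
  final <- vapply(runs, `[[`, numeric(1), "final_emergence_rate")
  causes <- t(vapply(runs, `[[`, numeric(length(fate_causes())),
                     "cause_partition"))
  summ <- data.frame(
    quantity = c("final_emergence_rate", fate_causes()),
    mean = c(mean(final), colMeans(causes)),
    sd = c(stats::sd(final), apply(causes, 2, stats::sd)))
  if (n_replicates == 1) summ$sd <- 0
  structure(list(runs = runs, summary = summ, replicate_seeds = sub_seeds,
                 master_seed = master_seed),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate emergence simulations (n = %d)\n", length(x$runs)))
  s <- x$summary
  for (i in seq_len(nrow(s))) if (s$mean[i] > 0 || i == 1)
    cat(sprintf("  %-30s %6.2f +/- %.2f\n", s$quantity[i], s$mean[i], s$sd[i]))
  invisible(x)
}
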