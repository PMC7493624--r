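#' Model-evaluation statistics for emergence courses
#'
#' Three standard criteria comparing predicted (\eqn{P_j}) with observed
#' (\eqn{O_j}) values over \eqn{n} paired points:
#' \deqn{EF = 1 - \frac{\sum_j (P_j - O_j)^2}{\sum_j (O_j - \bar O)^2}}
#' \deqn{RMSEP = \sqrt{\frac{1}{n} \sum_j (P_j - O_j)^2}}
#' \deqn{MD = \frac{1}{n} \sum_j (P_j - O_j)}
#' Model efficiency EF ranges over \eqn{(-\infty, 1]}: 1 for a perfect
#' prediction, 0 for a model no better than the observed mean. RMSEP shares
#' the units of the compared variable. MD is signed: a negative value means
#' predictions fall mostly below the observations.
#'
#' @param observed,predicted paired numeric vectors of equal length.
#' @return \code{model_efficiency}, \code{rmsep}, \code{mean_deviation}: a
#'   single number; \code{evaluation_stats}: a list with \code{EF},
#'   \code{RMSEP}, \code{MD} and \code{n}.
#' @export
model_efficiency <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 2)
  ss_obs <- sum((observed - mean(observed))^2)
  if (ss_obs == 0)
    stop("model efficiency is undefined when all observed values are identical")
  1 - sum((predicted - observed)^2) / ss_obs
}

#' @rdname model_efficiency
#' @export
rmsep <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 1)
  sqrt(sum((predicted - observed)^2) / length(observed))
}

#' @rdname model_efficiency
#' @export
mean_deviation <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 1)
  mean(predicted - observed)
}

#' @rdname model_efficiency
#' @export
evaluation_stats <- function(observed, predicted) {
  structure(list(EF = model_efficiency(observed, predicted),
                 RMSEP = rmsep(observed, predicted),
                 MD = mean_deviation(observed, predicted),
                 n = length(observed)),
            class = "evaluation_stats")
}

#' @export
print.evaluation_stats <- function(x, ...) {
  cat(sprintf("EF = %.3f, RMSEP = %.3f, MD = %+.3f (n = %d)\n",
              x$EF, x$RMSEP, x$MD, x$n))
  invisible(x)
}

check_paired <- function(observed, predicted, min_n) {
  if (length(observed) != length(predicted))
    stop("observed and predicted series must have the same length")
  if (length(observed) < min_n)
    stop("need at least ", min_n, " paired points")
  invisible(TRUE)
}

#' Classify final emergence rates into quality classes
#'
#' Classes: poor (< 50%), good (50-75%), very good (> 75%). The boundaries
#' 50 and 75 belong to \code{good}.
#'
#' @param final_rates final emergence rates in percent, each in [0, 100].
#' @return named numeric vector of class frequencies (%) summing to 100.
#' @export
classify_emergence <- function(final_rates) {
  if (!length(final_rates)) stop("empty rate list")
  if (any(final_rates < 0 | final_rates > 100))
    stop("rates must lie in [0, 100]")
  cls <- cut(final_rates, breaks = c(-Inf, 50, 75, Inf), right = FALSE,
             labels = c("poor", "good", "very_good"))
  # cut() puts 50 in "good" (right = FALSE) and 75 in "very_good"; move the
  # 75 boundary into "good"
  cls[final_rates == 75] <- "good"
  tab <- table(cls)
  stats::setNames(100 * as.numeric(tab) / length(final_rates), names(tab))
}

#' Pair observed field counts with a simulated emergence course
#'
#' Field counts fall on irregular dates; at a daily simulation resolution
#' the simulated value is read directly at each observation day (no
#' interpolation). Pairs are returned in date order regardless of the input
#' ordering.
#'
#' @param observed data frame with columns \code{day} and \code{emerged_pct}.
#' @param simulated_daily daily simulated values (cumulative emerged %, one
#'   per day starting at day 1), or a \code{simulation_result} (its daily
#'   curve is converted to % of sown seeds).
#' @return data frame with columns \code{day}, \code{observed},
#'   \code{predicted}.
#' @export
align_courses <- function(observed, simulated_daily) {
  if (inherits(simulated_daily, "simulation_result"))
    simulated_daily <- simulated_daily$daily_emerged /
      simulated_daily$n_seeds * 100
  stopifnot(all(c("day", "emerged_pct") %in% names(observed)))
  if (!nrow(observed))
    return(data.frame(day = numeric(), observed = numeric(),
                      predicted = numeric()))
  obs <- observed[order(observed$day), ]
  if (any(obs$day < 1 | obs$day > length(simulated_daily)))
    stop("observation day beyond the simulated horizon")
  data.frame(day = obs$day, observed = obs$emerged_pct,
             predicted = simulated_daily[obs$day])
}

#' Evaluate a simulated emergence course against field observations
#'
#' Convenience wrapper: aligns the courses and computes EF, RMSEP and MD.
#'
#' @param observed data frame with columns \code{day}, \code{emerged_pct}.
#' @param simulated a \code{simulation_result} or daily vector; see
#'   \code{\link{align_courses}}.
#' @return an \code{\link{evaluation_stats}} object.
#' @export
evaluate_emergence <- function(observed, simulated) {
  pairs <- align_courses(observed, simulated)
  evaluation_stats(pairs$observed, pairs$predicted)
}

#' Cumulative degree-days since sowing
#'
#' Sum of (daily mean temperature - base temperature) x 1 day, with days
#' below the base temperature contributing zero.
#'
#' @param daily_temp_C daily mean temperatures (degrees C).
#' @param Tb base temperature (degrees C).
#' @return cumulative degree-days, one value per day.
#' @export
degree_days <- function(daily_temp_C, Tb) {
  cumsum(pmax(0, daily_temp_C - Tb))
}
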