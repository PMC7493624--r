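#' Gompertz cumulative germination curve
#'
#' \code{gompertz(t, A, k, tm)} evaluates
#' \deqn{g(t) = A \exp(-\exp(-k (t - t_m)))}
#' the three-parameter Gompertz curve used throughout for cumulative
#' germination fractions: \code{A} is the final germination fraction
#' (asymptote), \code{k} the rate parameter (1/time), and \code{tm} the
#' inflection time. \code{gompertz_inverse} solves \eqn{g(t) = p} in closed
#' form; it returns \code{NA} where \eqn{p \ge A}.
#'
#' @param t time (same units as \code{tm}, typically hours or degree-days).
#' @param A asymptote in [0, 1].
#' @param k rate parameter, positive.
#' @param tm inflection time.
#' @param p target cumulative fraction in (0, 1).
#' @return \code{gompertz}: fraction(s); \code{gompertz_inverse}: time(s).
#' @export
gompertz <- function(t, A, k, tm) A * exp(-exp(-k * (t - tm)))

#' @rdname gompertz
#' @export
gompertz_inverse <- function(p, A, k, tm) {
  out <- rep(NA_real_, length(p))
  ok <- p > 0 & p < A
  out[ok] <- tm - log(-log(p[ok] / A)) / k
  out
}

#' Fit a Gompertz curve to a germination time-course
#'
#' Pools replicates by summing counts (\code{\link{pool_replicates}}) and fits
#' the cumulative germination fraction by nonlinear least squares
#' (Levenberg-Marquardt), with data-driven starting values and up to
#' \code{n_restarts} random restarts if the first attempt fails or stalls.
#'
#' @param tc a \code{\link{germination_time_course}}, or a data frame with
#'   columns \code{time_h} and \code{fraction} (already pooled).
#' @param n_restarts maximum number of random restarts after the data-driven
#'   start (default 10).
#' @param restart_seed RNG seed for the restart draws, so fits are
#'   reproducible (default 1L).
#' @return object of class \code{gompertz_fit}: list with \code{A}, \code{k},
#'   \code{tm}, \code{rss}, \code{n_obs}, \code{converged}.
#' @export
fit_gompertz <- function(tc, n_restarts = 10, restart_seed = 1L) {
  if (inherits(tc, "germination_time_course")) {
    d <- pool_replicates(tc)
  } else {
    d <- as.data.frame(tc)
    if (!all(c("time_h", "fraction") %in% names(d)))
      stop("need a germination_time_course or a data frame with time_h and fraction")
  }
  if (length(unique(d$time_h)) < 4)
    stop("need at least 4 distinct observation times to fit a Gompertz curve")
  if (all(d$fraction == 0))
    stop("degenerate data: all counts are zero, no germination to fit")

  starts <- gompertz_starts(d)
  best <- NULL
  trials <- vector("list", n_restarts + 1L)
  trials[[1L]] <- starts
  # restart draws come from a private stream so fitting never disturbs the
  # caller's RNG state
  u <- with_preserved_rng(restart_seed, stats::runif(3 * n_restarts))
  tspan <- max(d$time_h) - min(d$time_h)
  for (i in seq_len(n_restarts)) {
    v <- u[(3 * i - 2):(3 * i)]
    trials[[i + 1L]] <- list(
      A = max(d$fraction) * 0.8 + v[1] * (1 - max(d$fraction) * 0.8),
      k = (0.2 + 4.8 * v[2]) * starts$k,
      tm = min(d$time_h) + v[3] * tspan)
  }
  for (st in trials) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fraction ~ A * exp(-exp(-k * (time_h - tm))), data = d,
        start = st, lower = c(A = 0, k = 1e-8, tm = -Inf),
        upper = c(A = 1, k = Inf, tm = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(A = unname(cf["A"]), k = unname(cf["k"]),
                   tm = unname(cf["tm"]), rss = rss)
    }
    if (!is.null(best) && best$rss < 1e-12) break
  }
  if (is.null(best))
    stop("Gompertz fit failed to converge after ", n_restarts, " restarts")
  structure(c(best, list(n_obs = nrow(d), converged = TRUE)),
            class = "gompertz_fit")
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  expr
}

# Data-driven starting values: asymptote from the plateau, inflection near the
# time the curve crosses A/e (~37% of final), rate from the rise span.
gompertz_starts <- function(d) {
  A0 <- min(1, max(d$fraction) * 1.02 + 1e-3)
  target <- A0 * exp(-1)
  above <- which(d$fraction >= target)
  tm0 <- if (length(above)) d$time_h[above[1]] else stats::median(d$time_h)
  rise <- d$time_h[d$fraction > 0.05 * A0 & d$fraction < 0.95 * A0]
  span <- if (length(rise) >= 2) diff(range(rise)) else diff(range(d$time_h)) / 4
  list(A = A0, k = max(3 / max(span, 1e-6), 1e-4), tm = tm0)
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("Gompertz fit: A = %.4f, k = %.5f, tm = %.3f (RSS %.3g, n = %d)\n",
              x$A, x$k, x$tm, x$rss, x$n_obs))
  invisible(x)
}

#' Germination rates at fixed percentiles from a fitted Gompertz curve
#'
#' For each requested percentile p, the time \eqn{T_p} at which cumulative
#' germination reaches p percent is obtained from the closed-form inverse of
#' the fitted curve, and the germination rate is \eqn{1/T_p}. A percentile
#' that the fitted asymptote never reaches (p/100 >= A) yields \code{NA}
#' rather than an error, so partial percentile sets propagate cleanly.
#'
#' @param fit a \code{\link{fit_gompertz}} result.
#' @param percentiles integer percentiles (default the standard set
#'   20, 40, 50, 60, 80, 90).
#' @return data frame of class \code{percentile_rates} with columns
#'   \code{percentile}, \code{time} (same units as the fit), \code{rate}
#'   (1/time).
#' @export
percentile_rates <- function(fit, percentiles = c(20, 40, 50, 60, 80, 90)) {
  stopifnot(inherits(fit, "gompertz_fit"))
  tp <- gompertz_inverse(percentiles / 100, fit$A, fit$k, fit$tm)
  tp[!is.na(tp) & tp <= 0] <- NA_real_  # a non-positive crossing time has no rate
  out <- data.frame(percentile = percentiles, time = tp, rate = 1 / tp)
  class(out) <- c("percentile_rates", "data.frame")
  out
}
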