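#' Germination time-course at one incubation level
#'
#' Container for replicated cumulative germination counts observed over time
#' at a single incubation condition (a temperature in degrees Celsius, or a
#' water potential in MPa).
#'
#' @param level_type either \code{"temperature"} or \code{"water_potential"}.
#' @param level_value the incubation level: degrees C for temperatures, MPa
#'   (non-positive) for water potentials.
#' @param observations data frame with columns \code{replicate},
#'   \code{time_h} (hours since imbibition) and \code{cum_germinated}
#'   (cumulative germinated count). Within each replicate, times must be
#'   strictly increasing and counts non-decreasing.
#' @param seeds_per_replicate number of seeds per replicate dish.
#'
#' @return an object of class \code{germination_time_course}.
#' @export
germination_time_course <- function(level_type, level_value, observations,
                                    seeds_per_replicate) {
  level_type <- match.arg(level_type, c("temperature", "water_potential"))
  stopifnot(is.numeric(level_value), length(level_value) == 1L)
  if (level_type == "water_potential" && level_value > 0)
    stop("water potentials must be <= 0 MPa")
  req <- c("replicate", "time_h", "cum_germinated")
  if (!all(req %in% names(observations)))
    stop("observations must have columns ", paste(req, collapse = ", "))
  observations <- observations[order(observations$replicate, observations$time_h), req]
  if (!is.numeric(seeds_per_replicate) || seeds_per_replicate < 1)
    stop("seeds_per_replicate must be a positive integer")
  for (r in split(observations, observations$replicate)) {
    if (any(diff(r$time_h) <= 0))
      stop("observation times must be strictly increasing within a replicate")
    if (any(diff(r$cum_germinated) < 0))
      stop("cumulative counts must be non-decreasing within a replicate")
    if (any(r$cum_germinated > seeds_per_replicate))
      stop("cumulative counts cannot exceed seeds_per_replicate")
    if (any(r$cum_germinated < 0)) stop("counts must be non-negative")
  }
  structure(
    list(level_type = level_type,
         level_value = level_value,
         observations = observations,
         seeds_per_replicate = as.integer(seeds_per_replicate),
         n_replicates = length(unique(observations$replicate))),
    class = "germination_time_course")
}

#' @export
print.germination_time_course <- function(x, ...) {
  unit <- if (x$level_type == "temperature") "degC" else "MPa"
  cat(sprintf("Germination time-course at %s %g %s\n", x$level_type,
              x$level_value, unit))
  cat(sprintf("  %d replicates x %d seeds, %d observation times\n",
              x$n_replicates, x$seeds_per_replicate,
              length(unique(x$observations$time_h))))
  invisible(x)
}

#' Pool replicate counts into a single cumulative germination fraction
#'
#' Replicates are pooled by summing counts (not by averaging per-replicate
#' fits), which is the appropriate treatment for small dishes of 25 seeds.
#' Counts are step functions of time, so each replicate is evaluated at the
#' union of observation times by carrying the last observation forward.
#'
#' @param tc a \code{\link{germination_time_course}}.
#' @return data frame with columns \code{time_h}, \code{germinated},
#'   \code{n_seeds}, \code{fraction}.
#' @export
pool_replicates <- function(tc) {
  stopifnot(inherits(tc, "germination_time_course"))
  times <- sort(unique(tc$observations$time_h))
  total <- numeric(length(times))
  for (r in split(tc$observations, tc$observations$replicate)) {
    f <- stats::stepfun(r$time_h, c(0, r$cum_germinated), right = FALSE)
    total <- total + f(times)
  }
  n <- tc$seeds_per_replicate * tc$n_replicates
  data.frame(time_h = times, germinated = total, n_seeds = n,
             fraction = total / n)
}

#' Read laboratory germination time-courses from a long-format CSV
#'
#' Expected columns: \code{cultivar}, \code{level_type} (\code{temperature}
#' or \code{water_potential}), \code{level_value}, \code{replicate},
#' \code{time_h}, \code{cum_germinated}, \code{seeds_total}.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return a nested list: cultivar -> level_type -> list of
#'   \code{germination_time_course} objects named by level value.
#' @export
read_germination_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cultivar", "level_type", "level_value", "replicate", "time_h",
           "cum_germinated", "seeds_total")
  if (!all(req %in% names(d)))
    stop("germination CSV must have columns ", paste(req, collapse = ", "))
  out <- list()
  for (cv in unique(d$cultivar)) {
    dc <- d[d$cultivar == cv, ]
    out[[cv]] <- list()
    for (lt in unique(dc$level_type)) {
      dl <- dc[dc$level_type == lt, ]
      courses <- lapply(split(dl, dl$level_value), function(g) {
        germination_time_course(
          level_type = lt, level_value = g$level_value[1],
          observations = g[, c("replicate", "time_h", "cum_germinated")],
          seeds_per_replicate = g$seeds_total[1])
      })
      out[[cv]][[lt]] <- courses
    }
  }
  out
}

#' Write germination time-courses to the long-format CSV dialect
#'
#' @param courses list of \code{germination_time_course} objects.
#' @param path output CSV path.
#' @param cultivar cultivar label stored in the file.
#' @return the path, invisibly.
#' @export
write_germination_csv <- function(courses, path, cultivar = "synthetic") {
  rows <- lapply(courses, function(tc) {
    o <- tc$observations
    data.frame(cultivar = cultivar, level_type = tc$level_type,
               level_value = tc$level_value, replicate = o$replicate,
               time_h = o$time_h, cum_germinated = o$cum_germinated,
               seeds_total = tc$seeds_per_replicate)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
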