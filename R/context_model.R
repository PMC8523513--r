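# Numerical guards used throughout the context model.
.EPS_DENSITY <- 1e-12   # floor returned for level sets / combos absent from a model
.RATIO_MAX   <- 100     # cap on the likelihood ratio P(C|A=1)/P(C)
.COV_RIDGE   <- 1e-6    # ridge added to every MLE covariance
.MIN_COMBO_N <- 3       # combos with fewer records fall back to the pooled Gaussian

.WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

.combo_key <- function(weather, wind, humidity) {
  paste(weather, wind, humidity, sep = "|")
}

.check_context_frame <- function(records) {
  needed <- c("hour", "weekday", "temperature", "weather", "wind", "humidity")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop("context records lack columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("context records are empty")
  if (any(records$hour < 0 | records$hour >= 24)) {
    stop("hour must lie in [0, 24)")
  }
  bad <- setdiff(unique(as.character(records$weekday)), .WEEKDAYS)
  if (length(bad) > 0L) {
    stop("unknown weekday levels: ", paste(bad, collapse = ", "))
  }
  invisible(records)
}

#' Fit the factorized context distribution
#'
#' Fits the density used on either side of the context-desirability ratio
#' P(C|A=1)/P(C): a categorical distribution over weekday (weekday is treated
#' as independent of the remaining features), a categorical distribution over
#' the discrete (weather, wind, humidity) combination, and, for each observed
#' combination, a bivariate Gaussian over (hour, temperature) fitted by
#' maximum likelihood.
#'
#' Combinations with fewer than 3 records borrow the pooled Gaussian fitted
#' on all records, and every covariance gets a small ridge (1e-6 on the
#' diagonal) so it stays positive definite on degenerate strata.
#'
#' @param records data frame with columns `hour` (real, in \[0,24)),
#'   `weekday` (`Mon`..`Sun`), `temperature` (degrees C), and categorical
#'   `weather`, `wind`, `humidity`.
#' @param levels optional named list declaring the level sets for `weather`,
#'   `wind` and `humidity`; defaults to the levels observed in `records`.
#' @return an object of class `context_model`.
#' @export
fit_context_distribution <- function(records, levels = NULL) {
  records <- as.data.frame(records)
  .check_context_frame(records)

  if (is.null(levels)) {
    levels <- list(
      weather  = sort(unique(as.character(records$weather))),
      wind     = sort(unique(as.character(records$wind))),
      humidity = sort(unique(as.character(records$humidity)))
    )
  }
  for (f in c("weather", "wind", "humidity")) {
    bad <- setdiff(unique(as.character(records[[f]])), levels[[f]])
    if (length(bad) > 0L) {
      stop("records contain ", f, " levels outside the declared set: ",
           paste(bad, collapse = ", "))
    }
  }

  wd <- factor(as.character(records$weekday), levels = .WEEKDAYS)
  weekday_probs <- as.numeric(table(wd)) / nrow(records)
  names(weekday_probs) <- .WEEKDAYS

  key <- .combo_key(records$weather, records$wind, records$humidity)
  counts <- table(key)
  combo_probs <- as.numeric(counts) / nrow(records)
  names(combo_probs) <- names(counts)

  xy <- cbind(records$hour, records$temperature)
  pooled_mean <- colMeans(xy)
  pooled_cov <- .mle_cov(xy) + .COV_RIDGE * diag(2)

  gaussians <- lapply(names(counts), function(k) {
    rows <- xy[key == k, , drop = FALSE]
    if (nrow(rows) < .MIN_COMBO_N) {
      list(mean = pooled_mean, cov = pooled_cov, n = nrow(rows), pooled = TRUE)
    } else {
      list(mean = colMeans(rows),
           cov = .mle_cov(rows) + .COV_RIDGE * diag(2),
           n = nrow(rows), pooled = FALSE)
    }
  })
  names(gaussians) <- names(counts)

  structure(
    list(
      weekday_probs = weekday_probs,
      combo_probs = combo_probs,
      gaussians = gaussians,
      pooled = list(mean = pooled_mean, cov = pooled_cov),
      levels = levels,
      n = nrow(records)
    ),
    class = "context_model"
  )
}

# MLE covariance (divisor n, not n-1), as a plain 2x2 matrix.
.mle_cov <- function(xy) {
  n <- nrow(xy)
  centered <- sweep(xy, 2, colMeans(xy))
  crossprod(centered) / n
}

#' @export
print.context_model <- function(x, ...) {
  cat("Factorized context distribution\n")
  cat("  records fitted:", x$n, "\n")
  cat("  weekday probs :", paste(sprintf("%s=%.3f", names(x$weekday_probs),
                                         x$weekday_probs), collapse = " "), "\n")
  cat("  discrete combos:", length(x$combo_probs),
      sprintf("(pooled fallback for %d)",
              sum(vapply(x$gaussians, function(g) isTRUE(g$pooled), logical(1)))),
      "\n")
  invisible(x)
}

.dmvnorm2 <- function(x, y, mean, cov) {
  # density of a bivariate normal, evaluated at (x, y); vectorized
  det <- cov[1, 1] * cov[2, 2] - cov[1, 2] * cov[2, 1]
  inv11 <- cov[2, 2] / det
  inv22 <- cov[1, 1] / det
  inv12 <- -cov[1, 2] / det
  dx <- x - mean[1]
  dy <- y - mean[2]
  q <- inv11 * dx * dx + 2 * inv12 * dx * dy + inv22 * dy * dy
  exp(-0.5 * q) / (2 * pi * sqrt(det))
}

#' Evaluate the fitted context density
#'
#' Returns the factorized mixed mass-density value
#' `P(weekday) * P(combo) * f(hour, temperature | combo)`. The value is only
#' meaningful inside ratios of two such models. Weekday levels, combos, or
#' level values absent from the model return the floor `1e-12` rather than
#' zero, so ratios stay finite.
#'
#' @param model a fitted [fit_context_distribution()] model.
#' @param context data frame (one or more rows) with the same columns as the
#'   fitting records.
#' @return numeric vector of nonnegative densities, one per row.
#' @export
context_density <- function(model, context) {
  stopifnot(inherits(model, "context_model"))
  context <- as.data.frame(context)
  .check_context_frame(context)

  wd_p <- model$weekday_probs[as.character(context$weekday)]
  wd_p[is.na(wd_p)] <- 0

  key <- .combo_key(context$weather, context$wind, context$humidity)
  combo_p <- model$combo_probs[key]
  combo_p[is.na(combo_p)] <- 0

  dens <- numeric(nrow(context))
  for (k in unique(key)) {
    rows <- which(key == k)
    g <- model$gaussians[[k]]
    if (is.null(g)) {
      dens[rows] <- 0
    } else {
      dens[rows] <- .dmvnorm2(context$hour[rows], context$temperature[rows],
                              g$mean, g$cov)
    }
  }

  unname(pmax(wd_p * combo_p * dens, .EPS_DENSITY))
}

#' Context-desirability likelihood ratio
#'
#' Computes P(C|A=1)/P(C) for each context row: how much the momentary
#' context favors the target activity relative to baseline. The ratio is
#' capped at 100; where both densities sit at the floor value (context
#' unknown to both models) the ratio is 1 (uninformative).
#'
#' @param cond model fitted on activity-conditional contexts (the activity log).
#' @param prior model fitted on the marginal context stream (hourly weather).
#' @param context data frame of context rows.
#' @param ratio_max cap applied to the ratio.
#' @return numeric vector of ratios in `[0, ratio_max]`.
#' @export
likelihood_ratio <- function(cond, prior, context, ratio_max = .RATIO_MAX) {
  num <- context_density(cond, context)
  den <- context_density(prior, context)
  r <- num / den
  r[num <= .EPS_DENSITY & den <= .EPS_DENSITY] <- 1
  pmin(pmax(r, 0), ratio_max)
}

#' Serialize a fitted context model to JSON
#' @param model a `context_model`.
#' @param path file path to write.
#' @export
write_context_model <- function(model, path) {
  stopifnot(inherits(model, "context_model"))
  obj <- list(
    levels = model$levels,
    weekday_probs = as.list(model$weekday_probs),
    combos = lapply(names(model$combo_probs), function(k) {
      g <- model$gaussians[[k]]
      list(key = k, prob = model$combo_probs[[k]],
           mean = unname(g$mean), cov = as.vector(g$cov),
           n = g$n, pooled = isTRUE(g$pooled))
    }),
    pooled = list(mean = unname(model$pooled$mean),
                  cov = as.vector(model$pooled$cov)),
    n = model$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a context model from JSON written by [write_context_model()]
#' @param path file path.
#' @return a `context_model`.
#' @export
read_context_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  combo_probs <- vapply(obj$combos, function(cb) cb$prob, numeric(1))
  names(combo_probs) <- vapply(obj$combos, function(cb) cb$key, character(1))
  gaussians <- lapply(obj$combos, function(cb) {
    list(mean = as.numeric(cb$mean),
         cov = matrix(as.numeric(cb$cov), 2, 2),
         n = cb$n, pooled = isTRUE(cb$pooled))
  })
  names(gaussians) <- names(combo_probs)
  wd <- unlist(obj$weekday_probs)[.WEEKDAYS]
  structure(
    list(weekday_probs = wd,
         combo_probs = combo_probs,
         gaussians = gaussians,
         pooled = list(mean = as.numeric(obj$pooled$mean),
                       cov = matrix(as.numeric(obj$pooled$cov), 2, 2)),
         levels = lapply(obj$levels, as.character),
         n = obj$n),
    class = "context_model"
  )
}

#' Read an activity-log CSV
#'
#' Expected header: `timestamp,hour,weekday,temperature,weather,wind,humidity`,
#' one row per performed activity.
#' @param path CSV file path.
#' @return data frame of context rows.
#' @export
read_activity_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_context_frame(df)
  df
}

#' Read an hourly weather-stream CSV
#'
#' Same columns as the activity log, one row per consecutive hour.
#' @param path CSV file path.
#' @return data frame of hourly context rows.
#' @export
read_weather_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_context_frame(df)
  df
}
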