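# Synthetic-data generators emulating the structure of the two empirical
# datasets behind the context models: an activity log (one row per performed
# run, context attached) and an hourly weather stream. Both are drawn from a
# known parametric world so that fitting can be checked by parameter
# recovery: weekday categorical x discrete (weather, wind, humidity) combo
# categorical x per-combo bivariate Gaussian over (hour, temperature). The
# activity-conditional distribution is a stated shift of the prior
# (reweighted weekdays and combos, offset Gaussian means), which is what
# makes the likelihood ratio informative.

#' Parameters of the synthetic world
#'
#' Defaults describe a temperate mid-latitude climate surrogate: four
#' weather types with persistence-driven hourly transitions, temperature
#' coupled to hour of day and weather, and an activity-conditional shift in
#' which runs favor weekends, fair weather, late-afternoon hours and
#' slightly warmer temperatures.
#'
#' @param weekday_weights conditional reweighting of the (uniform) weekday
#'   prior; default doubles weekend days.
#' @param hour_shift,temp_shift offsets (hours, degrees C) added to every
#'   combo's Gaussian mean in the activity-conditional distribution.
#' @param persistence probability that the weather combo carries over from
#'   one hour to the next in the stream; the default gives synoptic-scale
#'   spells (mean length about a day and a half), so good and bad weather
#'   arrive as whole-day episodes.
#' @return a `synthetic_world` parameter object.
#' @export
synthetic_world <- function(weekday_weights = c(Mon = 1, Tue = 1, Wed = 1,
                                                Thu = 1, Fri = 1,
                                                Sat = 2, Sun = 2),
                            hour_shift = 4, temp_shift = 2,
                            persistence = 0.97) {
  levels <- list(weather = c("clear", "cloudy", "rain", "snow"),
                 wind = c("calm", "moderate", "strong"),
                 humidity = c("low", "moderate", "high"))
  # maritime mid-latitude climate: cloud and rain dominate the prior, and
  # the activity-conditional reweighting is strongly fair-weather-seeking
  # (runs are rare in rain, strong wind, or high humidity), so whether a
  # given afternoon is worth a notification genuinely depends on weather
  prior <- list(weather = c(clear = 0.22, cloudy = 0.38, rain = 0.32, snow = 0.08),
                wind = c(calm = 0.35, moderate = 0.45, strong = 0.20),
                humidity = c(low = 0.20, moderate = 0.50, high = 0.30))
  # the conditional reweighting is strongly concentrated: running is a rare
  # event that clusters in fair weather and the late afternoon, so most
  # context cells carry a desirability ratio well below one and only the
  # favorable cells rise far above it
  shift <- list(weekday_weights = weekday_weights,
                weather = c(clear = 3.2, cloudy = 0.35, rain = 0.06, snow = 0.02),
                wind = c(calm = 1.5, moderate = 0.8, strong = 0.15),
                humidity = c(low = 1.3, moderate = 0.9, high = 0.4),
                hour_shift = hour_shift, temp_shift = temp_shift)
  structure(list(
    levels = levels,
    prior = prior,
    shift = shift,
    temp_base = c(clear = 16, cloudy = 11, rain = 8, snow = -2),
    wind_mod = c(calm = 1, moderate = 0, strong = -2),
    humidity_mod = c(low = 1, moderate = 0, high = -1),
    gauss = list(hour_mean = 12, hour_var = 20.25, ht_cov = 8.1, temp_var = 16),
    persistence = persistence
  ), class = "synthetic_world")
}

#' Discrete-combo table of the synthetic world
#'
#' Enumerates all (weather, wind, humidity) combinations with their prior or
#' activity-conditional probabilities and the generating bivariate Gaussian
#' over (hour, temperature).
#'
#' @param params a [synthetic_world()].
#' @param conditional if TRUE, the activity-conditional distribution
#'   (reweighted combos, shifted means).
#' @return data frame with columns `weather,wind,humidity,key,prob,
#'   hour_mean,temp_mean,hour_var,ht_cov,temp_var`.
#' @export
world_combo_table <- function(params, conditional = FALSE) {
  lv <- params$levels
  g <- expand.grid(weather = lv$weather, wind = lv$wind,
                   humidity = lv$humidity, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  prob <- params$prior$weather[g$weather] *
    params$prior$wind[g$wind] *
    params$prior$humidity[g$humidity]
  hour_mean <- rep(params$gauss$hour_mean, nrow(g))
  temp_mean <- params$temp_base[g$weather] + params$wind_mod[g$wind] +
    params$humidity_mod[g$humidity]
  if (conditional) {
    w <- params$shift$weather[g$weather] * params$shift$wind[g$wind] *
      params$shift$humidity[g$humidity]
    prob <- prob * w
    prob <- prob / sum(prob)
    hour_mean <- hour_mean + params$shift$hour_shift
    temp_mean <- temp_mean + params$shift$temp_shift
  } else {
    prob <- prob / sum(prob)
  }
  data.frame(g,
             key = .combo_key(g$weather, g$wind, g$humidity),
             prob = unname(prob),
             hour_mean = unname(hour_mean),
             temp_mean = unname(temp_mean),
             hour_var = params$gauss$hour_var,
             ht_cov = params$gauss$ht_cov,
             temp_var = params$gauss$temp_var,
             stringsAsFactors = FALSE)
}

#' Weekday distribution of the synthetic world
#' @param params a [synthetic_world()].
#' @param conditional if TRUE, the activity-conditional (reweighted)
#'   distribution; otherwise uniform.
#' @return named probability 7-vector (Mon..Sun).
#' @export
world_weekday_probs <- function(params, conditional = FALSE) {
  if (!conditional) {
    p <- rep(1 / 7, 7)
    names(p) <- .WEEKDAYS
    return(p)
  }
  w <- params$shift$weekday_weights[.WEEKDAYS]
  w / sum(w)
}

# weekday index (1 = Mon) of a day offset from the Unix epoch (a Thursday)
.epoch_weekday <- function(days_since_epoch) {
  ((days_since_epoch + 3) %% 7) + 1
}

#' Generate an hourly weather stream
#'
#' Consecutive hourly context rows. The discrete (weather, wind, humidity)
#' combo follows a first-order categorical chain: with probability
#' `persistence` the previous combo carries over, otherwise a fresh combo is
#' drawn from the prior — making the prior the chain's stationary
#' distribution. Temperature is drawn from the combo's Gaussian conditioned
#' on the hour of day.
#'
#' @param params a [synthetic_world()].
#' @param n_hours number of hourly rows (starting at hour 0).
#' @param seed integer seed.
#' @param start_date first day (character, `YYYY-MM-DD`).
#' @return data frame with columns
#'   `timestamp,hour,weekday,temperature,weather,wind,humidity`.
#' @export
generate_weather_stream <- function(params, n_hours, seed,
                                    start_date = "2015-01-01") {
  stopifnot(inherits(params, "synthetic_world"), n_hours >= 1)
  combos <- world_combo_table(params, conditional = FALSE)
  rng <- rng_stream(seed)
  draws <- with_rng(rng, list(
    carry = stats::runif(n_hours) < params$persistence,
    fresh = sample.int(nrow(combos), n_hours, replace = TRUE,
                       prob = combos$prob),
    z = stats::rnorm(n_hours)
  ))
  idx <- integer(n_hours)
  idx[1] <- draws$fresh[1]
  if (n_hours > 1) {
    for (t in 2:n_hours) {
      idx[t] <- if (draws$carry[t]) idx[t - 1] else draws$fresh[t]
    }
  }
  hour <- (seq_len(n_hours) - 1) %% 24
  day0 <- as.integer(as.Date(start_date))
  days <- day0 + (seq_len(n_hours) - 1) %/% 24
  slope <- params$gauss$ht_cov / params$gauss$hour_var
  resid_sd <- sqrt(params$gauss$temp_var -
                     params$gauss$ht_cov^2 / params$gauss$hour_var)
  temp <- combos$temp_mean[idx] + slope * (hour - params$gauss$hour_mean) +
    resid_sd * draws$z
  data.frame(
    timestamp = sprintf("%s %02d:00:00", as.character(as.Date(days,
                                                              origin = "1970-01-01")), hour),
    hour = hour,
    weekday = .WEEKDAYS[.epoch_weekday(days)],
    temperature = round(temp, 2),
    weather = combos$weather[idx],
    wind = combos$wind[idx],
    humidity = combos$humidity[idx],
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic activity log
#'
#' One row per performed activity, drawn from the activity-conditional
#' distribution: weekday from the reweighted weekday categorical, a
#' (weather, wind, humidity) combo from the reweighted combo categorical,
#' and (hour, temperature) from the combo's shifted bivariate Gaussian
#' (rejection-sampled into hour in \[0, 24), a negligible truncation at the
#' default parameters).
#'
#' @param params a [synthetic_world()].
#' @param n_records number of activity rows.
#' @param seed integer seed.
#' @return data frame with the activity-log CSV columns.
#' @export
generate_activity_log <- function(params, n_records, seed) {
  stopifnot(inherits(params, "synthetic_world"), n_records >= 1)
  combos <- world_combo_table(params, conditional = TRUE)
  wd_probs <- world_weekday_probs(params, conditional = TRUE)
  rng <- rng_stream(seed)

  # bivariate Gaussian via Cholesky of the shared covariance
  cv <- matrix(c(params$gauss$hour_var, params$gauss$ht_cov,
                 params$gauss$ht_cov, params$gauss$temp_var), 2, 2)
  L <- t(chol(cv))

  sample_block <- function(n) {
    d <- with_rng(rng, list(
      wd = sample.int(7, n, replace = TRUE, prob = wd_probs),
      combo = sample.int(nrow(combos), n, replace = TRUE, prob = combos$prob),
      z = matrix(stats::rnorm(2 * n), 2, n)
    ))
    xy <- L %*% d$z
    data.frame(
      weekday_idx = d$wd,
      combo_idx = d$combo,
      hour = combos$hour_mean[d$combo] + xy[1, ],
      temperature = combos$temp_mean[d$combo] + xy[2, ],
      stringsAsFactors = FALSE
    )
  }

  # keep a margin below 24 so the later 3-decimal rounding cannot reach 24.0
  ok <- function(h) h >= 0 & h < 23.9995
  out <- sample_block(n_records)
  bad <- which(!ok(out$hour))
  while (length(bad) > 0) {
    repl <- sample_block(length(bad))
    out[bad, ] <- repl
    bad <- bad[!ok(repl$hour)]
  }

  # synthesize a timestamp on a base week consistent with weekday and hour
  base_monday <- as.integer(as.Date("2015-01-05"))
  days <- base_monday + out$weekday_idx - 1
  data.frame(
    timestamp = sprintf("%s %02d:%02d:00",
                        as.character(as.Date(days, origin = "1970-01-01")),
                        floor(out$hour),
                        floor((out$hour %% 1) * 60)),
    hour = round(out$hour, 3),
    weekday = .WEEKDAYS[out$weekday_idx],
    temperature = round(out$temperature, 2),
    weather = combos$weather[out$combo_idx],
    wind = combos$wind[out$combo_idx],
    humidity = combos$humidity[out$combo_idx],
    stringsAsFactors = FALSE
  )
}

#' Write an activity log / weather stream CSV
#'
#' Emits the exact CSV dialect the readers expect
#' (`timestamp,hour,weekday,temperature,weather,wind,humidity`).
#' @param df data frame from the generators.
#' @param path output path.
#' @export
write_context_csv <- function(df, path) {
  cols <- c("timestamp", "hour", "weekday", "temperature",
            "weather", "wind", "humidity")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
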