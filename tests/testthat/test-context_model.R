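make_records <- function(n, hour, temp, weekday = "Mon", weather = "clear",
                         wind = "calm", humidity = "low") {
  data.frame(hour = rep_len(hour, n), weekday = rep_len(weekday, n),
              temperature = rep_len(temp, n), weather = rep_len(weather, n),
              wind = rep_len(wind, n), humidity = rep_len(humidity, n),
              stringsAsFactors = FALSE)
}

test_that("weekday probabilities are empirical frequencies", {
  rec <- make_records(7, hour = 10, temp = 12,
                      weekday = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  rec$hour <- rec$hour + 0:6  # avoid a singular pooled Gaussian
  m <- fit_context_distribution(rec)
  expect_equal(unname(m$weekday_probs), rep(1 / 7, 7))
  expect_equal(sum(m$weekday_probs), 1, tolerance = 1e-9)
})

test_that("a combo's Gaussian mean is the sample mean", {
  rec <- make_records(2, hour = c(8, 12), temp = c(10, 14))
  m <- fit_context_distribution(rec)
  expect_equal(unname(m$gaussians[["clear|calm|low"]]$mean), c(10, 12))
  expect_equal(unname(m$combo_probs), 1)
})

test_that("fitting errors on empty or malformed input", {
  expect_error(fit_context_distribution(make_records(0, 1, 1)), "empty")
  bad <- make_records(3, hour = c(5, 25, 7), temp = 10)
  expect_error(fit_context_distribution(bad), "hour")
  bad2 <- make_records(3, hour = 5, temp = 10, weekday = "Monday")
  expect_error(fit_context_distribution(bad2), "weekday")
})

test_that("fitting recovers the parameters of a known two-combo world", {
  w2 <- two_combo_world()
  log40 <- generate_activity_log(w2, 40000, seed = 11)
  fit <- fit_context_distribution(log40)
  truth <- world_combo_table(w2, conditional = TRUE)
  expect_equal(nrow(truth), 2)
  for (k in truth$key) {
    g <- fit$gaussians[[k]]
    tr <- truth[truth$key == k, ]
    expect_lt(abs(g$mean[1] - tr$hour_mean), 0.1)
    expect_lt(abs(g$mean[2] - tr$temp_mean), 0.1)
    expect_lt(abs(g$cov[1, 1] - tr$hour_var) / tr$hour_var, 0.1)
    expect_lt(abs(g$cov[2, 2] - tr$temp_var) / tr$temp_var, 0.1)
    expect_lt(abs(g$cov[1, 2] - tr$ht_cov) / tr$ht_cov, 0.1)
    expect_lt(abs(fit$combo_probs[[k]] - tr$prob), 0.01)
  }
})

test_that("density factorizes as weekday x combo x Gaussian", {
  rec <- make_records(21, hour = rnorm(21, 12, 2), temp = rnorm(21, 10, 3),
                      weekday = rep(c("Mon", "Tue", "Wed"), each = 7))
  m <- fit_context_distribution(rec)
  g <- m$gaussians[["clear|calm|low"]]
  at_mean <- make_records(1, hour = g$mean[1], temp = g$mean[2])
  d_gauss <- ref_dmvnorm2(g$mean[1], g$mean[2], g$mean, g$cov)
  expect_equal(context_density(m, at_mean), (1 / 3) * 1 * d_gauss,
               tolerance = 1e-12)
})

test_that("unseen combos and weekdays hit the density floor, never zero", {
  rec <- make_records(5, hour = 9:13, temp = 10:14)
  m <- fit_context_distribution(
    rec, levels = list(weather = c("clear", "rain"), wind = "calm",
                       humidity = "low"))
  unseen <- make_records(1, hour = 10, temp = 10, weather = "rain")
  expect_equal(context_density(m, unseen), 1e-12)
  other_day <- make_records(1, hour = 10, temp = 10, weekday = "Sun")
  expect_equal(context_density(m, other_day), 1e-12)
  expect_gt(context_density(m, make_records(1, 10, 11)), 0)
})

test_that("density integrates to one over a fine grid for a one-combo model", {
  set.seed(3)
  rec <- make_records(400, hour = rnorm(400, 12, 2),
                      temp = rnorm(400, 10, 3),
                      weekday = sample(c("Mon", "Sat"), 400, replace = TRUE))
  rec$hour <- pmin(pmax(rec$hour, 0), 23.9)
  m <- fit_context_distribution(rec)
  hs <- seq(4, 20, by = 0.1)            # hour support must stay in [0, 24)
  ts <- seq(-15, 35, by = 0.2)
  total <- 0
  for (wd in c("Mon", "Sat")) {         # sum the categorical blocks
    grid <- expand.grid(hour = hs, temperature = ts)
    grid$weekday <- wd
    grid$weather <- "clear"; grid$wind <- "calm"; grid$humidity <- "low"
    total <- total + sum(context_density(m, grid)) * 0.1 * 0.2
  }
  expect_equal(total, 1, tolerance = 0.02)
})

test_that("likelihood ratio is one for identical models and responds to shifts", {
  ctx <- tw_weather[seq(1, 500, by = 7), ]
  expect_equal(likelihood_ratio(tw_prior, tw_prior, ctx),
               rep(1, nrow(ctx)))
  # conditional model concentrated at a context makes that context desirable
  peak <- make_records(60, hour = rnorm(60, 17, 0.5), temp = rnorm(60, 15, 0.5),
                       weekday = "Sat")
  conc <- fit_context_distribution(peak, levels = tw_prior$levels)
  at_peak <- make_records(1, hour = 17, temp = 15, weekday = "Sat")
  expect_gt(likelihood_ratio(conc, tw_prior, at_peak), 1)
})

test_that("likelihood ratio matches direct hand computation on a 2-combo fixture", {
  rec <- rbind(
    make_records(4, hour = c(8, 9, 10, 11), temp = c(5, 6, 7, 8)),
    make_records(4, hour = c(15, 16, 17, 18), temp = c(12, 13, 14, 15),
                 weather = "rain", weekday = "Tue")
  )
  prior2 <- fit_context_distribution(rec)
  shifted <- rec
  shifted$hour <- shifted$hour + 1
  cond2 <- fit_context_distribution(shifted, levels = prior2$levels)
  q <- make_records(1, hour = 10, temp = 7)
  num <- cond2$weekday_probs[["Mon"]] * cond2$combo_probs[["clear|calm|low"]] *
    ref_dmvnorm2(10, 7, cond2$gaussians[["clear|calm|low"]]$mean,
                 cond2$gaussians[["clear|calm|low"]]$cov)
  den <- prior2$weekday_probs[["Mon"]] * prior2$combo_probs[["clear|calm|low"]] *
    ref_dmvnorm2(10, 7, prior2$gaussians[["clear|calm|low"]]$mean,
                 prior2$gaussians[["clear|calm|low"]]$cov)
  expect_equal(likelihood_ratio(cond2, prior2, q), unname(num / den),
               tolerance = 1e-9)
})

test_that("the ratio is capped and uninformative where both densities floor", {
  lv <- list(weather = c("clear", "snow"), wind = "calm", humidity = "low")
  a <- fit_context_distribution(make_records(5, 9:13, 10:14), levels = lv)
  b <- fit_context_distribution(make_records(5, 9:13, 10:14), levels = lv)
  q_unseen <- make_records(1, 10, 10, weather = "snow")
  expect_equal(likelihood_ratio(a, b, q_unseen), 1)
  # concentrated numerator against diffuse denominator hits the cap
  tight <- make_records(50, hour = rnorm(50, 12, 0.05),
                        temp = rnorm(50, 10, 0.05))
  wide <- make_records(50, hour = pmin(pmax(rnorm(50, 12, 8), 0), 23.9),
                       temp = rnorm(50, 10, 8))
  r <- likelihood_ratio(fit_context_distribution(tight),
                        fit_context_distribution(wide),
                        make_records(1, 12, 10))
  expect_lte(r, 100)
})

test_that("probability blocks sum to one for arbitrary logs (property)", {
  for (s in 1:5) {
    log_s <- generate_activity_log(tw, 300, seed = 1000 + s)
    m <- fit_context_distribution(log_s)
    expect_equal(sum(m$weekday_probs), 1, tolerance = 1e-9)
    expect_equal(sum(m$combo_probs), 1, tolerance = 1e-9)
    for (g in m$gaussians) {
      expect_true(all(eigen(g$cov, symmetric = TRUE,
                            only.values = TRUE)$values > 0))
      expect_equal(g$cov[1, 2], g$cov[2, 1])
    }
  }
})

test_that("model JSON serialization round-trips densities exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  write_context_model(tw_cond, path)
  back <- read_context_model(path)
  ctx <- tw_weather[1:50, ]
  expect_equal(context_density(back, ctx), context_density(tw_cond, ctx))
  expect_equal(back$levels, tw_cond$levels)
})

test_that("activity-log and weather CSVs round-trip through the writers", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_context_csv(tw_log[1:100, ], path)
  expect_identical(readLines(path, n = 1),
                   "timestamp,hour,weekday,temperature,weather,wind,humidity")
  back <- read_activity_log(path)
  expect_equal(back$hour, tw_log$hour[1:100])
  expect_equal(back$weather, tw_log$weather[1:100])
})
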