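# Shared small-scale world: one synthetic parameter set, a weather stream
# covering 12 full weeks, a 6,000-run activity log, and the fitted context
# model pair. Built once per test run.

tw <- synthetic_world()
tw_weather <- generate_weather_stream(tw, 24 * 7 * 12, seed = 421)
tw_log <- generate_activity_log(tw, 6000, seed = 422)
tw_prior <- fit_context_distribution(tw_weather)
tw_cond <- fit_context_distribution(tw_log, levels = tw_prior$levels)

# reduced world with exactly two discrete combos and a centered, narrow
# hour Gaussian (no appreciable [0,24) truncation), for well-powered
# parameter-recovery checks
two_combo_world <- function() {
  w <- synthetic_world(hour_shift = 0)
  w$levels <- list(weather = c("clear", "rain"), wind = "calm",
                   humidity = "low")
  w$prior <- list(weather = c(clear = 0.6, rain = 0.4),
                  wind = c(calm = 1), humidity = c(low = 1))
  w$shift$weather <- c(clear = 1.5, rain = 0.5)
  w$shift$wind <- c(calm = 1)
  w$shift$humidity <- c(low = 1)
  w$gauss <- list(hour_mean = 12, hour_var = 6.25, ht_cov = 2.5,
                  temp_var = 16)
  w
}

# mean of a normal truncated to [lo, hi] (the activity generator's hour
# domain), and the induced temperature mean through the regression slope
truncated_combo_means <- function(tr, lo = 0, hi = 23.9995) {
  s <- sqrt(tr$hour_var)
  a <- (lo - tr$hour_mean) / s
  b <- (hi - tr$hour_mean) / s
  delta <- (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  hour_mu <- tr$hour_mean + s * delta
  slope <- tr$ht_cov / tr$hour_var
  c(hour = hour_mu, temp = tr$temp_mean + slope * (hour_mu - tr$hour_mean))
}

make_test_env <- function(cfg = simulator_config(), restrict = "agent") {
  notification_env(cfg, tw_weather, tw_cond, tw_prior, restrict = restrict)
}

# independent bivariate normal density (arithmetic oracle for tests)
ref_dmvnorm2 <- function(x, y, mean, cov) {
  d <- det(cov)
  inv <- solve(cov)
  v <- c(x - mean[1], y - mean[2])
  exp(-0.5 * drop(t(v) %*% inv %*% v)) / (2 * pi * sqrt(d))
}

# brute-force collapsed marginalization of the decision probability: place
# the deterministic (Kronecker-delta) transition masses on a discrete grid
# of candidate (M, U) values and sum ratio * P(A|U,M) * P(M|N,m_prev) *
# P(U|A_prev,u_prev) over the grid.
ref_decision_probability <- function(m_prev, u_prev, notified, acted_prev,
                                     ratio, sigma = 0.8, mu = 0.05) {
  m_star <- if (notified == 1) 1.0 else sigma * m_prev
  u_star <- if (acted_prev == 1) 0.0 else min(1, u_prev + mu)
  m_grid <- unique(c(seq(0, 1, by = 0.125), m_star))
  u_grid <- unique(c(seq(0, 1, by = 0.125), u_star))
  total <- 0
  for (m in m_grid) for (u in u_grid) {
    p_m <- as.numeric(m == m_star)   # delta mass
    p_u <- as.numeric(u == u_star)
    total <- total + ratio * (u * m) * p_m * p_u
  }
  min(1, max(0, total))
}
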