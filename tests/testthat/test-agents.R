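# deterministic zero policy: logits (0,0), send probability exactly 0.5
zero_policy <- function(obs_dim, hidden = 4) {
  p <- policy_new(obs_dim, hidden = hidden, rng = rng_stream(1))
  p$W1[] <- 0; p$b1[] <- 0; p$W2[] <- 0; p$b2[] <- 0
  p
}

test_that("policy outputs are probabilities summing to one", {
  pol <- policy_new(10, hidden = 8, rng = rng_stream(3))
  X <- matrix(rnorm(50), 5, 10)
  P <- policy_probs(pol, X)
  expect_equal(rowSums(P), rep(1, 5))
  expect_true(all(P > 0 & P < 1))
})

test_that("agent-side clipping forces no-send at zero budget, C-mode samples freely", {
  pol <- zero_policy(4)
  obs <- rep(0.5, 4)
  out <- select_action(pol, obs, remaining_budget = 0, mode = "R")
  expect_equal(out$action, 0L)
  expect_true(out$forced)
  expect_equal(out$p_send, 0)
  # C-mode may still choose to send with an exhausted budget
  rng <- rng_stream(8)
  acts <- replicate(50, select_action(pol, obs, 0, mode = "C", rng)$action)
  expect_true(any(acts == 1))
})

test_that("a balanced policy sends about half the time", {
  pol <- zero_policy(4)
  rng <- rng_stream(12)
  acts <- replicate(10000, select_action(pol, rep(0.2, 4), 5, "R", rng)$action)
  expect_lt(abs(mean(acts) - 0.5), 0.015)
})

test_that("returns accumulate rewards under the discount", {
  expect_equal(compute_returns(c(0, 1, 0, 1), 1), c(2, 2, 1, 1))
  expect_equal(compute_returns(numeric(4), 1), numeric(4))
  r <- c(0.3, 1, 0.2)
  expect_equal(compute_returns(r, 0), r)
  expect_equal(compute_returns(c(1, 1, 1), 0.5), c(1.75, 1.5, 1))
})

test_that("baseline buffer averages per-step returns over its window", {
  b <- baseline_buffer(n_steps = 3, window = 2)
  expect_equal(baseline_values(b), c(0, 0, 0))
  baseline_push(b, c(1, 2, 3))
  expect_equal(baseline_values(b), c(1, 2, 3))
  baseline_push(b, c(3, 2, 1))
  expect_equal(baseline_values(b), c(2, 2, 2))
  baseline_push(b, c(5, 6, 7))   # evicts the oldest episode
  expect_equal(baseline_values(b), c(4, 4, 4))
})

test_that("the analytic policy gradient matches central finite differences", {
  pol <- policy_new(3, hidden = 2, rng = rng_stream(5))
  set.seed(17)
  X <- matrix(rnorm(15), 5, 3)
  actions <- c(0L, 1L, 1L, 0L, 1L)
  adv <- c(0.5, -1.2, 2.0, 0.3, -0.4)
  forced <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  g <- policy_gradient(pol, X, actions, adv, forced)
  loss <- function(p) {
    P <- policy_probs(p, X)
    sum(log(P[cbind(1:5, actions + 1)]) * adv * !forced)
  }
  h <- 1e-5
  for (nm in c("W1", "b1", "W2", "b2")) {
    for (i in seq_along(pol[[nm]])) {
      pp <- pol; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- pol; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss(pp) - loss(pm)) / (2 * h)
      expect_lt(abs(fd - g[[nm]][i]), 1e-5)
    }
  }
})

test_that("zero advantages leave the policy unchanged", {
  pol <- policy_new(4, hidden = 3, rng = rng_stream(6))
  X <- matrix(rnorm(12), 3, 4)
  b <- baseline_buffer(3, window = 5)
  baseline_push(b, c(1, 1, 1))
  upd <- reinforce_update(pol, X, c(1L, 0L, 1L), returns = c(1, 1, 1),
                          forced = rep(FALSE, 3), buffer = b)
  expect_equal(upd$W1, pol$W1)
  expect_equal(upd$b2, pol$b2)
})

test_that("a positive-advantage send step increases the send probability", {
  pol <- policy_new(4, hidden = 8, rng = rng_stream(9))
  x <- c(0.1, -0.3, 0.7, 0.2)
  b <- baseline_buffer(1, window = 5)
  p0 <- policy_probs(pol, x)[1, 2]
  upd <- reinforce_update(pol, matrix(x, 1), actions = 1L, returns = 2,
                          forced = FALSE, buffer = b, lr = 0.01)
  expect_gt(policy_probs(upd, x)[1, 2], p0)
})

test_that("forced steps contribute exactly zero gradient", {
  pol <- policy_new(4, hidden = 3, rng = rng_stream(10))
  X <- matrix(rnorm(20), 5, 4)
  actions <- c(1L, 0L, 0L, 1L, 0L)
  adv <- c(1.5, -0.5, 2, 1, -1)
  forced <- c(FALSE, FALSE, TRUE, FALSE, TRUE)
  g_all <- policy_gradient(pol, X, actions, adv, forced)
  keep <- !forced
  g_sub <- policy_gradient(pol, X[keep, , drop = FALSE], actions[keep],
                           adv[keep], forced[keep])
  expect_identical(g_all$W1, g_sub$W1)
  expect_identical(g_all$W2, g_sub$W2)
  expect_identical(g_all$b1, g_sub$b1)
  expect_identical(g_all$b2, g_sub$b2)
})

test_that("adam optimizer updates parameters and keeps state", {
  pol <- policy_new(4, hidden = 3, rng = rng_stream(11))
  X <- matrix(rnorm(12), 3, 4)
  b <- baseline_buffer(3, window = 5)
  upd <- reinforce_update(pol, X, c(1L, 0L, 1L), returns = c(2, 0, 1),
                          forced = rep(FALSE, 3), buffer = b,
                          optimizer = "adam")
  expect_false(identical(upd$W2, pol$W2))
  expect_equal(upd$opt$t, 1)
})

test_that("policy checkpoints round-trip through JSON exactly", {
  pol <- policy_new(6, hidden = 5, rng = rng_stream(44))
  b <- baseline_buffer(2, window = 3)
  pol <- reinforce_update(pol, matrix(rnorm(12), 2, 6), c(1L, 0L),
                          returns = c(1, 0), forced = c(FALSE, FALSE),
                          buffer = b, optimizer = "adam")
  path <- withr::local_tempfile(fileext = ".json")
  write_policy(pol, path)
  back <- read_policy(path)
  X <- matrix(rnorm(18), 3, 6)
  expect_equal(policy_probs(back, X), policy_probs(pol, X))
  expect_equal(back$opt$t, pol$opt$t)
  expect_equal(back$opt$v$W1, pol$opt$v$W1)
})

test_that("fixed baseline sends exactly at 12:00 and 16:00 every day", {
  cfg <- simulator_config()
  ag <- make_baseline_agent("fixed", cfg)
  s <- ag$schedule(rng_stream(1))
  hours <- rep(cfg$decision_hours, cfg$episode_days)
  expect_equal(sort(unique(hours[s == 1])), c(12, 16))
  expect_equal(sum(s), 14)
  days <- rep(seq_len(7), each = 13)
  expect_true(all(tapply(s, days, sum) == 2))
})

test_that("random-week baseline uses its whole budget, random-day picks 2 a day", {
  cfg <- simulator_config()
  rng <- rng_stream(21)
  for (i in 1:20) {
    expect_equal(sum(make_baseline_agent("random_week", cfg)$schedule(rng)), 14)
    s <- make_baseline_agent("random_day", cfg)$schedule(rng)
    expect_true(all(tapply(s, rep(1:7, each = 13), sum) == 2))
  }
  expect_error(make_baseline_agent("nope", cfg), "unknown")
})

test_that("random-day selection is uniform over decision hours", {
  cfg <- simulator_config()
  ag <- make_baseline_agent("random_day", cfg)
  rng <- rng_stream(33)
  counts <- numeric(13)
  n_episodes <- 1500                        # 10,500 days
  for (i in seq_len(n_episodes)) {
    s <- ag$schedule(rng)
    counts <- counts + colSums(matrix(s, nrow = 7, byrow = TRUE))
  }
  freq <- counts / (n_episodes * 7)
  expect_true(all(abs(freq - 2 / 13) < 0.02))
})

test_that("the R agent learns on a simulator that pays only in flagged contexts", {
  # degenerate world: the user responds essentially only to notifications
  # sent during clear-weather hours around mid-afternoon; everything else
  # has desirability near zero, so the learning signal is crisp
  w <- synthetic_world(persistence = 0.9)
  stream <- generate_weather_stream(w, 24 * 7 * 20, seed = 77)
  prior <- fit_context_distribution(stream)
  set.seed(5)
  n <- 1200
  good <- data.frame(
    hour = pmin(pmax(rnorm(n, 14, 2.5), 0), 23.9),
    weekday = sample(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"),
                     n, replace = TRUE),
    temperature = rnorm(n, 15, 3),
    weather = "clear",
    wind = sample(c("calm", "moderate", "strong"), n, replace = TRUE),
    humidity = sample(c("low", "moderate", "high"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cond <- fit_context_distribution(good, levels = prior$levels)
  env <- notification_env(simulator_config(), stream, cond, prior)
  improved <- logical(3)
  for (s in 1:3) {
    run <- train_agent(env, "R", 1500, env_seed = 200 + s,
                       agent_seed = 300 + s)
    r <- run$results$reward
    improved[s] <- mean(r[1001:1500]) > mean(r[1:500])
  }
  expect_true(all(improved))
})
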