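# Dynamic-Bayesian-network user simulator.
#
# Latent state: memory accessibility M (reset to 1 by a notification, decaying
# geometrically by sigma per hour otherwise) and urge U (reset to 0 by
# performing the activity, recovering linearly by mu per hour otherwise).
# The activity decision at a decision hour is Bernoulli with probability
# clamp(ratio(C) * U * M, 0, 1), where ratio(C) is the context-desirability
# likelihood ratio. Because the M and U transitions are Kronecker-delta
# deterministic given their parents, marginalizing over them collapses to a
# single term.

#' Memory-accessibility transition
#'
#' A notification resets memory accessibility of the target activity to its
#' maximum (1); otherwise it decays exponentially at retention rate `sigma`
#' per hour.
#'
#' @param m_prev previous memory value in (0, 1].
#' @param notified 0/1, whether a notification was delivered this hour.
#' @param sigma hourly retention rate in (0, 1).
#' @return the new memory value.
#' @export
update_memory <- function(m_prev, notified, sigma = 0.8) {
  stopifnot(all(m_prev > 0), all(m_prev <= 1), sigma > 0, sigma < 1)
  ifelse(notified == 1, 1.0, sigma * m_prev)
}

#' Urge transition
#'
#' Performing the activity resets the urge to 0; otherwise the urge recovers
#' linearly at rate `mu` per hour, capped at 1.
#'
#' @param u_prev previous urge in \[0, 1\].
#' @param acted_prev 0/1, whether the activity was performed last hour.
#' @param mu hourly recovery rate in (0, 1).
#' @return the new urge value.
#' @export
update_urge <- function(u_prev, acted_prev, mu = 0.05) {
  stopifnot(all(u_prev >= 0), all(u_prev <= 1), mu > 0, mu < 1)
  ifelse(acted_prev == 1, 0.0, pmin(1, u_prev + mu))
}

#' Probability of acting given memory and urge alone
#'
#' The context-free component of the decision model: `P(A=1|U,M) = U * M`.
#' It is monotone in each argument, stays in \[0,1\], and is zero whenever
#' either determinant is absent.
#'
#' @param m memory accessibility in \[0, 1\].
#' @param u urge in \[0, 1\].
#' @return probability in \[0, 1\].
#' @export
base_action_probability <- function(m, u) {
  stopifnot(all(m >= 0), all(m <= 1), all(u >= 0), all(u <= 1))
  u * m
}

#' One-step decision probability of the simulated user
#'
#' Advances the deterministic latent transitions (memory given the
#' notification, urge given the previous action) and returns the probability
#' that the user performs the activity this hour:
#' `clamp(ratio * U_t * M_t, 0, 1)`. The product with the likelihood ratio
#' is not guaranteed to stay below 1, so it is clamped.
#'
#' @param m_prev,u_prev latent state before the transition.
#' @param notified 0/1 notification delivered this hour.
#' @param acted_prev 0/1 activity performed at the previous hour.
#' @param ratio context-desirability likelihood ratio at this hour.
#' @param sigma,mu transition rates.
#' @return list with `p` (decision probability), `memory`, `urge` (the
#'   post-transition latent values).
#' @export
decision_probability <- function(m_prev, u_prev, notified, acted_prev, ratio,
                                 sigma = 0.8, mu = 0.05) {
  m <- update_memory(m_prev, notified, sigma)
  u <- update_urge(u_prev, acted_prev, mu)
  p <- pmin(1, pmax(0, ratio * base_action_probability(m, u)))
  list(p = p, memory = m, urge = u)
}

#' Simulator configuration
#'
#' @param sigma hourly memory retention rate (default 0.8).
#' @param mu hourly urge recovery rate (default 0.05).
#' @param decision_hours hours of day at which the agent decides
#'   (default 8..20 inclusive, i.e. 13 decisions/day).
#' @param episode_days days per episode (default 7, one week).
#' @param budget maximum notifications deliverable per episode (default 14).
#' @param reward_per_run reward credited when the user runs within the hour.
#' @param initial_memory,initial_urge latent state at 0:00 of the episode's
#'   first day.
#' @param ratio_max cap on the likelihood ratio.
#' @return a `simulator_config` list.
#' @export
simulator_config <- function(sigma = 0.8, mu = 0.05,
                             decision_hours = 8:20, episode_days = 7,
                             budget = 14, reward_per_run = 1.0,
                             initial_memory = 0.5, initial_urge = 0.5,
                             ratio_max = 100) {
  stopifnot(sigma > 0, sigma < 1, mu > 0, mu < 1,
            budget >= 0, episode_days >= 1,
            all(diff(decision_hours) > 0),
            all(decision_hours >= 0), all(decision_hours <= 23),
            initial_memory > 0, initial_memory <= 1,
            initial_urge >= 0, initial_urge <= 1)
  structure(list(sigma = sigma, mu = mu,
                 decision_hours = as.integer(decision_hours),
                 episode_days = as.integer(episode_days),
                 budget = as.integer(budget),
                 reward_per_run = reward_per_run,
                 initial_memory = initial_memory,
                 initial_urge = initial_urge,
                 ratio_max = ratio_max),
            class = "simulator_config")
}

#' Number of decision steps per episode
#' @param cfg a [simulator_config()].
#' @return integer step count (91 with defaults).
#' @export
steps_per_episode <- function(cfg) {
  cfg$episode_days * length(cfg$decision_hours)
}

# ---------------------------------------------------------------------------
# RNG streams: the environment and each agent draw from their own stream so
# that trajectories are coupled across agents sharing an environment seed.

#' Create an independent RNG stream
#' @param seed integer seed.
#' @return an opaque stream object for [with_rng()].
#' @export
rng_stream <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env <- new.env(parent = emptyenv())
  env$state <- state
  class(env) <- "rng_stream"
  env
}

#' Evaluate an expression under an RNG stream
#'
#' Swaps the stream's saved state into R's global RNG, evaluates `expr`, and
#' saves the advanced state back, restoring whatever RNG state was current.
#' @param rng a [rng_stream()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# ---------------------------------------------------------------------------
# Environment

#' Build the weekly notification environment
#'
#' Wraps an hourly weather stream and a fitted pair of context models into an
#' episodic environment. Episodes start at 0:00 of a random date; the agent
#' decides whether to notify at every decision hour; the user's response
#' follows the DBN. Between decision points (overnight) the latent dynamics
#' advance one hourly update per skipped hour with no decision and no
#' notification. The per-row context desirability and the static part of the
#' agent observation are precomputed here.
#'
#' @param cfg a [simulator_config()].
#' @param weather hourly weather stream data frame
#'   (see [read_weather_stream()]); rows must be consecutive hours starting
#'   at hour 0.
#' @param cond,prior fitted context models (activity-conditional and
#'   marginal).
#' @param restrict `"agent"` — deliveries follow the agent's actions (the
#'   agent is responsible for respecting the budget); `"env"` — the
#'   environment suppresses deliveries beyond the budget; `"none"` — no
#'   restriction.
#' @return a mutable environment object of class `notification_env`.
#' @export
notification_env <- function(cfg, weather, cond, prior, restrict = c("agent", "env", "none")) {
  restrict <- match.arg(restrict)
  stopifnot(inherits(cfg, "simulator_config"))
  .check_context_frame(weather)
  n_hours_needed <- 24 * cfg$episode_days
  if (nrow(weather) < n_hours_needed) {
    stop("weather stream shorter than one episode (", n_hours_needed, " hours)")
  }
  if (weather$hour[1] != 0) stop("weather stream must start at hour 0")
  if (any(weather$hour != (seq_len(nrow(weather)) - 1) %% 24)) {
    stop("weather stream hours must be consecutive (0..23 cycling)")
  }

  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  e$restrict <- restrict
  e$weather <- weather
  e$desirability <- likelihood_ratio(cond, prior, weather, ratio_max = cfg$ratio_max)
  e$obs_static <- .encode_static(weather, cond$levels)
  e$n_days <- nrow(weather) %/% 24
  # admissible start days: a full episode must fit
  e$max_start_day <- e$n_days - cfg$episode_days + 1
  if (e$max_start_day < 1) stop("weather stream shorter than one episode")
  e$step_hours <- rep(cfg$decision_hours, cfg$episode_days) +
    24 * rep(seq_len(cfg$episode_days) - 1L, each = length(cfg$decision_hours))
  e$n_steps <- length(e$step_hours)
  e$done <- TRUE
  class(e) <- "notification_env"
  e
}

# One-hot weekday + one-hot discrete features + normalized hour/temperature,
# one row per weather-stream row. Levels come from the fitted model so the
# encoding is stable across streams.
.encode_static <- function(weather, levels) {
  enc1 <- function(x, lv) {
    m <- matrix(0, nrow = length(x), ncol = length(lv),
                dimnames = list(NULL, lv))
    m[cbind(seq_along(x), match(as.character(x), lv))] <- 1
    m
  }
  cbind(
    enc1(weather$weekday, .WEEKDAYS),
    enc1(weather$weather, levels$weather),
    enc1(weather$wind, levels$wind),
    enc1(weather$humidity, levels$humidity),
    hour = weather$hour / 23,
    temperature = weather$temperature / 30
  )
}

#' Observation dimensionality of an environment
#' @param env a `notification_env`.
#' @return integer: static context features + remaining budget +
#'   hours-since-last-run.
#' @export
observation_dim <- function(env) ncol(env$obs_static) + 2L

#' Reset the environment to the start of a new episode
#'
#' Picks a uniformly random start date (0:00-aligned) from the weather
#' stream, sets the latent state to its initial values, and advances the
#' clock to the first decision hour, applying one hourly latent update per
#' skipped hour. The decision step at the first decision hour applies the
#' final hourly transition itself, so with default hours the memory entering
#' the first decision is `initial_memory * sigma^8`.
#'
#' All environment randomness for the episode (the start date and the
#' uniform draws behind each user decision) is drawn here from the
#' environment's RNG stream, so two agents driven by the same environment
#' seed face identical weather, start dates, and decision draws — the
#' common-random-numbers coupling used when agents share an environment
#' initialization.
#'
#' @param env a `notification_env`.
#' @param rng a [rng_stream()] for the environment's randomness.
#' @return the first observation (numeric vector), invisibly also stored in
#'   the environment.
#' @export
env_reset <- function(env, rng) {
  cfg <- env$cfg
  draws <- with_rng(rng, list(start_day = sample.int(env$max_start_day, 1L),
                              u = stats::runif(env$n_steps)))
  start_day <- draws$start_day
  env$u_decisions <- draws$u
  env$start_row <- (start_day - 1L) * 24L
  env$memory <- cfg$initial_memory
  env$urge <- cfg$initial_urge
  env$last_action <- 0L
  env$notifications_used <- 0L
  env$step_idx <- 0L
  env$hours_since_run <- 72L
  env$done <- FALSE
  # advance 0:00 -> first decision hour; the decision step itself performs
  # the final hourly transition, so apply (first_hour - 1) updates here
  n_skip <- cfg$decision_hours[1] - 1L
  if (n_skip > 0) {
    env$memory <- cfg$sigma^n_skip * env$memory
    env$urge <- min(1, env$urge + n_skip * cfg$mu)
    env$hours_since_run <- env$hours_since_run + n_skip
  }
  invisible(env_observation(env))
}

#' Current observation vector
#'
#' Static context encoding of the upcoming decision hour plus the normalized
#' remaining budget and (capped, normalized) hours since the last run. The
#' latent memory and urge are deliberately not observable.
#' @param env a `notification_env`.
#' @return numeric vector of length [observation_dim()].
#' @export
env_observation <- function(env) {
  if (env$done) stop("environment is done; call env_reset()")
  cfg <- env$cfg
  row <- env$start_row + env$step_hours[env$step_idx + 1L] + 1L
  c(env$obs_static[row, ],
    budget = max(0, cfg$budget - env$notifications_used) / max(1, cfg$budget),
    recency = min(env$hours_since_run, 72) / 72)
}

#' Advance the environment by one decision step
#'
#' Within a step: (1) the notification is delivered unless an environment-side
#' restriction suppresses it; (2) memory updates given the notification;
#' (3) urge updates given the previous hour's action; (4) the user's decision
#' is sampled from the context-modulated probability; (5) the reward is
#' `reward_per_run` per run; (6) the clock advances to the next decision
#' hour, applying one latent hourly update per skipped hour.
#'
#' The user's decision is resolved against the uniform draw pre-committed
#' for this step at [env_reset()].
#'
#' @param env a `notification_env` (mutated in place).
#' @param action 0/1, the agent's send decision.
#' @return list with `observation` (NULL when done), `reward`, `done`, and
#'   `info` (delivered notification, latent state, desirability).
#' @export
env_step <- function(env, action) {
  if (env$done) stop("env_step() called on a finished episode")
  cfg <- env$cfg
  sig <- cfg$sigma
  mu <- cfg$mu

  delivered <- as.integer(action != 0)
  if (delivered == 1L && env$restrict == "env" &&
      env$notifications_used >= cfg$budget) {
    delivered <- 0L
  }

  row <- env$start_row + env$step_hours[env$step_idx + 1L] + 1L
  ratio <- env$desirability[row]

  m <- if (delivered == 1L) 1.0 else sig * env$memory
  u <- if (env$last_action == 1L) 0.0 else min(1, env$urge + mu)
  p <- min(1, ratio * u * m)
  a <- as.integer(env$u_decisions[env$step_idx + 1L] < p)
  reward <- cfg$reward_per_run * a

  env$notifications_used <- env$notifications_used + delivered
  env$memory <- m
  env$urge <- u
  env$last_action <- a
  env$hours_since_run <- if (a == 1L) 0L else env$hours_since_run + 1L
  env$last_info <- list(notification = delivered, memory = m, urge = u,
                        action = a, desirability = ratio,
                        clock = env$step_hours[env$step_idx + 1L])

  env$step_idx <- env$step_idx + 1L
  if (env$step_idx >= env$n_steps) {
    env$done <- TRUE
    return(list(observation = NULL, reward = reward, done = TRUE,
                info = env$last_info))
  }

  # hourly updates for skipped (non-decision) hours; the next decision step
  # performs its own final hourly transition
  gap <- env$step_hours[env$step_idx + 1L] - env$step_hours[env$step_idx]
  n_skip <- gap - 1L
  if (n_skip > 0L) {
    for (i in seq_len(n_skip)) {
      env$memory <- sig * env$memory
      env$urge <- if (env$last_action == 1L) 0.0 else min(1, env$urge + mu)
      env$last_action <- 0L
      env$hours_since_run <- env$hours_since_run + 1L
    }
  }
  list(observation = env_observation(env), reward = reward, done = FALSE,
       info = env$last_info)
}
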