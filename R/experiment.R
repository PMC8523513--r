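# Experiment runners: train/evaluate agents on a shared environment
# initialization, produce per-episode results, sliding-window learning
# curves, and episode visualizations.

# placeholder policy passed to the rollout kernel for rule-based agents
# (the kernel never evaluates it when a schedule is supplied)
.null_policy <- list(W1 = matrix(0, 1, 1), b1 = 0,
                     W2 = matrix(0, 2, 1), b2 = c(0, 0))

#' Train or evaluate one agent on an environment
#'
#' Runs `episodes` weekly episodes. Learning agents (`"R"`, `"C"`, `"B"`)
#' update a REINFORCE policy once per episode; rule-based agents
#' (`"random_week"`, `"random_day"`, `"fixed"`) follow their schedules with
#' no learning. The environment's restriction mode is set from the agent
#' mode: agent-side clipping for R, environment-side suppression for C, and
#' for B no restriction until `switch_episode`, environment-side after.
#'
#' @param env a [notification_env()] (its `restrict` field is set here).
#' @param mode agent mode.
#' @param episodes number of episodes.
#' @param env_seed seed of the environment RNG stream. Agents run with equal
#'   `env_seed` share start dates, weather, and user-decision draws.
#' @param agent_seed seed of the agent RNG stream (policy initialization and
#'   action sampling).
#' @param hidden,lr,gamma,baseline_window,optimizer policy hyperparameters
#'   (see [reinforce_update()]).
#' @param switch_episode first episode (1-based) at which a B agent becomes
#'   restricted.
#' @param trace_episodes integer vector of episode numbers for which a full
#'   [EpisodeTrace][visualize_episode()] data frame is kept.
#' @return list with `results` (data frame `episode,reward,notifications`),
#'   `policy` (NULL for rule-based agents), and `traces` (named list).
#' @export
train_agent <- function(env, mode, episodes,
                        env_seed = 1, agent_seed = env_seed + 10000,
                        hidden = 64, lr = 0.001, gamma = 1,
                        baseline_window = 50, switch_episode = 15000,
                        optimizer = "sgd", trace_episodes = integer(0)) {
  cfg <- env$cfg
  n_steps <- env$n_steps
  env_rng <- rng_stream(env_seed)
  agent_rng <- rng_stream(agent_seed)
  learning <- mode %in% c("R", "C", "B")
  if (!learning && !mode %in% c("random_week", "random_day", "fixed")) {
    stop("unknown agent mode: ", mode)
  }

  env$restrict <- switch(mode,
                         R = "agent",
                         C = "env",
                         B = if (switch_episode <= 1) "env" else "none",
                         "env")

  policy <- NULL
  buffer <- NULL
  baseline <- NULL
  if (learning) {
    policy <- policy_new(observation_dim(env), hidden = hidden, rng = agent_rng)
    buffer <- baseline_buffer(n_steps, window = baseline_window)
  } else {
    baseline <- make_baseline_agent(mode, cfg)
  }

  rewards_ep <- numeric(episodes)
  notes_ep <- integer(episodes)
  traces <- list()

  # episode constants shared with the compiled rollout kernel; the state
  # entering the first decision hour reflects the hourly updates applied
  # between 0:00 and that hour (the first step performs the final one)
  h1 <- cfg$decision_hours[1]
  m0 <- cfg$initial_memory * cfg$sigma^(h1 - 1)
  u0 <- min(1, cfg$initial_urge + (h1 - 1) * cfg$mu)
  hsr0 <- 72L + (h1 - 1L)
  gaps <- c(0L, diff(env$step_hours) - 1L)
  zero_sched <- integer(0)

  for (ep in seq_len(episodes)) {
    if (mode == "B" && ep == switch_episode) env$restrict <- "env"
    mode_int <- switch(env$restrict, agent = 0L, env = 1L, none = 2L)
    draws <- with_rng(env_rng,
                      list(start_day = sample.int(env$max_start_day, 1L),
                           u = stats::runif(n_steps)))
    start_row <- (draws$start_day - 1L) * 24L
    rows <- start_row + env$step_hours + 1L

    if (learning) {
      u_agent <- with_rng(agent_rng, stats::runif(n_steps))
      sched <- zero_sched
    } else {
      u_agent <- numeric(n_steps)
      sched <- as.integer(baseline$schedule(agent_rng))
    }
    pol <- if (learning) policy else .null_policy
    out <- rollout_episode_cpp(pol$W1, pol$b1, pol$W2, pol$b2,
                               env$obs_static[rows, , drop = FALSE],
                               env$desirability[rows], gaps,
                               draws$u, u_agent, sched,
                               cfg$sigma, cfg$mu, m0, u0, hsr0,
                               cfg$budget, cfg$reward_per_run, mode_int)

    if (learning) {
      returns <- compute_returns(out$rewards, gamma)
      policy <- reinforce_update(policy, out$X, out$actions, returns,
                                 as.logical(out$forced), buffer,
                                 lr = lr, optimizer = optimizer)
    }

    rewards_ep[ep] <- sum(out$rewards)
    notes_ep[ep] <- out$delivered
    if (ep %in% trace_episodes) {
      traces[[as.character(ep)]] <- data.frame(
        step = seq_len(n_steps),
        clock = env$step_hours,
        hour = env$weather$hour[rows],
        weekday = env$weather$weekday[rows],
        notification = out$notifications,
        memory = out$memory,
        urge = out$urge,
        action = out$runs,
        reward = out$rewards,
        desirability = env$desirability[rows],
        stringsAsFactors = FALSE
      )
    }
  }

  list(results = data.frame(episode = seq_len(episodes),
                            reward = rewards_ep,
                            notifications = notes_ep),
       policy = policy,
       traces = traces)
}

#' Run a multi-agent, multi-seed experiment
#'
#' For each seed (repetition), every agent is trained/evaluated against the
#' same environment initialization: equal environment seed, hence identical
#' start dates, weather, and user-decision draws. Agents differ only in
#' their own RNG streams and policies.
#'
#' @param agents character vector of agent modes.
#' @param episodes episodes per run.
#' @param cfg a [simulator_config()].
#' @param weather hourly weather stream.
#' @param cond,prior fitted context models.
#' @param seeds one integer seed per repetition.
#' @param switch_episode restriction-switch episode for B agents.
#' @param ... passed to [train_agent()] (`hidden`, `lr`, `gamma`,
#'   `baseline_window`, `trace_episodes`).
#' @return data frame `episode,agent,seed,reward,notifications`.
#' @export
run_training <- function(agents, episodes, cfg, weather, cond, prior,
                         seeds = 1:20, switch_episode = 15000, ...) {
  env <- notification_env(cfg, weather, cond, prior)
  out <- vector("list", length(seeds) * length(agents))
  i <- 0L
  for (seed in seeds) {
    for (agent in agents) {
      run <- train_agent(env, agent, episodes,
                         env_seed = seed,
                         agent_seed = seed * 131L + match(agent, agents) * 17L,
                         switch_episode = switch_episode, ...)
      df <- run$results
      df$agent <- agent
      df$seed <- seed
      i <- i + 1L
      out[[i]] <- df[, c("episode", "agent", "seed", "reward", "notifications")]
    }
  }
  do.call(rbind, out)
}

#' Exact optimal expected reward for one week's desirability sequence
#'
#' Solves the weekly notification-scheduling problem by backward induction.
#' Because the latent transitions are deterministic, the reachable states
#' are indexed by the number of hourly decay steps since the last
#' notification (memory is `sigma^j`), the hours since the last run (urge
#' is `min(1, mu * (h - 1))`), and the remaining budget, so the
#' finite-horizon MDP can be solved exactly. The initial cognitive state is
#' mapped to the nearest decay index (a relative error below 3% on a memory
#' value that is itself below 0.1).
#'
#' This is the planning upper bound used to separate "the environment has
#' no headroom" from "the learner has not found the headroom": no policy,
#' learned or rule-based, can exceed it in expectation.
#'
#' @param ratios desirability (likelihood ratio) at each of the week's
#'   decision points, in schedule order.
#' @param cfg a [simulator_config()].
#' @return the optimal expected number of runs for the week.
#' @export
dp_weekly_value <- function(ratios, cfg = simulator_config()) {
  sigma <- cfg$sigma
  mu <- cfg$mu
  B <- cfg$budget
  n <- length(ratios)
  stopifnot(n == steps_per_episode(cfg))
  gaps <- c(diff(rep(cfg$decision_hours, cfg$episode_days) +
                   24 * rep(seq_len(cfg$episode_days) - 1L,
                            each = length(cfg$decision_hours))), 0)
  Jmax <- 40L                      # memory below sigma^40 is numerically dead
  Hmax <- as.integer(ceiling(1 / mu)) + 1L   # urge saturates at h >= Hmax
  Vnext <- array(0, c(Jmax + 1, Hmax + 1, B + 1))
  for (t in n:1) {
    V <- array(-Inf, c(Jmax + 1, Hmax + 1, B + 1))
    g <- max(gaps[t], 1L)
    u <- pmin(1, mu * ((0:Hmax) - 1))
    u[1] <- 0                      # h = 0 only as a formal index
    for (j in 0:Jmax) {
      for (a in 0:1) {
        jp <- if (a == 1) 0L else min(j + 1L, Jmax)
        p <- pmin(1, ratios[t] * u * sigma^jp)
        if (t == n) {
          ev <- matrix(p, Hmax + 1, B + 1)
        } else {
          j_next <- min(jp + g - 1L, Jmax)
          h_run <- min(g, Hmax)
          h_no <- pmin((0:Hmax) + g, Hmax)
          v_run <- Vnext[j_next + 1, h_run + 1, ]          # over budgets
          v_no <- Vnext[j_next + 1, h_no + 1, , drop = FALSE]
          ev <- p * (1 + rep(v_run, each = Hmax + 1)) +
            (1 - p) * matrix(v_no, Hmax + 1, B + 1)
        }
        bs <- if (a == 1) seq_len(B) else 0:B
        for (b in bs) {
          cand <- ev[, b - a + 1]
          cur <- V[j + 1, , b + 1]
          V[j + 1, , b + 1] <- pmax(cur, cand)
        }
      }
    }
    Vnext <- V
  }
  h1 <- cfg$decision_hours[1]
  m0 <- cfg$initial_memory * sigma^(h1 - 1)     # memory entering step 1
  j0 <- max(0L, min(Jmax, as.integer(round(log(m0) / log(sigma)))))
  h0 <- min(Hmax, as.integer(round(cfg$initial_urge / mu)) + h1 + 1L)
  Vnext[j0 + 1, h0 + 1, B + 1]
}

#' Mean optimal weekly value over random episodes of an environment
#'
#' Draws episode start dates exactly as [env_reset()] does and averages the
#' [dp_weekly_value()] planning bound over them.
#'
#' @param env a [notification_env()].
#' @param rng a [rng_stream()].
#' @param weeks number of sampled weeks.
#' @return mean optimal expected reward per week.
#' @export
dp_optimal_mean <- function(env, rng, weeks = 30) {
  vals <- numeric(weeks)
  for (i in seq_len(weeks)) {
    env_reset(env, rng)
    ratios <- env$desirability[env$start_row + env$step_hours + 1]
    vals[i] <- dp_weekly_value(ratios, env$cfg)
  }
  mean(vals)
}

#' Trailing sliding-window average
#'
#' Mean of each trailing window of `window` values; defined from index
#' `window` onward (length `length(values) - window + 1`). Window means are
#' exactly recomputable from the raw per-episode values.
#'
#' @param values numeric sequence (e.g. per-episode rewards).
#' @param window window length (>= 1).
#' @return numeric vector of trailing means (empty if `window` exceeds the
#'   sequence length).
#' @export
sliding_window_average <- function(values, window) {
  stopifnot(window >= 1)
  n <- length(values)
  if (window > n) return(numeric(0))
  cs <- cumsum(c(0, values))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Window-mean learning curves for an experiment result
#'
#' @param results data frame from [run_training()].
#' @param window sliding-window length (default 500).
#' @return data frame `window_end,agent,seed,mean_reward`.
#' @export
learning_curves <- function(results, window = 500) {
  parts <- split(results, list(results$agent, results$seed), drop = TRUE)
  out <- lapply(parts, function(df) {
    df <- df[order(df$episode), ]
    wm <- sliding_window_average(df$reward, window)
    if (length(wm) == 0) return(NULL)
    data.frame(window_end = seq(window, nrow(df)),
               agent = df$agent[1], seed = df$seed[1],
               mean_reward = wm, stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Visualize one episode on the hour-by-weekday grid
#'
#' One mark per decision point: fill encodes the context desirability
#' (the step's likelihood ratio) binned into diverging color classes by
#' within-episode quantiles; a left tick marks a notification, a right tick
#' marks a run.
#'
#' @param trace an episode trace data frame
#'   (`step,clock,hour,weekday,notification,memory,urge,action,reward,desirability`).
#' @param quantile_bins number of desirability color classes (default 5).
#' @return list with `figure` (a ggplot) and `table` (the plotted data,
#'   including the assigned desirability bin).
#' @export
visualize_episode <- function(trace, quantile_bins = 5) {
  stopifnot(nrow(trace) > 0)
  qs <- stats::quantile(trace$desirability,
                        probs = seq(0, 1, length.out = quantile_bins + 1),
                        names = FALSE)
  qs <- unique(qs)
  if (length(qs) < 2) {
    bin <- rep((quantile_bins + 1) %/% 2, nrow(trace))
  } else {
    bin <- cut(trace$desirability, breaks = qs, include.lowest = TRUE,
               labels = FALSE)
    # map the collapsed bins onto 1..quantile_bins centered labels
    bin <- round(1 + (bin - 1) * (quantile_bins - 1) /
                   max(1, length(qs) - 2))
  }
  tab <- trace
  tab$desirability_bin <- as.integer(bin)
  tab$day <- (tab$clock %/% 24) + 1
  tab$weekday <- factor(tab$weekday, levels = .WEEKDAYS)

  fig <- ggplot2::ggplot(tab, ggplot2::aes(x = hour, y = day)) +
    ggplot2::geom_point(ggplot2::aes(fill = factor(desirability_bin)),
                        shape = 21, size = 6, color = "grey40") +
    ggplot2::geom_point(data = tab[tab$notification == 1, , drop = FALSE],
                        ggplot2::aes(x = hour - 0.22), shape = "|", size = 4) +
    ggplot2::geom_point(data = tab[tab$action == 1, , drop = FALSE],
                        ggplot2::aes(x = hour + 0.22), shape = "|", size = 4) +
    ggplot2::scale_fill_brewer(palette = "RdBu", direction = -1,
                               name = "desirability\n(quantile bin)") +
    ggplot2::scale_y_reverse(breaks = unique(tab$day),
                             labels = as.character(tab$weekday[!duplicated(tab$day)])) +
    ggplot2::labs(x = "hour of day", y = NULL,
                  title = "Episode decisions: | left = notification, | right = run") +
    ggplot2::theme_minimal()
  list(figure = fig, table = tab)
}

#' Write experiment results and provenance
#'
#' Writes `episodes.csv` (`episode,agent,seed,reward,notifications`),
#' `curves.csv` (`window_end,agent,seed,mean_reward`), and a `meta.json`
#' sidecar carrying the configuration and seeds.
#'
#' @param results data frame from [run_training()].
#' @param dir output directory (created if needed).
#' @param window sliding-window length.
#' @param meta named list of extra provenance fields.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(results, dir, window = 500, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results, file.path(dir, "episodes.csv"), row.names = FALSE)
  curves <- learning_curves(results, window)
  if (!is.null(curves)) {
    utils::write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE)
  }
  meta$window <- window
  meta$agents <- unique(results$agent)
  meta$seeds <- unique(results$seed)
  meta$episodes <- max(results$episode)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an episode trace CSV
#' @param trace episode trace data frame.
#' @param path output CSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[, c("step", "clock", "hour", "weekday",
                             "notification", "memory", "urge", "action",
                             "reward", "desirability")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an experiment YAML config
#'
#' Fields: `episodes`, `agents`, `seeds`, `window`, `switch_episode`, and a
#' `simulator` block passed to [simulator_config()].
#' @param path YAML file.
#' @return named list with a `simulator_config` in `$simulator`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read experiment configs")
  }
  raw <- yaml::read_yaml(path)
  sim <- do.call(simulator_config, as.list(raw$simulator))
  list(episodes = raw$episodes %||% 1000,
       agents = raw$agents %||% c("R", "random_week", "random_day", "fixed"),
       seeds = raw$seeds %||% 1:20,
       window = raw$window %||% 500,
       switch_episode = raw$switch_episode %||% 15000,
       simulator = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
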