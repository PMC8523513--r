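# Budget-restricted REINFORCE learner and rule-based baseline agents.
#
# The policy is a small feed-forward network (one hidden tanh layer, softmax
# over {no-send, send}) trained by Monte-Carlo policy gradient with a
# per-step baseline: the average return at each step position over the past
# n episodes. Restriction modes:
#   R — agent-side clipping: once the budget is spent, the send probability
#       is forced to 0 and those steps are excluded from the gradient;
#   C — environment-side suppression: the agent samples freely, the
#       environment drops deliveries beyond the budget;
#   B — unrestricted until a switch episode, then environment-side.

#' Initialize policy parameters
#'
#' One hidden layer of `hidden` tanh units and a softmax output over
#' {no-send, send}. Weights start small and random (scaled Gaussian) so the
#' initial policy is near-uniform.
#'
#' @param obs_dim observation dimensionality.
#' @param hidden hidden units (default 64).
#' @param rng a [rng_stream()] controlling initialization.
#' @return a `policy` object.
#' @export
policy_new <- function(obs_dim, hidden = 64, rng = rng_stream(1)) {
  w <- with_rng(rng, list(
    W1 = matrix(stats::rnorm(hidden * obs_dim, sd = 1 / sqrt(obs_dim)),
                hidden, obs_dim),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(2 * hidden, sd = 0.01), 2, hidden),
    b2 = numeric(2)
  ))
  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 obs_dim = obs_dim, hidden = hidden),
            class = "policy")
}

#' Action probabilities of the policy
#'
#' @param policy a [policy_new()] object.
#' @param X observation matrix (one row per observation) or a single
#'   observation vector.
#' @return matrix with columns `P(no-send)`, `P(send)`; rows sum to 1.
#' @export
policy_probs <- function(policy, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  H <- tanh(X %*% t(policy$W1) + rep(policy$b1, each = nrow(X)))
  logits <- H %*% t(policy$W2) + rep(policy$b2, each = nrow(X))
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m)
  e2 <- exp(logits[, 2] - m)
  cbind(e1 / (e1 + e2), e2 / (e1 + e2))
}

#' Sample a send/no-send action
#'
#' In R-mode with an exhausted budget the send probability is clipped to 0:
#' the action is forced to no-send and flagged so the gradient skips it.
#' In C- and B-modes the agent always samples freely; any suppression
#' happens inside the environment.
#'
#' @param policy a `policy`.
#' @param obs observation vector.
#' @param remaining_budget notifications still deliverable this episode.
#' @param mode one of `"R"`, `"C"`, `"B"`.
#' @param rng agent-side [rng_stream()].
#' @return list with `action` (0/1), `forced` (logical), and `p_send`.
#' @export
select_action <- function(policy, obs, remaining_budget, mode = "R",
                          rng = rng_stream(1)) {
  if (mode == "R" && remaining_budget <= 0) {
    return(list(action = 0L, forced = TRUE, p_send = 0))
  }
  p <- policy_probs(policy, obs)[1, 2]
  a <- with_rng(rng, as.integer(stats::runif(1) < p))
  list(action = a, forced = FALSE, p_send = p)
}

#' Discounted returns
#'
#' `G_t = sum_{k >= t} gamma^(k-t) r_k`.
#' @param rewards numeric reward sequence.
#' @param gamma discount factor (default 1).
#' @return numeric vector of returns, same length.
#' @export
compute_returns <- function(rewards, gamma = 1) {
  n <- length(rewards)
  g <- numeric(n)
  acc <- 0
  for (t in n:1) {
    acc <- rewards[t] + gamma * acc
    g[t] <- acc
  }
  g
}

#' Per-step return baseline over past episodes
#'
#' Ring buffer holding the returns of the most recent `window` episodes;
#' the baseline at step position t is the mean return at t over those
#' episodes (0 while the buffer is empty).
#'
#' @param n_steps steps per episode.
#' @param window episodes retained (default 50).
#' @return a `baseline_buffer`.
#' @export
baseline_buffer <- function(n_steps, window = 50) {
  e <- new.env(parent = emptyenv())
  e$returns <- matrix(0, nrow = window, ncol = n_steps)
  e$count <- 0L
  e$window <- window
  class(e) <- "baseline_buffer"
  e
}

#' Baseline values per step position
#' @param buffer a [baseline_buffer()].
#' @return numeric vector of per-step mean returns (zeros when empty).
#' @export
baseline_values <- function(buffer) {
  k <- min(buffer$count, buffer$window)
  if (k == 0L) return(numeric(ncol(buffer$returns)))
  colSums(buffer$returns[seq_len(min(buffer$window, buffer$count)), , drop = FALSE]) / k
}

#' Push an episode's returns into the baseline buffer
#' @param buffer a [baseline_buffer()].
#' @param returns this episode's per-step returns.
#' @export
baseline_push <- function(buffer, returns) {
  slot <- (buffer$count %% buffer$window) + 1L
  buffer$returns[slot, ] <- returns
  buffer$count <- buffer$count + 1L
  invisible(buffer)
}

#' Policy-gradient loss gradient for one episode
#'
#' Gradient of `sum_t 1[not forced_t] log pi(a_t | x_t) * adv_t` with respect
#' to the policy parameters, computed in one batched backward pass.
#'
#' @param policy a `policy`.
#' @param X observation matrix (steps x obs_dim).
#' @param actions 0/1 vector of sampled actions.
#' @param advantages per-step advantages `G_t - baseline_t`.
#' @param forced logical vector; forced steps contribute zero gradient.
#' @return list of gradients `W1`, `b1`, `W2`, `b2`.
#' @export
policy_gradient <- function(policy, X, actions, advantages, forced) {
  H <- tanh(X %*% t(policy$W1) + rep(policy$b1, each = nrow(X)))
  logits <- H %*% t(policy$W2) + rep(policy$b2, each = nrow(X))
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m)
  e2 <- exp(logits[, 2] - m)
  P <- cbind(e1 / (e1 + e2), e2 / (e1 + e2))
  onehot <- unname(cbind(1 - actions, actions))
  w <- advantages * !forced
  dlogits <- (onehot - P) * w           # d loss / d logits, row-weighted
  gW2 <- t(dlogits) %*% H
  gb2 <- colSums(dlogits)
  dH <- dlogits %*% policy$W2
  dZ <- dH * (1 - H * H)
  gW1 <- t(dZ) %*% X
  gb1 <- colSums(dZ)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' One REINFORCE-with-baseline update
#'
#' Performs a single gradient-ascent step
#' `theta <- theta + alpha * sum_t grad log pi(a_t|x_t) (G_t - Gbar_t)` over
#' the episode's non-forced steps, then pushes this episode's returns into
#' the baseline buffer.
#'
#' @param policy a `policy`.
#' @param X,actions,forced episode data as collected during rollout.
#' @param returns per-step returns `G_t`.
#' @param buffer a [baseline_buffer()] (mutated).
#' @param lr learning rate alpha (default 0.001).
#' @param optimizer `"sgd"` (plain gradient ascent, the default) or
#'   `"adam"` (adaptive moments; state kept on the policy object).
#' @return the updated `policy`.
#' @export
reinforce_update <- function(policy, X, actions, returns, forced,
                             buffer, lr = 0.001, optimizer = "sgd") {
  adv <- returns - baseline_values(buffer)
  g <- policy_gradient(policy, X, actions, adv, forced)
  if (!all(vapply(g, function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite policy gradient (advantage range: ",
         paste(signif(range(adv), 4), collapse = " .. "), ")")
  }
  pars <- c("W1", "b1", "W2", "b2")
  if (optimizer == "sgd") {
    for (p in pars) policy[[p]] <- policy[[p]] + lr * g[[p]]
  } else if (optimizer == "adam") {
    b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
    if (is.null(policy$opt)) {
      policy$opt <- list(t = 0,
                         m = lapply(g, function(x) x * 0),
                         v = lapply(g, function(x) x * 0))
    }
    policy$opt$t <- policy$opt$t + 1
    t <- policy$opt$t
    for (p in pars) {
      policy$opt$m[[p]] <- b1m * policy$opt$m[[p]] + (1 - b1m) * g[[p]]
      policy$opt$v[[p]] <- b2m * policy$opt$v[[p]] + (1 - b2m) * g[[p]]^2
      mhat <- policy$opt$m[[p]] / (1 - b1m^t)
      vhat <- policy$opt$v[[p]] / (1 - b2m^t)
      policy[[p]] <- policy[[p]] + lr * mhat / (sqrt(vhat) + eps)
    }
  } else {
    stop("unknown optimizer: ", optimizer)
  }
  baseline_push(buffer, returns)
  policy
}

#' Save a policy checkpoint to a single portable JSON file
#'
#' Stores the network weights, the architecture, and (if present) the
#' optimizer state, so training can resume or a trained policy can be
#' shipped alongside experiment outputs.
#'
#' @param policy a `policy`.
#' @param path file path to write.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "policy"))
  obj <- list(obs_dim = policy$obs_dim, hidden = policy$hidden,
              W1 = as.vector(policy$W1), b1 = policy$b1,
              W2 = as.vector(policy$W2), b2 = policy$b2)
  if (!is.null(policy$opt)) {
    obj$opt <- list(t = policy$opt$t,
                    m = lapply(policy$opt$m, as.vector),
                    v = lapply(policy$opt$v, as.vector))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a policy checkpoint written by [write_policy()]
#' @param path file path.
#' @return a `policy`.
#' @export
read_policy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pol <- structure(
    list(W1 = matrix(obj$W1, obj$hidden, obj$obs_dim),
         b1 = as.numeric(obj$b1),
         W2 = matrix(obj$W2, 2, obj$hidden),
         b2 = as.numeric(obj$b2),
         obs_dim = obj$obs_dim, hidden = obj$hidden),
    class = "policy")
  if (!is.null(obj$opt)) {
    pol$opt <- list(
      t = obj$opt$t,
      m = list(W1 = matrix(obj$opt$m$W1, obj$hidden, obj$obs_dim),
               b1 = as.numeric(obj$opt$m$b1),
               W2 = matrix(obj$opt$m$W2, 2, obj$hidden),
               b2 = as.numeric(obj$opt$m$b2)),
      v = list(W1 = matrix(obj$opt$v$W1, obj$hidden, obj$obs_dim),
               b1 = as.numeric(obj$opt$v$b1),
               W2 = matrix(obj$opt$v$W2, 2, obj$hidden),
               b2 = as.numeric(obj$opt$v$b2)))
  }
  pol
}

#' Rule-based baseline agents
#'
#' Context-blind notification schedules matched to the weekly budget:
#' `random_week` picks `budget` of the episode's decision steps uniformly
#' without replacement; `random_day` picks 2 distinct decision steps per
#' day; `fixed` sends at 12:00 and 16:00 every day.
#'
#' @param kind one of `"random_week"`, `"random_day"`, `"fixed"`.
#' @param cfg a [simulator_config()].
#' @return an object with a `$schedule(rng)` function returning a 0/1 vector
#'   over the episode's decision steps.
#' @export
make_baseline_agent <- function(kind, cfg) {
  n_hours <- length(cfg$decision_hours)
  n_steps <- steps_per_episode(cfg)
  schedule <- switch(
    kind,
    random_week = function(rng) {
      s <- integer(n_steps)
      idx <- with_rng(rng, sample.int(n_steps, min(cfg$budget, n_steps)))
      s[idx] <- 1L
      s
    },
    random_day = function(rng) {
      s <- integer(n_steps)
      for (d in seq_len(cfg$episode_days)) {
        idx <- with_rng(rng, sample.int(n_hours, 2L)) + (d - 1L) * n_hours
        s[idx] <- 1L
      }
      s
    },
    fixed = function(rng) {
      hit <- cfg$decision_hours %in% c(12L, 16L)
      rep(as.integer(hit), cfg$episode_days)
    },
    stop("unknown baseline agent kind: ", kind)
  )
  structure(list(kind = kind, schedule = schedule), class = "baseline_agent")
}
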