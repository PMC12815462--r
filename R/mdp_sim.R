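# Simulator of the M-step decision task with episode-wise drifting
# state-action transition probabilities and terminal Bernoulli reward.
#
# Decision states form a full binary tree: step m has 2^(m-1) nodes, node j of
# step m leads (for either action) to child 2j or 2j+1 of step m+1.  The cue
# shown to the decision maker is the node's parity (j mod 2), so each step
# presents one of two cues and the cue sequence identifies the node path
# (node' = 2*node + cue').  Every transition entry holds a probability pair
# from {(0.8,0.2), (0.2,0.8), (0.6,0.4), (0.4,0.6)}, stored as p1 =
# P(odd child); final-step entries hold the same pairs as P(reward = 1).

#' Initialize a drifting MDP environment
#'
#' Every state-action entry (transition and terminal reward) is assigned a
#' probability pair uniformly at random from the allowed set.
#'
#' @param M steps per episode (2 or 3).
#' @param p_trans per-episode drift probability in `[0, 1]`.
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   environment is reproducible. Otherwise the current RNG state is used.
#' @return an object of class `mdp_env` with elements `M`, `p_trans`,
#'   `trans` (list over steps `1..M-1` of `nodes x 2` matrices of p1 values)
#'   and `reward` (`2^(M-1) x 2` matrix of reward probabilities).
#' @export
init_environment <- function(M, p_trans = 0.2, seed = NULL) {
  if (!M %in% c(2L, 3L)) stop_eidt("unsupported number of steps: ", M)
  if (!is.numeric(p_trans) || p_trans < 0 || p_trans > 1)
    stop_eidt("p_trans must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  rnd <- function(n) sample(ALLOWED_P1, n, replace = TRUE)
  trans <- lapply(seq_len(M - 1), function(m)
    matrix(rnd(2^(m - 1) * 2), nrow = 2^(m - 1), ncol = 2))
  reward <- matrix(rnd(2^(M - 1) * 2), nrow = 2^(M - 1), ncol = 2)
  structure(list(M = as.integer(M), p_trans = p_trans,
                 trans = trans, reward = reward),
            class = "mdp_env")
}

#' @export
print.mdp_env <- function(x, ...) {
  cat(sprintf("<mdp_env> M=%d, p_trans=%g, %d state-action entries\n",
              x$M, x$p_trans, n_env_entries(x$M)))
  invisible(x)
}

#' Enumerate the state-action entries of an environment
#'
#' @param env an `mdp_env`.
#' @return data.frame with columns `kind` ("trans"/"reward"), `step`, `node`,
#'   `action`, `p1`, in the fixed enumeration order used for drift.
#' @export
env_entry_table <- function(env) {
  rows <- list()
  for (m in seq_len(env$M - 1))
    for (j in seq_len(2^(m - 1)) - 1L)
      for (a in 0:1)
        rows[[length(rows) + 1L]] <-
          data.frame(kind = "trans", step = m, node = j, action = a,
                     p1 = env$trans[[m]][j + 1, a + 1])
  for (j in seq_len(2^(env$M - 1)) - 1L)
    for (a in 0:1)
      rows[[length(rows) + 1L]] <-
        data.frame(kind = "reward", step = env$M, node = j, action = a,
                   p1 = env$reward[j + 1, a + 1])
  do.call(rbind, rows)
}

# Rebuild an environment from an entry table (inverse of env_entry_table).
# Does not touch the RNG.
env_from_entries <- function(entries, M, p_trans = 0.2) {
  env <- structure(list(M = as.integer(M), p_trans = p_trans,
                        trans = lapply(seq_len(M - 1), function(m)
                          matrix(NA_real_, nrow = 2^(m - 1), ncol = 2)),
                        reward = matrix(NA_real_, nrow = 2^(M - 1), ncol = 2)),
                   class = "mdp_env")
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    if (e$kind == "trans") env$trans[[e$step]][e$node + 1, e$action + 1] <- e$p1
    else env$reward[e$node + 1, e$action + 1] <- e$p1
  }
  env
}

#' Apply one drift step to an environment
#'
#' With probability `p_trans`, exactly one state-action entry (chosen
#' uniformly among all transition and terminal-reward entries) is reassigned
#' a pair drawn uniformly from the allowed set; otherwise the environment is
#' returned unchanged.  Applied once at the start of each episode by
#' [run_block()].
#'
#' @param env an `mdp_env`.
#' @return the (possibly updated) environment. The attribute `"last_event"`
#'   holds a one-row data.frame describing the reassignment, or `NULL` if no
#'   drift occurred this call.
#' @export
drift <- function(env) {
  attr(env, "last_event") <- NULL
  if (runif(1) < env$p_trans) {
    n <- n_env_entries(env$M)
    idx <- sample.int(n, 1)
    entries <- env_entry_table(env)
    e <- entries[idx, ]
    newp <- sample(ALLOWED_P1, 1)
    if (e$kind == "trans") env$trans[[e$step]][e$node + 1, e$action + 1] <- newp
    else env$reward[e$node + 1, e$action + 1] <- newp
    e$p1 <- newp
    attr(env, "last_event") <- e
  }
  env
}

#' Action with the larger terminal reward probability
#'
#' @param env an `mdp_env` (as in force at the episode of interest; see
#'   [env_at_episode()]).
#' @param final_node 0-based node index at the final step.
#' @return action code (0 = C1, 1 = C2); ties broken by the lower index
#'   (impossible with the allowed pair set).
#' @export
highly_rewarding_action <- function(env, final_node) {
  p <- env$reward[final_node + 1, ]
  which.max(p) - 1L
}

#' Run a single episode
#'
#' @param env an `mdp_env`.
#' @param policy function `(step, cue) -> length-2 probability vector` over
#'   actions (C1, C2).
#' @return an `episode_trace`: list with `steps` (data.frame `step, node, cue,
#'   action`) and `reward` (0/1).
#' @export
run_episode <- function(env, policy) {
  node <- 0L
  steps <- data.frame(step = integer(env$M), node = integer(env$M),
                      cue = integer(env$M), action = integer(env$M))
  for (m in seq_len(env$M)) {
    cue <- node %% 2L
    pr <- policy(m, cue)
    if (length(pr) != 2 || any(!is.finite(pr)) || any(pr < 0) ||
        abs(sum(pr) - 1) > 1e-8)
      stop_eidt("policy returned an invalid probability vector")
    a <- if (runif(1) < pr[2]) 1L else 0L
    steps[m, ] <- list(m, node, cue, a)
    if (m < env$M) {
      p1 <- env$trans[[m]][node + 1, a + 1]
      node <- 2L * node + (runif(1) < p1)
    } else {
      p1 <- env$reward[node + 1, a + 1]
      reward <- as.integer(runif(1) < p1)
    }
  }
  structure(list(steps = steps, reward = reward), class = "episode_trace")
}

# Stateful-agent interface used by the simulators: a list of closures
#   reset()                                  - called at block start
#   choose(step, cue) -> action (0/1)        - samples an action
#   learn(step, cue, action, reward, next_step, next_cue) - observe outcome
#     (reward is 0 on intermediate steps; next_* are NA at episode end)
run_block_agent <- function(env, agent, n_episodes = 50) {
  agent$reset()
  L <- env$M * n_episodes
  trials <- data.frame(episode = rep(seq_len(n_episodes) - 1L, each = env$M),
                       step = rep(seq_len(env$M), n_episodes),
                       cue = integer(L), action = integer(L),
                       reward = NA_integer_, rt = NA_real_)
  events <- list()
  env_init <- NULL
  row <- 1L
  for (ep in seq_len(n_episodes) - 1L) {
    env <- drift(env)
    if (ep == 0L) env_init <- env_entry_table(env)
    else if (!is.null(attr(env, "last_event")))
      events[[length(events) + 1L]] <- cbind(episode = ep, attr(env, "last_event"))
    node <- 0L
    path <- integer(env$M); acts <- integer(env$M); cues <- integer(env$M)
    for (m in seq_len(env$M)) {
      cue <- node %% 2L
      a <- agent$choose(m, cue)
      path[m] <- node; cues[m] <- cue; acts[m] <- a
      if (m < env$M) {
        p1 <- env$trans[[m]][node + 1, a + 1]
        node <- 2L * node + (runif(1) < p1)
      }
    }
    r <- as.integer(runif(1) < env$reward[path[env$M] + 1, acts[env$M] + 1])
    for (m in seq_len(env$M)) {
      agent$learn(m, cues[m], acts[m], if (m == env$M) r else 0L,
                  if (m < env$M) m + 1L else NA_integer_,
                  if (m < env$M) cues[m + 1] else NA_integer_)
      trials$cue[row] <- cues[m]; trials$action[row] <- acts[m]
      if (m == env$M) trials$reward[row] <- r
      row <- row + 1L
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(episode = integer(), kind = character(),
                        step = integer(), node = integer(), action = integer(),
                        p1 = numeric())
  rownames(ev) <- NULL
  structure(list(condition = NULL, M = env$M, trials = trials,
                 env_init = env_init, env_events = ev),
            class = "block_record")
}

#' Run a block of episodes under a fixed stochastic policy
#'
#' Drift is applied once before each episode (including the first; the
#' episode-0 table is logged after that drift).
#'
#' @inheritParams run_episode
#' @param n_episodes number of episodes (default 50).
#' @param condition optional condition label stored on the block.
#' @return a `block_record` with `M * n_episodes` trials and the environment
#'   trace (`env_init`, `env_events`).
#' @export
run_block <- function(env, policy, n_episodes = 50, condition = NULL) {
  if (n_episodes < 1) stop_eidt("n_episodes must be >= 1")
  agent <- list(reset = function() NULL,
                choose = function(step, cue) {
                  pr <- policy(step, cue)
                  if (length(pr) != 2 || any(!is.finite(pr)) || any(pr < 0) ||
                      abs(sum(pr) - 1) > 1e-8)
                    stop_eidt("policy returned an invalid probability vector")
                  if (runif(1) < pr[2]) 1L else 0L
                },
                learn = function(...) NULL)
  blk <- run_block_agent(env, agent, n_episodes)
  blk$condition <- condition
  blk
}

#' Environment in force at a given episode of a logged block
#'
#' Reconstructs the entry table from the block's logged initial table and the
#' drift events with episode index `<= episode`.
#'
#' @param block a `block_record` with an environment trace.
#' @param episode 0-based episode index.
#' @param p_trans drift probability recorded on the returned environment.
#' @return an `mdp_env`.
#' @export
env_at_episode <- function(block, episode, p_trans = 0.2) {
  entries <- block$env_init
  ev <- block$env_events
  if (nrow(ev)) {
    ev <- ev[ev$episode <= episode, , drop = FALSE]
    entries <- rbind(entries, ev[, c("kind", "step", "node", "action", "p1")])
  }
  env_from_entries(entries, block$M, p_trans)
}

# Node path of each episode, reconstructed from the logged cues
# (root node 0; node' = 2*node + cue').  Returns the trials data.frame with a
# `node` column appended.
block_node_path <- function(block) {
  tr <- block$trials
  node <- integer(nrow(tr))
  cur <- 0L
  for (i in seq_len(nrow(tr))) {
    if (tr$step[i] == 1L) cur <- 0L
    else cur <- 2L * cur + tr$cue[i]
    node[i] <- cur
  }
  tr$node <- node
  tr
}
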