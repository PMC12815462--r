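# The Q-learning cognitive model: softmax policy over tabular Q-values,
# one-step value update, behavior simulation, trial-wise likelihood, and
# maximum-likelihood parameter fitting (the individual and pool-average
# baselines).
#
# The model's state is the observation (step m, cue c); an M-step condition
# has 1 + 2*(M-1) such states (the first step always shows cue 0).

#' Cognitive-model parameter vector
#'
#' @param q_lr learning rate in (0, 1).
#' @param q_dr discount rate in (0, 1).
#' @param q_it inverse temperature (> 0); softmax sharpness.
#' @param q_init initial Q-value.
#' @return named numeric of class `qparams`.
#' @export
qparams <- function(q_lr, q_dr, q_it, q_init = 0) {
  if (!is.finite(q_lr) || q_lr <= 0 || q_lr >= 1) stop_eidt("q_lr must be in (0,1)")
  if (!is.finite(q_dr) || q_dr <= 0 || q_dr >= 1) stop_eidt("q_dr must be in (0,1)")
  if (!is.finite(q_it) || q_it <= 0) stop_eidt("q_it must be positive")
  if (!is.finite(q_init)) stop_eidt("q_init must be finite")
  structure(c(q_lr = q_lr, q_dr = q_dr, q_it = q_it, q_init = q_init),
            class = "qparams")
}

# observation-state index (0-based) for C++ kernels
q_state_index <- function(M, step, cue) {
  ifelse(step == 1L, 0L, 1L + 2L * (step - 2L) + cue)
}

n_q_states <- function(M) 1L + 2L * (M - 1L)

#' Fresh Q-table for an M-step condition
#'
#' @param M number of steps.
#' @param q_init initial value for every entry.
#' @return a `2 x n_states` matrix (rows = actions C1, C2; columns =
#'   observation states in `(step, cue)` order), class `qtable` with
#'   attribute `M`.
#' @export
new_qtable <- function(M, q_init = 0) {
  qt <- matrix(q_init, nrow = 2, ncol = n_q_states(M))
  structure(qt, class = "qtable", M = as.integer(M))
}

#' Softmax action probabilities from a Q-table
#'
#' @param qtable a `qtable`.
#' @param state `c(step, cue)`.
#' @param q_it inverse temperature (> 0).
#' @return length-2 probability vector over actions (C1, C2).
#' @export
action_probs <- function(qtable, state, q_it) {
  if (q_it <= 0) stop_eidt("q_it must be positive")
  M <- attr(qtable, "M")
  if (state[1] < 1 || state[1] > M || !state[2] %in% c(0, 1))
    stop_eidt("state not in table")
  v <- q_it * qtable[, q_state_index(M, state[1], state[2]) + 1]
  e <- exp(v - max(v))
  e / sum(e)
}

#' One Q-value update
#'
#' `Q(s,a) <- (1 - q_lr) Q(s,a) + q_lr (r + q_dr * max_a' Q(s',a'))`; for a
#' terminal transition (`s_next = NULL`) the bootstrap term is 0.
#'
#' @param qtable a `qtable`.
#' @param s state `c(step, cue)`; @param a action 0/1; @param r reward;
#' @param s_next next state or `NULL` at episode end.
#' @param params a `qparams`.
#' @return the updated `qtable` (only the `(s, a)` entry changes).
#' @export
update_q <- function(qtable, s, a, r, s_next, params) {
  M <- attr(qtable, "M")
  i <- q_state_index(M, s[1], s[2]) + 1
  boot <- if (is.null(s_next)) 0
          else params[["q_dr"]] * max(qtable[, q_state_index(M, s_next[1], s_next[2]) + 1])
  qtable[a + 1, i] <- (1 - params[["q_lr"]]) * qtable[a + 1, i] +
    params[["q_lr"]] * (r + boot)
  qtable
}

# stateful agent (run_block_agent interface) wrapping the Q model
q_agent <- function(params, M) {
  qt <- NULL
  list(
    reset = function() qt <<- new_qtable(M, params[["q_init"]]),
    choose = function(step, cue) {
      pr <- action_probs(qt, c(step, cue), params[["q_it"]])
      if (runif(1) < pr[2]) 1L else 0L
    },
    learn = function(step, cue, action, reward, next_step, next_cue) {
      s_next <- if (is.na(next_step)) NULL else c(next_step, next_cue)
      qt <<- update_q(qt, c(step, cue), action, reward, s_next, params)
    })
}

#' Default task configuration for the value-guided experiment
#'
#' Three 50-episode blocks per condition for the 2-step and 3-step
#' conditions, drift probability 0.2 per episode.
#'
#' @param conditions named integer vector (label -> M).
#' @param p_trans per-episode drift probability.
#' @param episodes_per_block episodes per block.
#' @return list used by [simulate_agent()] and [build_mdp_dataset()].
#' @export
mdp_task_config <- function(conditions = c("2step" = 2L, "3step" = 3L),
                            p_trans = 0.2, episodes_per_block = 50L) {
  list(conditions = conditions, p_trans = p_trans,
       episodes_per_block = as.integer(episodes_per_block))
}

#' Simulate a Q-learning agent on the full task protocol
#'
#' The agent plays `n_blocks` blocks per condition on freshly initialized
#' drifting environments; Q-values carry across episodes within a block and
#' reset to `q_init` at each block start.
#'
#' @param params a `qparams`.
#' @param task_config see [mdp_task_config()].
#' @param n_blocks blocks per condition.
#' @param seed optional integer seed.
#' @param participant_id id stored on the record.
#' @return an `individual_record` whose blocks carry full environment traces.
#' @export
simulate_agent <- function(params, task_config = mdp_task_config(),
                           n_blocks = 3, seed = NULL, participant_id = "agent") {
  force(params); force(task_config)  # before seeding: arguments may draw
  if (!is.null(seed)) set.seed(seed)
  blocks <- list()
  for (cond in names(task_config$conditions)) {
    M <- task_config$conditions[[cond]]
    for (b in seq_len(n_blocks)) {
      env <- init_environment(M, task_config$p_trans)
      blk <- run_block_agent(env, q_agent(params, M),
                             task_config$episodes_per_block)
      blk$condition <- cond
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  structure(list(participant_id = participant_id, blocks = blocks),
            class = "individual_record")
}

# Flatten an individual's blocks of one condition into replay vectors for
# the C++ kernel: observation-state index, next-state index (-1 terminal),
# action, reward (0 on intermediate steps), block starts.
q_replay_vectors <- function(record, condition) {
  blocks <- Filter(function(b) identical(b$condition, condition), record$blocks)
  if (!length(blocks)) stop_eidt("record has no blocks of condition ", condition)
  svec <- integer(); nxt <- integer(); avec <- integer(); rvec <- numeric()
  starts <- integer()
  for (blk in blocks) {
    tr <- blk$trials
    M <- blk$M
    starts <- c(starts, length(svec))
    s <- q_state_index(M, tr$step, tr$cue)
    nx <- c(s[-1], -1L)
    nx[tr$step == M] <- -1L
    r <- ifelse(is.na(tr$reward), 0, tr$reward)
    svec <- c(svec, s); nxt <- c(nxt, nx); avec <- c(avec, tr$action)
    rvec <- c(rvec, r)
  }
  list(svec = svec, nxt = nxt, avec = avec, rvec = rvec, starts = starts,
       n_states = n_q_states(blocks[[1]]$M))
}

#' Trial-wise negative log-likelihood of the cognitive model
#'
#' Replays the logged trials: at each trial the policy probability of the
#' logged action is scored (before the Q update from that trial's outcome).
#' The Q-table resets to `q_init` at each block start.
#'
#' @param params a `qparams`.
#' @param record an `individual_record`.
#' @param condition condition label to replay.
#' @return mean NLL per trial, with attribute `"probs"` (the `L x 2` matrix
#'   of policy probabilities).
#' @export
negloglik <- function(params, record, condition) {
  rv <- q_replay_vectors(record, condition)
  P <- t(cpp_q_replay(as.numeric(params[c("q_lr", "q_dr", "q_it", "q_init")]),
                      rv$n_states, rv$svec, rv$nxt, rv$avec, rv$rvec, rv$starts))
  p_act <- P[cbind(seq_along(rv$avec), rv$avec + 1L)]
  structure(mean(-log(p_act)), probs = P)
}

q_bounds <- list(q_lr = c(1e-3, 1 - 1e-3), q_dr = c(1e-3, 1 - 1e-3),
                 q_it = c(1e-3, 50), q_init = c(-5, 5))

q_to_unconstrained <- function(p) {
  vapply(names(q_bounds), function(k) {
    b <- q_bounds[[k]]
    qlogis((p[[k]] - b[1]) / (b[2] - b[1]))
  }, 0)
}

q_from_unconstrained <- function(u) {
  p <- vapply(seq_along(q_bounds), function(i) {
    b <- q_bounds[[i]]
    b[1] + (b[2] - b[1]) * plogis(u[i])
  }, 0)
  names(p) <- names(q_bounds)
  p
}

#' Maximum-likelihood fit of the cognitive model to one individual
#'
#' All blocks of the source condition are pooled.  Parameters are optimized
#' in an unconstrained space (scaled logistic transform of the bounded box),
#' by BFGS from multiple random starts with fixed seeds; the best start wins.
#'
#' @param record an `individual_record`.
#' @param condition condition to fit.
#' @param n_starts number of random restarts (default 10).
#' @param seed seed controlling the restart draws.
#' @return a `qparams` with attributes `nll` (mean per-trial NLL at the
#'   optimum) and `convergence`.
#' @export
fit_params <- function(record, condition, n_starts = 10, seed = 1) {
  rv <- q_replay_vectors(record, condition)
  obj <- function(u) {
    p <- q_from_unconstrained(u)
    P <- cpp_q_replay(p, rv$n_states, rv$svec, rv$nxt, rv$avec, rv$rvec, rv$starts)
    -mean(log(P[cbind(rv$avec + 1L, seq_along(rv$avec))]))
  }
  set.seed(seed)
  starts <- replicate(n_starts, rnorm(4, 0, 1), simplify = FALSE)
  starts[[1]] <- q_to_unconstrained(list(q_lr = 0.3, q_dr = 0.7, q_it = 3, q_init = 0))
  best <- NULL
  errors <- character()
  for (u0 in starts) {
    fit <- tryCatch(optim(u0, obj, method = "BFGS", control = list(maxit = 300)),
                    error = function(e) e)
    if (inherits(fit, "error")) { errors <- c(errors, conditionMessage(fit)); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_eidt("all optimizer starts failed: ", paste(unique(errors), collapse = "; "))
  p <- q_from_unconstrained(best$par)
  out <- qparams(p[["q_lr"]], p[["q_dr"]], p[["q_it"]], p[["q_init"]])
  attr(out, "nll") <- best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Element-wise average of fitted parameter vectors
#'
#' The pool-average cognitive model baseline.
#'
#' @param fits non-empty list of `qparams`.
#' @return a `qparams` (means stay inside the parameter box).
#' @export
average_params <- function(fits) {
  if (!length(fits)) stop_eidt("empty list of fits")
  m <- rowMeans(vapply(fits, function(p)
    as.numeric(p[c("q_lr", "q_dr", "q_it", "q_init")]), numeric(4)))
  qparams(m[1], m[2], m[3], m[4])
}
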