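# GRU task solver for the value-guided task: input encoding, teacher-forced
# likelihood prediction, on-policy action generation, and the
# within-condition baseline trainer.
#
# Step inputs are 1-of-K codes, concatenated in the fixed layout
#   [prev step (3) | prev cue (2) | prev action (2) | prev reward (2) |
#    current step (3) | current cue (2)]                      (length 14)
# with all "previous" fields zero at the first trial of a block.  The
# intermediate-step reward is an explicit r = 0 code.

MDP_INPUT_LEN <- 14L

#' Task-solver architecture descriptor
#'
#' @param M steps per episode (2 or 3); the GRU has 4 cells for the 2-step
#'   condition and 8 for the 3-step condition.
#' @return list `(M, I, Q, K, n_weights)` of class `solver_arch`.
#' @export
solver_arch <- function(M) {
  if (!M %in% c(2L, 3L)) stop_eidt("unsupported number of steps: ", M)
  Q <- if (M == 2) 4L else 8L
  structure(list(M = as.integer(M), I = MDP_INPUT_LEN, Q = Q, K = 2L,
                 n_weights = cpp_solver_npar(MDP_INPUT_LEN, Q, 2L)),
            class = "solver_arch")
}

#' Evidence-accumulator architecture for the perceptual task
#'
#' @param K number of classes (10 digits).
#' @param Q GRU cells (4).
#' @param S evidence samples per stimulus (16).
#' @return list of class `solver_arch`.
#' @export
accumulator_arch <- function(K = 10L, Q = 4L, S = 16L) {
  structure(list(M = NA_integer_, I = as.integer(K), Q = as.integer(Q),
                 K = as.integer(K), S = as.integer(S),
                 n_weights = cpp_solver_npar(K, Q, K)),
            class = "solver_arch")
}

#' Bundle a flat weight vector with its architecture
#'
#' @param theta numeric vector of length `arch$n_weights` (packed
#'   column-major: GRU input/recurrent/bias blocks, then the `K x Q` readout).
#' @param arch a `solver_arch`.
#' @return object of class `solver_weights`.
#' @export
solver_weights <- function(theta, arch) {
  if (length(theta) != arch$n_weights)
    stop_eidt("expected ", arch$n_weights, " weights, got ", length(theta))
  if (any(!is.finite(theta))) stop_eidt("solver weights must be finite")
  structure(list(theta = as.numeric(theta), arch = arch),
            class = "solver_weights")
}

#' Random solver initialization (uniform +/- 1/sqrt(fan-in), zero biases)
#' @param arch a `solver_arch`; @param seed optional seed.
#' @return a `solver_weights`.
#' @export
init_solver_weights <- function(arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  I <- arch$I; Q <- arch$Q; K <- arch$K
  theta <- c(runif_fan(3 * Q * I, I), runif_fan(3 * Q * Q, Q),
             numeric(3 * Q), runif_fan(K * Q, Q))
  solver_weights(theta, arch)
}

# unpack the flat vector into matrices (R mirror of the C++ layout), used by
# the incremental on-policy stepper
unpack_solver <- function(w) {
  I <- w$arch$I; Q <- w$arch$Q; K <- w$arch$K
  th <- w$theta
  off <- 0
  take <- function(n, nr, nc) {
    m <- matrix(th[(off + 1):(off + n)], nr, nc)
    off <<- off + n
    m
  }
  list(Wz = take(Q * I, Q, I), Wr = take(Q * I, Q, I), Wc = take(Q * I, Q, I),
       Uz = take(Q * Q, Q, Q), Ur = take(Q * Q, Q, Q), Uc = take(Q * Q, Q, Q),
       bz = drop(take(Q, Q, 1)), br = drop(take(Q, Q, 1)), bc = drop(take(Q, Q, 1)),
       Wout = take(K * Q, K, Q))
}

gru_step_r <- function(p, x, h) {
  u <- plogis(drop(p$Wz %*% x + p$Uz %*% h) + p$bz)
  r <- plogis(drop(p$Wr %*% x + p$Ur %*% h) + p$br)
  cd <- tanh(drop(p$Wc %*% x + p$Uc %*% (r * h)) + p$bc)
  (1 - u) * h + u * cd
}

#' Encode one solver input step
#'
#' @param prev_state `c(step, cue)` of the previous trial, or `NULL` at the
#'   first trial of a block (all "previous" fields become zero vectors).
#' @param prev_action,prev_reward previous action / reward codes (ignored
#'   when `prev_state` is `NULL`).
#' @param cur_state `c(step, cue)` of the current trial.
#' @return numeric vector of length 14.
#' @export
encode_step_input <- function(prev_state, prev_action, prev_reward, cur_state) {
  chk <- function(s) {
    if (!(s[1] %in% 1:3) || !(s[2] %in% 0:1)) stop_eidt("invalid task state")
  }
  chk(cur_state)
  if (is.null(prev_state)) {
    prev <- numeric(9)
  } else {
    chk(prev_state)
    if (!prev_action %in% 0:1) stop_eidt("invalid action code")
    if (!prev_reward %in% 0:1) stop_eidt("invalid reward code")
    prev <- c(one_hot(prev_state[1] - 1, 3), one_hot(prev_state[2], 2),
              one_hot(prev_action, 2), one_hot(prev_reward, 2))
  }
  c(prev, one_hot(cur_state[1] - 1, 3), one_hot(cur_state[2], 2))
}

# Build the full I x L input matrix and the action vector for a logged block.
# Vectorized; the intermediate-step previous reward is the r = 0 code.
solver_inputs <- function(block) {
  tr <- block$trials
  L <- nrow(tr)
  X <- matrix(0, MDP_INPUT_LEN, L)
  X[cbind(9L + tr$step, seq_len(L))] <- 1         # current step one-hot (rows 10..12)
  X[cbind(13L + tr$cue, seq_len(L))] <- 1         # current cue (rows 13..14)
  if (L > 1) {
    j <- 2:L
    pr <- ifelse(is.na(tr$reward[j - 1]), 0L, tr$reward[j - 1])
    X[cbind(tr$step[j - 1], j)] <- 1              # prev step (rows 1..3)
    X[cbind(4L + tr$cue[j - 1], j)] <- 1          # prev cue (rows 4..5)
    X[cbind(6L + tr$action[j - 1], j)] <- 1       # prev action (rows 6..7)
    X[cbind(8L + pr, j)] <- 1                     # prev reward (rows 8..9)
  }
  list(X = X, actions = tr$action)
}

#' Teacher-forced action probabilities for a logged block
#'
#' The hidden state starts at zero; at each trial the solver receives the
#' logged (not self-generated) history and outputs softmax action
#' probabilities.
#'
#' @param weights a `solver_weights` for the block's condition.
#' @param block a `block_record`.
#' @return `L x 2` matrix of probabilities (rows sum to 1).
#' @export
forward_teacher <- function(weights, block) {
  if (!is.na(weights$arch$M) && weights$arch$M != block$M)
    stop_eidt("solver architecture does not match the block's condition")
  si <- solver_inputs(block)
  t(cpp_solver_forward(weights$theta, weights$arch$I, weights$arch$Q,
                       weights$arch$K, si$X))
}

# stateful agent driven by the solver's own output distribution
solver_agent <- function(weights) {
  p <- unpack_solver(weights)
  Q <- weights$arch$Q
  h <- NULL; prev <- NULL
  list(
    reset = function() { h <<- numeric(Q); prev <<- NULL },
    choose = function(step, cue) {
      x <- if (is.null(prev)) encode_step_input(NULL, NULL, NULL, c(step, cue))
           else encode_step_input(prev$s, prev$a, prev$r, c(step, cue))
      h <<- gru_step_r(p, x, h)
      v <- drop(p$Wout %*% h)
      pr <- exp(v - max(v)); pr <- pr / sum(pr)
      if (runif(1) < pr[2]) 1L else 0L
    },
    learn = function(step, cue, action, reward, next_step, next_cue) {
      prev <<- list(s = c(step, cue), a = action, r = reward)
    })
}

#' Let a task solver act on-policy in the environment
#'
#' Actions are sampled from the solver's own output distribution; the
#' environment drifts and is stepped as in [run_block()].
#'
#' @param weights a `solver_weights`.
#' @param env an `mdp_env` matching the architecture.
#' @param n_episodes episodes to play.
#' @param condition optional label stored on the block.
#' @param seed optional seed.
#' @return a `block_record`.
#' @export
act_on_policy <- function(weights, env, n_episodes = 50, condition = NULL,
                          seed = NULL) {
  if (!is.na(weights$arch$M) && weights$arch$M != env$M)
    stop_eidt("solver architecture does not match the environment")
  if (!is.null(seed)) set.seed(seed)
  blk <- run_block_agent(env, solver_agent(weights), n_episodes)
  blk$condition <- condition
  blk
}

#' Train the within-condition baseline solver
#'
#' A single task solver (the same architecture the transfer pipeline
#' generates) is trained by Adam on the pooled blocks of one condition,
#' minimizing mean per-trial NLL, with participant-level validation split and
#' early stopping on validation loss.
#'
#' @param ds a `behavioral_dataset`.
#' @param condition condition label.
#' @param hyper list of hyperparameters: `lr` (default 0.01), `max_epochs`
#'   (200), `patience` (20), `val_frac` (0.1), `grad_clip` (10), `seed` (1).
#' @return a `solver_weights` (best-validation checkpoint) with attribute
#'   `"log"`: data.frame of per-epoch training/validation loss.
#' @export
train_baseline <- function(ds, condition, hyper = list()) {
  h <- modifyList(list(lr = 0.01, lr_decay = 0.985, max_epochs = 200,
                       patience = 20, val_frac = 0.1, grad_clip = 10,
                       seed = 1), hyper)
  ids <- individual_ids(ds)
  if (length(ids) < 2) stop_eidt("need at least 2 individuals")
  arch <- solver_arch(ds$steps[[condition]])
  set.seed(h$seed)
  n_val <- max(1L, round(h$val_frac * length(ids)))
  val_ids <- sample(ids, n_val)
  prep <- function(sel) {
    out <- list()
    for (id in sel)
      for (blk in get_blocks(ds, id, condition))
        out[[length(out) + 1L]] <- solver_inputs(blk)
    out
  }
  tr <- prep(setdiff(ids, val_ids)); va <- prep(val_ids)
  w0 <- init_solver_weights(arch)
  theta <- w0$theta
  adam <- make_adam(length(theta), lr = h$lr)
  loss_of <- function(th, set, grad = FALSE) {
    g <- numeric(length(th)); tot <- 0
    for (b in set) {
      r <- cpp_solver_nll_grad(th, arch$I, arch$Q, arch$K, b$X, b$actions, grad)
      tot <- tot + r$nll
      if (grad) g <- g + r$grad
    }
    list(nll = tot / length(set), grad = g / length(set))
  }
  best <- list(theta = theta, val = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  for (ep in seq_len(h$max_epochs)) {
    tr_loss <- 0
    lr_ep <- h$lr * h$lr_decay^(ep - 1)
    for (i in sample.int(length(tr))) {  # one stochastic update per block
      r <- cpp_solver_nll_grad(theta, arch$I, arch$Q, arch$K, tr[[i]]$X,
                               tr[[i]]$actions, TRUE)
      theta <- adam(theta, clip_grad(r$grad, h$grad_clip), lr_ep)
      tr_loss <- tr_loss + r$nll
    }
    v <- loss_of(theta, va)$nll
    log <- rbind(log, data.frame(epoch = ep, train = tr_loss / length(tr), val = v))
    if (v < best$val) best <- list(theta = theta, val = v, epoch = ep)
    if (ep - best$epoch >= h$patience) break
  }
  out <- solver_weights(best$theta, arch)
  attr(out, "log") <- log
  out
}
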