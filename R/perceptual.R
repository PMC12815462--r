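# Transfer pipeline for single-shot perceptual decisions (digit
# classification).  The visual front end is abstracted behind a pluggable
# stochastic evidence source shared by all individuals; the individual part
# is a small evidence-accumulating GRU whose weights the decoder generates.
# Response times are binned to accumulator steps at 10 steps per second.

#' Convert a response time to an accumulator time step
#'
#' `t = round(10 b)` (nearest integer, ties to even), clipped to
#' `[0, S - 1]`.
#'
#' @param b response time in seconds (vectorized, non-negative).
#' @param S number of accumulator steps (default 16).
#' @return integer time step(s) in `0..S-1`.
#' @export
rt_to_step <- function(b, S = 16L) {
  if (any(b < 0)) stop_eidt("response times must be non-negative")
  pmin(as.integer(round(10 * b)), as.integer(S) - 1L)
}

#' A stochastic evidence source
#'
#' The contract standing in for a pretrained stochastic visual network: each
#' call yields `S` evidence vectors of length `K` for a stimulus, differing
#' across calls.
#'
#' @param sample_fun function `(true_label) -> K x S` evidence matrix
#'   (columns are time steps); called with the 0-based class of the stimulus.
#' @param S,K evidence steps and classes.
#' @return object of class `evidence_source`.
#' @export
evidence_source <- function(sample_fun, S = 16L, K = 10L) {
  structure(list(sample = sample_fun, S = as.integer(S), K = as.integer(K)),
            class = "evidence_source")
}

#' Gaussian evidence source
#'
#' Evidence at each step is `gain * onehot(true_label) + N(0, noise^2)`
#' i.i.d. across steps and calls; `gain / noise` controls difficulty (the
#' easy/difficult condition analog).
#'
#' @param gain signal gain; @param noise noise standard deviation.
#' @inheritParams evidence_source
#' @return an `evidence_source`.
#' @export
gaussian_evidence_source <- function(gain = 1, noise = 0.5, S = 16L, K = 10L) {
  force(gain); force(noise)
  evidence_source(function(true_label) {
    E <- matrix(rnorm(K * S, 0, noise), K, S)
    E[true_label + 1, ] <- E[true_label + 1, ] + gain
    E
  }, S = S, K = K)
}

#' Per-step class probabilities of the evidence accumulator
#'
#' @param weights a `solver_weights` with an accumulator architecture.
#' @param evidence `S x K` matrix of evidence vectors (rows are time steps).
#' @return `S x K` matrix of class probabilities, each row summing to 1.
#' @export
accumulate <- function(weights, evidence) {
  arch <- weights$arch
  if (ncol(evidence) != arch$K) stop_eidt("evidence must have K columns")
  t(cpp_solver_forward(weights$theta, arch$I, arch$Q, arch$K, t(evidence)))
}

#' Likelihood of one observed perceptual decision
#'
#' The probability the accumulator assigned to the chosen digit at the
#' converted response-time step.
#'
#' @param probs `S x K` matrix from [accumulate()].
#' @param trial list or one-row data.frame with `action` (0-based) and `rt`
#'   (seconds).
#' @return scalar probability.
#' @export
trial_likelihood <- function(probs, trial) {
  tt <- rt_to_step(trial$rt, nrow(probs))
  probs[tt + 1L, trial$action + 1L]
}

# Encoder input for one source trial: evidence stacked over the action
# channel, which is the one-hot action at t = t~ and zeros elsewhere.
perc_encoder_slice <- function(E, action, tstep, K) {
  A <- matrix(0, K, ncol(E))
  A[action + 1L, tstep + 1L] <- 1
  rbind(E, A)
}

#' Set-based latent inference for the perceptual task
#'
#' Each trial's evidence (freshly sampled from the shared source unless
#' supplied) enters the encoder GRU together with the gated action channel;
#' the final hidden states are averaged over trials before the head maps
#' them to `z`.
#'
#' @param model a trained `perc_eidt_model`.
#' @param trials data.frame of the individual's source-condition trials
#'   (`true_label`, `action`, `rt`).
#' @param evidence optional list of pre-sampled `K x S` evidence matrices,
#'   one per trial (used to hold evidence fixed).
#' @return numeric latent vector.
#' @export
set_encode <- function(model, trials, evidence = NULL) {
  if (nrow(trials) < 1) stop_eidt("need at least one trial")
  src <- model$sources[[model$source]]
  K <- src$K; S <- src$S
  d <- eidt_dims(model)
  cube <- array(0, c(2L * K, S, nrow(trials)))
  tt <- rt_to_step(trials$rt, S)
  for (u in seq_len(nrow(trials))) {
    E <- if (is.null(evidence)) src$sample(trials$true_label[u]) else evidence[[u]]
    cube[, , u] <- perc_encoder_slice(E, trials$action[u], tt[u], K)
  }
  drop(cpp_set_encode(model$par[seq_len(d$n_enc)], d$Ie, d$R, d$head_sizes, cube))
}

#' Per-trial likelihoods of target-condition decisions
#'
#' Decodes `z` into accumulator weights and scores each target trial at its
#' converted response-time step, with evidence freshly sampled from the
#' shared source for the target condition.
#'
#' @param model a trained `perc_eidt_model`.
#' @param z latent vector.
#' @param trials data.frame of target-condition trials.
#' @return numeric vector of probabilities, one per trial.
#' @export
predict_perceptual <- function(model, z, trials) {
  w <- decode_weights(model, z)
  src <- model$sources[[model$target]]
  vapply(seq_len(nrow(trials)), function(u) {
    probs <- accumulate(w, t(src$sample(trials$true_label[u])))
    trial_likelihood(probs, trials[u, ])
  }, 0)
}

new_perc_model <- function(source, target, sources, config) {
  K <- sources[[source]]$K
  head_sizes <- c(config$encoder_cells, config$head_hidden, config$latent_dim)
  structure(list(task = "perceptual", source = source, target = target,
                 latent_dim = config$latent_dim, Ie = 2L * K,
                 R = config$encoder_cells, head_sizes = head_sizes,
                 arch_tgt = accumulator_arch(K = K, S = sources[[source]]$S),
                 par = NULL, config = config, sources = sources, log = NULL),
            class = c("perc_eidt_model", "eidt_model"))
}

# per-individual training tensors; evidence is sampled once, up front
perc_prepare <- function(ds, id, source, target, sources) {
  tr <- ds$trials
  srcd <- tr[tr$participant == id & tr$condition == source, ]
  tgtd <- tr[tr$participant == id & tr$condition == target, ]
  if (!nrow(srcd) || !nrow(tgtd)) return(NULL)
  K <- sources[[source]]$K; S <- sources[[source]]$S
  tt_s <- rt_to_step(srcd$rt, S)
  Xs <- array(0, c(2L * K, S, nrow(srcd)))
  for (u in seq_len(nrow(srcd)))
    Xs[, , u] <- perc_encoder_slice(sources[[source]]$sample(srcd$true_label[u]),
                                    srcd$action[u], tt_s[u], K)
  Et <- array(0, c(K, S, nrow(tgtd)))
  for (v in seq_len(nrow(tgtd)))
    Et[, , v] <- sources[[target]]$sample(tgtd$true_label[v])
  list(id = id, Xs = Xs, Et = Et,
       tt = rt_to_step(tgtd$rt, S), act = tgtd$action)
}

#' Train the perceptual transfer model
#'
#' As [train_eidt()], with the set encoder over an individual's source
#' trials and the loss `-log P_t~(a)` averaged over their target trials.
#' Evidence for the training tensors is sampled once at setup (seeded); at
#' inference time evidence is re-sampled per call.
#'
#' @param ds a perceptual `behavioral_dataset`.
#' @param source,target condition labels.
#' @param sources named list of [evidence_source()] objects, one per
#'   condition (shared across individuals).
#' @param config an [eidt_config()]; defaults here use a 16-cell encoder
#'   with a single-layer head.
#' @return a trained `perc_eidt_model`.
#' @export
train_perceptual_eidt <- function(ds, source, target, sources,
                                  config = eidt_config(encoder_cells = 16,
                                                       head_hidden = integer(0),
                                                       lr = 0.01)) {
  ids <- individual_ids(ds)
  if (length(ids) < 10) stop_eidt("need at least 10 individuals to train")
  model <- new_perc_model(source, target, sources, config)
  d <- eidt_dims(model)
  set.seed(config$seed)
  data <- Filter(Negate(is.null),
                 lapply(ids, perc_prepare, ds = ds, source = source,
                        target = target, sources = sources))
  n_val <- max(1L, round(config$val_frac * length(data)))
  val_idx <- sample(seq_along(data), n_val)
  tr <- data[-val_idx]; va <- data[val_idx]
  par <- init_eidt_par(model)
  adam <- make_adam(length(par), lr = config$lr)
  one <- function(p, ind, grad = FALSE)
    cpp_perc_pair_grad(p, d$Ie, d$R, d$head_sizes, d$I, d$Q, d$K,
                       ind$Xs, ind$Et, ind$tt, ind$act, grad)
  pool_loss <- function(p, pool)
    mean(vapply(pool, function(ind) one(p, ind)$loss, 0))
  best <- list(par = par, val = pool_loss(par, va), epoch = 0L)
  log <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  decay <- config$lr_decay %||% 1
  for (ep in seq_len(config$max_epochs)) {
    tr_loss <- 0
    lr_ep <- config$lr * decay^(ep - 1)
    for (ind in tr[sample.int(length(tr))]) {
      r <- one(par, ind, grad = TRUE)
      par <- adam(par, clip_grad(r$grad, config$grad_clip), lr_ep)
      tr_loss <- tr_loss + r$loss
    }
    v <- pool_loss(par, va)
    log <- rbind(log, data.frame(epoch = ep, train = tr_loss / length(tr), val = v))
    if (v < best$val) best <- list(par = par, val = v, epoch = ep)
    if (ep - best$epoch >= config$patience) break
  }
  model$par <- best$par
  model$log <- log
  model
}

#' Train a group-agnostic accumulator on one condition
#'
#' A single accumulator (no individuality) fitted by Adam to the pooled
#' trials of a condition; the within-condition baseline for the perceptual
#' task.
#'
#' @inheritParams train_perceptual_eidt
#' @param condition condition whose trials are fitted.
#' @param hyper list: `lr` (0.02), `max_epochs` (150), `patience` (20),
#'   `val_frac` (0.1), `grad_clip` (10), `seed` (1).
#' @return a `solver_weights` with attribute `"log"`.
#' @export
train_perceptual_baseline <- function(ds, condition, sources, hyper = list()) {
  h <- modifyList(list(lr = 0.02, lr_decay = 0.985, max_epochs = 150,
                       patience = 20, val_frac = 0.1, grad_clip = 10,
                       seed = 1), hyper)
  force(ds); force(sources)
  set.seed(h$seed)
  src <- sources[[condition]]
  tr <- ds$trials[ds$trials$condition == condition, ]
  if (!nrow(tr)) stop_eidt("no trials of condition ", condition)
  K <- src$K; S <- src$S
  E <- array(0, c(K, S, nrow(tr)))
  for (v in seq_len(nrow(tr))) E[, , v] <- src$sample(tr$true_label[v])
  tt <- rt_to_step(tr$rt, S)
  ids <- unique(tr$participant)
  val_ids <- sample(ids, max(1L, round(h$val_frac * length(ids))))
  vi <- tr$participant %in% val_ids
  arch <- accumulator_arch(K = K, S = S)
  theta <- init_solver_weights(arch)$theta
  adam <- make_adam(length(theta), lr = h$lr)
  best <- list(theta = theta, val = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  for (ep in seq_len(h$max_epochs)) {
    r <- cpp_acc_nll_grad(theta, arch$I, arch$Q, arch$K, E[, , !vi, drop = FALSE],
                          tt[!vi], tr$action[!vi], TRUE)
    theta <- adam(theta, clip_grad(r$grad, h$grad_clip),
                  h$lr * h$lr_decay^(ep - 1))
    v <- cpp_acc_nll_grad(theta, arch$I, arch$Q, arch$K, E[, , vi, drop = FALSE],
                          tt[vi], tr$action[vi], FALSE)$nll
    log <- rbind(log, data.frame(epoch = ep, train = r$nll, val = v))
    if (v < best$val) best <- list(theta = theta, val = v, epoch = ep)
    if (ep - best$epoch >= h$patience) break
  }
  out <- solver_weights(best$theta, arch)
  attr(out, "log") <- log
  out
}
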