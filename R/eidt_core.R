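# The transfer pipeline: encoder GRU -> individual latent representation ->
# linear hypernetwork decoder -> task-solver weights, trained end-to-end on
# a pool of individuals who performed both task conditions.
#
# The encoder consumes the same step inputs as the task solver, augmented
# with the one-hot of the action actually taken (16 inputs in total); its
# final hidden state passes through a feed-forward head to produce the
# latent vector z.  The decoder is a single affine map from z to the
# flattened solver weight vector.  The loss is the teacher-forced mean
# per-trial NLL of the target-condition actions, averaged over individuals
# and over all (source block, target block) pairs of each individual.

#' Training configuration for the transfer model
#'
#' @param latent_dim dimension of the individual latent representation
#'   (default 2).
#' @param encoder_cells encoder GRU size (default 32).
#' @param head_hidden hidden-layer sizes of the encoder head; the default
#'   `c(32, 16, 8)` gives a four-layer head ending in `latent_dim`.
#' @param lr Adam learning rate.
#' @param lr_decay multiplicative per-epoch decay of the learning rate
#'   (default 0.985), stabilizing the late stochastic updates.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience, in epochs without validation
#'   improvement.
#' @param val_frac fraction of participants held out for validation
#'   (default 0.1; the split is by participant, never by block).
#' @param grad_clip global gradient-norm clip.
#' @param latent_averaging when `TRUE`, each training update uses the
#'   individual's latent representation averaged over all of their source
#'   blocks — the quantity used at inference time — instead of a single
#'   block's encoding.  Default `FALSE`: one update per (source block,
#'   target block) pair, the strict reading of the training objective.
#' @param warm_start when `TRUE`, the decoder bias is initialized from a
#'   solver pre-trained on the training split's target-condition blocks, so
#'   that from the first epoch the reproduction-loss gradient carries
#'   individual differences rather than the population-average policy.
#'   Default `FALSE`: joint training from scratch.
#' @param seed integer seed controlling the split, initialization, and batch
#'   order.
#' @return a list of class `eidt_config`.
#' @export
eidt_config <- function(latent_dim = 2, encoder_cells = 32,
                        head_hidden = c(32, 16, 8), lr = 0.005,
                        lr_decay = 0.985, max_epochs = 150, patience = 20,
                        val_frac = 0.1, grad_clip = 10, warm_start = FALSE,
                        latent_averaging = FALSE, seed = 1) {
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_cells = as.integer(encoder_cells),
                 head_hidden = as.integer(head_hidden), lr = lr,
                 lr_decay = lr_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_frac = val_frac,
                 grad_clip = grad_clip, warm_start = isTRUE(warm_start),
                 latent_averaging = isTRUE(latent_averaging),
                 seed = as.integer(seed)),
            class = "eidt_config")
}

# encoder input: solver step input plus the taken action's one-hot
eidt_encoder_inputs <- function(block) {
  si <- solver_inputs(block)
  A <- matrix(0, 2, ncol(si$X))
  A[cbind(si$actions + 1L, seq_len(ncol(si$X)))] <- 1
  rbind(si$X, A)
}

eidt_dims <- function(model) {
  list(Ie = model$Ie, R = model$R, head_sizes = model$head_sizes,
       I = model$arch_tgt$I, Q = model$arch_tgt$Q, K = model$arch_tgt$K,
       n_enc = cpp_encoder_npar(model$Ie, model$R, model$head_sizes),
       Nts = model$arch_tgt$n_weights)
}

new_eidt_model <- function(source, target, steps, config) {
  head_sizes <- c(config$encoder_cells, config$head_hidden, config$latent_dim)
  structure(list(task = "mdp", source = source, target = target,
                 latent_dim = config$latent_dim, Ie = MDP_INPUT_LEN + 2L,
                 R = config$encoder_cells, head_sizes = head_sizes,
                 arch_tgt = solver_arch(steps[[target]]),
                 par = NULL, config = config, log = NULL),
            class = "eidt_model")
}

#' @export
print.eidt_model <- function(x, ...) {
  cat(sprintf("<eidt_model> %s -> %s, latent dim %d, %d parameters\n",
              x$source, x$target, x$latent_dim, length(x$par)))
  if (!is.null(x$log))
    cat(sprintf("  trained %d epochs, best validation loss %.4f\n",
                nrow(x$log), min(x$log$val)))
  invisible(x)
}

init_eidt_par <- function(model) {
  d <- eidt_dims(model)
  Ie <- d$Ie; R <- d$R
  enc_gru <- c(runif_fan(3 * R * Ie, Ie), runif_fan(3 * R * R, R), numeric(3 * R))
  head <- numeric(0)
  hs <- model$head_sizes
  for (i in seq_along(hs)[-1])
    head <- c(head, runif_fan(hs[i] * hs[i - 1], hs[i - 1]), numeric(hs[i]))
  arch <- model$arch_tgt
  decb <- init_solver_weights(arch)$theta
  decW <- 0.1 * runif_fan(d$Nts * model$latent_dim, model$latent_dim)
  c(enc_gru, head, decW, decb)
}

#' Latent representation of a single source-condition block
#'
#' @param model a trained `eidt_model`.
#' @param block a `block_record` of the model's source condition.
#' @return numeric latent vector `z`.
#' @export
encode_sequence <- function(model, block) {
  if (!identical(block$condition, model$source))
    stop_eidt("block is not from the source condition '", model$source, "'")
  d <- eidt_dims(model)
  drop(cpp_encode(model$par[seq_len(d$n_enc)], d$Ie, d$R, d$head_sizes,
                  eidt_encoder_inputs(block)))
}

#' Generate task-solver weights from a latent representation
#'
#' The decoder is a single affine map (hypernetwork): `theta = W z + b`.
#'
#' @param model a trained `eidt_model`.
#' @param z latent vector of length `model$latent_dim`.
#' @return a `solver_weights` for the target condition.
#' @export
decode_weights <- function(model, z) {
  if (length(z) != model$latent_dim)
    stop_eidt("latent dimension mismatch: expected ", model$latent_dim)
  d <- eidt_dims(model)
  W <- matrix(model$par[d$n_enc + seq_len(d$Nts * model$latent_dim)],
              d$Nts, model$latent_dim)
  b <- model$par[d$n_enc + d$Nts * model$latent_dim + seq_len(d$Nts)]
  solver_weights(drop(W %*% z) + b, model$arch_tgt)
}

#' An individual's latent representation
#'
#' The arithmetic mean of [encode_sequence()] over all of the individual's
#' source-condition blocks.
#'
#' @param model a trained `eidt_model`.
#' @param record an `individual_record` with source-condition blocks.
#' @return numeric latent vector.
#' @export
individual_latent <- function(model, record) {
  blocks <- Filter(function(b) identical(b$condition, model$source),
                   record$blocks)
  if (!length(blocks)) stop_eidt("record has no source-condition blocks")
  zs <- vapply(blocks, function(b) encode_sequence(model, b),
               numeric(model$latent_dim))
  rowMeans(matrix(zs, nrow = model$latent_dim))
}

#' Predict target-condition behavior for an individual
#'
#' The individual's latent representation (from source-condition behavior
#' only) is decoded into solver weights, which score the target block
#' teacher-forced.  The individual's target-condition data never enter the
#' latent inference.
#'
#' @param model a trained `eidt_model`.
#' @param record an `individual_record` with source-condition blocks.
#' @param target_block a `block_record` of the target condition.
#' @return `L x 2` matrix of per-trial action probabilities.
#' @export
transfer_predict <- function(model, record, target_block) {
  if (!identical(target_block$condition, model$target))
    stop_eidt("block is not from the target condition '", model$target, "'")
  w <- decode_weights(model, individual_latent(model, record))
  forward_teacher(w, target_block)
}

#' Reproduction loss for one (source block, target block) pair
#'
#' Mean per-trial NLL of the logged target actions under the solver generated
#' from the source block.
#'
#' @param model an `eidt_model`.
#' @param source_block,target_block blocks of one individual, in the model's
#'   source and target conditions.
#' @return scalar loss.
#' @export
eidt_loss <- function(model, source_block, target_block) {
  d <- eidt_dims(model)
  si <- solver_inputs(target_block)
  r <- cpp_eidt_pair_grad(model$par, d$Ie, d$R, d$head_sizes, d$I, d$Q, d$K,
                          eidt_encoder_inputs(source_block), si$X, si$actions,
                          FALSE)
  r$loss
}

# Precompute per-individual encoder/solver inputs for training.
build_eidt_pairs <- function(ds, source, target) {
  lapply(individual_ids(ds), function(id) {
    list(id = id,
         src = lapply(get_blocks(ds, id, source), eidt_encoder_inputs),
         tgt = lapply(get_blocks(ds, id, target), solver_inputs))
  })
}

#' Train the transfer model
#'
#' Participants are split 90/10 into training and validation pools (by
#' participant).  Each epoch visits the training individuals in a shuffled
#' order; for each individual the gradient of the loss averaged over all of
#' their (source block, target block) pairs drives one Adam update.  The
#' returned model carries the parameters of the best-validation epoch.
#'
#' @param ds a `behavioral_dataset` containing both conditions.
#' @param source,target condition labels.
#' @param config an [eidt_config()].
#' @return a trained `eidt_model`; element `log` holds the per-epoch
#'   training/validation loss trace.
#' @export
train_eidt <- function(ds, source, target, config = eidt_config()) {
  ids <- individual_ids(ds)
  if (length(ids) < 10) stop_eidt("need at least 10 individuals to train")
  for (cond in c(source, target))
    if (!cond %in% names(ds$steps)) stop_eidt("condition not in dataset: ", cond)
  model <- new_eidt_model(source, target, ds$steps, config)
  d <- eidt_dims(model)
  set.seed(config$seed)
  n_val <- max(1L, round(config$val_frac * length(ids)))
  val_ids <- sample(ids, n_val)
  pairs <- build_eidt_pairs(ds, source, target)
  names(pairs) <- vapply(pairs, `[[`, "", "id")
  tr <- pairs[setdiff(ids, val_ids)]
  va <- pairs[val_ids]
  par <- init_eidt_par(model)
  if (isTRUE(config$warm_start)) {
    # pre-train the decoder bias as a population solver on the training split
    sub <- ds
    keep <- ds$trials$participant %in% setdiff(ids, val_ids)
    sub$trials <- ds$trials[keep, ]
    sub$envs <- ds$envs[ds$envs$participant %in% setdiff(ids, val_ids), ]
    w0 <- train_baseline(sub, target,
                         list(max_epochs = 80, patience = 80, lr = 0.01,
                              seed = config$seed + 1L))
    par[(length(par) - d$Nts + 1):length(par)] <- w0$theta
  }
  adam <- make_adam(length(par), lr = config$lr)
  avg <- isTRUE(config$latent_averaging)
  indiv_grad <- function(p, ind, t_idx, grad = FALSE)
    cpp_eidt_indiv_grad(p, d$Ie, d$R, d$head_sizes, d$I, d$Q, d$K,
                        ind$src, ind$tgt[[t_idx]]$X, ind$tgt[[t_idx]]$actions,
                        grad)
  pair_grad <- function(p, Xs, tg, grad = FALSE)
    cpp_eidt_pair_grad(p, d$Ie, d$R, d$head_sizes, d$I, d$Q, d$K,
                       Xs, tg$X, tg$actions, grad)
  indiv_loss <- function(p, ind) {
    if (avg)
      mean(vapply(seq_along(ind$tgt), function(t)
        indiv_grad(p, ind, t)$loss, 0))
    else
      mean(vapply(ind$src, function(Xs)
        vapply(ind$tgt, function(tg) pair_grad(p, Xs, tg)$loss, 0),
        numeric(length(ind$tgt))))
  }
  pool_loss <- function(p, pool)
    mean(vapply(pool, function(ind) indiv_loss(p, ind), 0))
  # one stochastic update per (individual, source block, target block) pair,
  # or per (individual, target block) when the latent is averaged over the
  # individual's source blocks (latent_averaging = TRUE)
  batches <- do.call(rbind, lapply(seq_along(tr), function(i)
    expand.grid(ind = i, s = if (avg) 0L else seq_along(tr[[i]]$src),
                t = seq_along(tr[[i]]$tgt))))
  best <- list(par = par, val = pool_loss(par, va), epoch = 0L)
  log <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  decay <- config$lr_decay %||% 1
  for (ep in seq_len(config$max_epochs)) {
    tr_loss <- 0
    lr_ep <- config$lr * decay^(ep - 1)
    for (b in sample.int(nrow(batches))) {
      ind <- tr[[batches$ind[b]]]
      r <- if (avg) indiv_grad(par, ind, batches$t[b], grad = TRUE)
           else pair_grad(par, ind$src[[batches$s[b]]], ind$tgt[[batches$t[b]]],
                          grad = TRUE)
      par <- adam(par, clip_grad(r$grad, config$grad_clip), lr_ep)
      tr_loss <- tr_loss + r$loss
    }
    v <- pool_loss(par, va)
    log <- rbind(log, data.frame(epoch = ep, train = tr_loss / nrow(batches), val = v))
    if (v < best$val) best <- list(par = par, val = v, epoch = ep)
    if (ep - best$epoch >= config$patience) break
  }
  model$par <- best$par
  model$log <- log
  model$val_ids <- val_ids
  model
}
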