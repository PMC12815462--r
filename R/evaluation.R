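# Metrics and statistical analyses: trial-wise NLL, behavior-match rate,
# cross-individual latent-distance regression, on-policy comparisons, and
# the latent-versus-cognitive-parameter regression.

#' Mean negative log-likelihood per trial
#'
#' @param probs `L x K` matrix of predicted action probabilities.
#' @param actions integer vector of 0-based taken actions.
#' @param clamp lower clamp for probabilities; `0` (default) lets a zero
#'   probability produce `Inf`.
#' @return scalar mean of `-log p(action_t)`.
#' @export
nll_metric <- function(probs, actions, clamp = 0) {
  if (nrow(probs) != length(actions)) stop_eidt("probs/actions length mismatch")
  p <- probs[cbind(seq_along(actions), actions + 1L)]
  mean(-log(pmax(p, clamp)))
}

#' Behavior-match rate
#'
#' Fraction of trials where the model's most probable action (ties broken by
#' the lowest action index) equals the taken action.
#'
#' @inheritParams nll_metric
#' @return proportion in `[0, 1]`.
#' @export
match_rate <- function(probs, actions) {
  if (nrow(probs) != length(actions)) stop_eidt("probs/actions length mismatch")
  mean(max.col(probs, ties.method = "first") - 1L == actions)
}

#' Cross-individual prediction matrix
#'
#' For every ordered pair `(k, l)` the task solver generated from individual
#' `l`'s latent representation predicts individual `k`'s target-condition
#' behavior; `d[k, l]` is the Euclidean distance between the two latents.
#'
#' @param model a trained `eidt_model`.
#' @param ds a `behavioral_dataset` containing the individuals to cross.
#' @return object of class `cross_individual_result`: list with `ids`, the
#'   latent matrix `z` (individuals x dims), and matrices `nll`, `match`,
#'   `d` (rows `k`, columns `l`).
#' @export
cross_individual_matrix <- function(model, ds) {
  ids <- individual_ids(ds)
  if (length(ids) < 2) stop_eidt("need at least 2 individuals")
  recs <- lapply(ids, get_individual, ds = ds)
  z <- t(vapply(recs, function(r) individual_latent(model, r),
                numeric(model$latent_dim)))
  tgt <- lapply(recs, function(r)
    lapply(Filter(function(b) identical(b$condition, model$target), r$blocks),
           solver_inputs))
  n <- length(ids)
  nll <- matrix(NA_real_, n, n); match <- matrix(NA_real_, n, n)
  a <- model$arch_tgt
  for (l in seq_len(n)) {
    w <- decode_weights(model, z[l, ])
    for (k in seq_len(n)) {
      P <- do.call(rbind, lapply(tgt[[k]], function(si)
        t(cpp_solver_forward(w$theta, a$I, a$Q, a$K, si$X))))
      acts <- unlist(lapply(tgt[[k]], `[[`, "actions"))
      nll[k, l] <- nll_metric(P, acts)
      match[k, l] <- match_rate(P, acts)
    }
  }
  d <- as.matrix(dist(z))
  dimnames(nll) <- dimnames(match) <- dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, z = z, nll = nll, match = match, d = d),
            class = "cross_individual_result")
}

#' Gamma regression of prediction performance on latent distance
#'
#' Fits `y_kl ~ Gamma(link = log)` with linear predictor
#' `intercept + participant_k effect (sum-to-zero) + beta_d * d_kl` over all
#' ordered pairs `k != l`, and reports the distance coefficient with its Wald
#' p-value.
#'
#' @param result a `cross_individual_result`.
#' @param metric `"nll"` or `"match"`; match-rate responses are shifted by
#'   `eps` so the Gamma family applies.
#' @param eps positive shift for zero responses.
#' @return object of class `distance_glm`: list with `beta_d`, `se`,
#'   `p_value`, and the underlying `glm` fit.
#' @export
fit_distance_glm <- function(result, metric = c("nll", "match"), eps = 1e-3) {
  metric <- match.arg(metric)
  n <- length(result$ids)
  k <- rep(seq_len(n), times = n); l <- rep(seq_len(n), each = n)
  off <- k != l
  y <- result[[metric]][cbind(k, l)][off]
  d <- result$d[cbind(k, l)][off]
  if (var(d) == 0) stop_eidt("latent distances are constant; design is singular")
  if (metric == "match") y <- y + eps
  df <- data.frame(y = y, d = d, participant = factor(result$ids[k[off]]))
  fit <- glm(y ~ participant + d, data = df, family = Gamma(link = "log"),
             contrasts = list(participant = "contr.sum"))
  sm <- summary(fit)$coefficients
  structure(list(beta_d = sm["d", "Estimate"], se = sm["d", "Std. Error"],
                 p_value = sm["d", "Pr(>|t|)"], fit = fit, metric = metric),
            class = "distance_glm")
}

#' @export
print.distance_glm <- function(x, ...) {
  cat(sprintf("<distance_glm> metric=%s: beta_d = %.4f (se %.4f, p = %.3g)\n",
              x$metric, x$beta_d, x$se, x$p_value))
  invisible(x)
}

# per-block on-policy summaries
block_total_reward <- function(block) sum(block$trials$reward, na.rm = TRUE)

block_high_reward_rate <- function(block) {
  tr <- block_node_path(block)
  fin <- tr[tr$step == block$M, ]
  hits <- vapply(seq_len(nrow(fin)), function(i) {
    env <- env_at_episode(block, fin$episode[i])
    fin$action[i] == highly_rewarding_action(env, fin$node[i])
  }, FALSE)
  mean(hits)
}

#' Replay a logged environment with a task solver acting on-policy
#'
#' The solver plays the exact environment sequence recorded in a block
#' (initial table plus drift events), sampling its own actions; used to
#' compare model-generated and original behavior on identical environments.
#'
#' @param weights a `solver_weights`.
#' @param block a `block_record` whose environment trace is replayed.
#' @return a `block_record` with the same environment trace.
#' @export
act_on_policy_traced <- function(weights, block) {
  agent <- solver_agent(weights)
  agent$reset()
  n_ep <- max(block$trials$episode) + 1L
  M <- block$M
  trials <- block$trials
  trials$reward <- NA_integer_; trials$rt <- NA_real_
  row <- 1L
  for (ep in seq_len(n_ep) - 1L) {
    env <- env_at_episode(block, ep)
    node <- 0L
    path <- integer(M); acts <- integer(M); cues <- integer(M)
    for (m in seq_len(M)) {
      cue <- node %% 2L
      a <- agent$choose(m, cue)
      path[m] <- node; cues[m] <- cue; acts[m] <- a
      if (m < M) node <- 2L * node + (runif(1) < env$trans[[m]][node + 1, a + 1])
    }
    r <- as.integer(runif(1) < env$reward[path[M] + 1, acts[M] + 1])
    for (m in seq_len(M)) {
      agent$learn(m, cues[m], acts[m], if (m == M) r else 0L,
                  if (m < M) m + 1L else NA_integer_,
                  if (m < M) cues[m + 1] else NA_integer_)
      trials$cue[row] <- cues[m]; trials$action[row] <- acts[m]
      if (m == M) trials$reward[row] <- r
      row <- row + 1L
    }
  }
  out <- block
  out$trials <- trials
  out
}

#' Compare on-policy model behavior against original behavior
#'
#' For each paired block: the total reward and the rate of choosing the
#' highly rewarding final-step action (judged against the environment logged
#' for that episode); Pearson correlations are computed across blocks.
#'
#' @param orig_blocks,model_blocks lists of paired `block_record`s of equal
#'   length, the model blocks played on the same logged environments (see
#'   [act_on_policy_traced()]).
#' @return list with `table` (per-pair metrics), `reward_cor` and
#'   `high_rate_cor` (each `list(r, p)`).
#' @export
onpolicy_compare <- function(orig_blocks, model_blocks) {
  if (length(orig_blocks) != length(model_blocks))
    stop_eidt("block lists must be paired (equal length)")
  tab <- do.call(rbind, lapply(seq_along(orig_blocks), function(i)
    data.frame(pair = i,
               reward_orig = block_total_reward(orig_blocks[[i]]),
               reward_model = block_total_reward(model_blocks[[i]]),
               high_orig = block_high_reward_rate(orig_blocks[[i]]),
               high_model = block_high_reward_rate(model_blocks[[i]]))))
  ct1 <- cor.test(tab$reward_orig, tab$reward_model)
  ct2 <- cor.test(tab$high_orig, tab$high_model)
  list(table = tab,
       reward_cor = list(r = unname(ct1$estimate), p = ct1$p.value),
       high_rate_cor = list(r = unname(ct2$estimate), p = ct2$p.value))
}

#' Regress latent coordinates on cognitive parameters
#'
#' For each latent dimension, the linear model
#' `z_i ~ q_lr + q_it + q_lr:q_it` (Gaussian, identity link) over a pool of
#' agents with known parameters.
#'
#' @param latents `n x M` matrix of latent representations.
#' @param params data.frame with columns `q_lr` and `q_it` (one row per
#'   agent, `n >= 20`, each parameter non-degenerate).
#' @return list of class `latent_param_glm`: per-dimension `lm` fits and
#'   coefficient tables.
#' @export
latent_param_glm <- function(latents, params) {
  latents <- as.matrix(latents)
  if (nrow(latents) < 20) stop_eidt("need at least 20 agents")
  if (nrow(latents) != nrow(params)) stop_eidt("latents/params row mismatch")
  for (v in c("q_lr", "q_it"))
    if (length(unique(params[[v]])) < 2)
      stop_eidt("degenerate spread in ", v)
  fits <- lapply(seq_len(ncol(latents)), function(i) {
    df <- data.frame(z = latents[, i], q_lr = params$q_lr, q_it = params$q_it)
    lm(z ~ q_lr * q_it, data = df)
  })
  names(fits) <- paste0("z", seq_along(fits))
  structure(list(fits = fits,
                 coef = lapply(fits, function(f) summary(f)$coefficients)),
            class = "latent_param_glm")
}
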