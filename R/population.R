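# Synthetic agent populations: heterogeneous Q-learning agents for the
# value-guided task and threshold/gain/lapse accumulator agents for the
# perceptual task, plus complete dataset builders.

rdist <- function(d, n) {
  if (is.numeric(d) && length(d) == 1) return(rep(d, n))
  kind <- d[[1]]
  switch(kind,
         fixed = rep(d[[2]], n),
         beta = {
           if (d[[2]] <= 0 || d[[3]] <= 0) stop_eidt("beta shapes must be positive")
           rbeta(n, d[[2]], d[[3]])
         },
         lnorm = {
           if (d[[3]] <= 0) stop_eidt("lnorm sd must be positive")
           rlnorm(n, d[[2]], d[[3]])
         },
         unif = {
           if (d[[3]] < d[[2]]) stop_eidt("unif bounds out of order")
           runif(n, d[[2]], d[[3]])
         },
         stop_eidt("unknown distribution kind: ", kind))
}

#' Specification of a Q-learning agent population
#'
#' Defaults: learning rates `Beta(2, 2)`, inverse temperatures
#' `LogNormal(log 3, 0.5)`, discount rate fixed at 0.9, initial Q fixed at 0.
#' Distributions are given as `list(kind, par1, par2)` with kinds `fixed`,
#' `beta`, `lnorm`, `unif`, or as a single number (fixed).
#'
#' @param n number of agents.
#' @param q_lr,q_it,q_dr,q_init distribution descriptors.
#' @param seed integer seed for the draws.
#' @return list of class `population_spec`.
#' @export
population_spec <- function(n, q_lr = list("beta", 2, 2),
                            q_it = list("lnorm", log(3), 0.5),
                            q_dr = 0.9, q_init = 0, seed = 1) {
  structure(list(n = as.integer(n), q_lr = q_lr, q_it = q_it, q_dr = q_dr,
                 q_init = q_init, seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a population of cognitive-model parameter vectors
#'
#' @param spec a [population_spec()].
#' @param id_prefix prefix for the generated participant ids.
#' @return data.frame `participant, q_lr, q_dr, q_it, q_init`, reproducible
#'   given the spec's seed. Rates are clipped into the open unit interval.
#' @export
sample_qpopulation <- function(spec, id_prefix = "a") {
  set.seed(spec$seed)
  n <- spec$n
  clip01 <- function(x) pmin(pmax(x, 1e-3), 1 - 1e-3)
  data.frame(participant = sprintf("%s%04d", id_prefix, seq_len(n)),
             q_lr = clip01(rdist(spec$q_lr, n)),
             q_dr = clip01(rdist(spec$q_dr, n)),
             q_it = pmax(rdist(spec$q_it, n), 1e-3),
             q_init = rdist(spec$q_init, n))
}

#' Build a complete synthetic value-guided dataset
#'
#' Each agent plays `blocks_per_condition` blocks of every condition on
#' freshly initialized drifting environments (the human protocol geometry:
#' 3 blocks of 50 episodes per condition).
#'
#' @param population data.frame from [sample_qpopulation()].
#' @param task_config see [mdp_task_config()].
#' @param blocks_per_condition blocks per agent per condition.
#' @param seed integer seed for all simulation randomness.
#' @return a validated `behavioral_dataset` with generator metadata.
#' @export
build_mdp_dataset <- function(population, task_config = mdp_task_config(),
                              blocks_per_condition = 3, seed = 1) {
  force(population); force(task_config)  # before seeding: arguments may draw
  set.seed(seed)
  records <- lapply(seq_len(nrow(population)), function(i) {
    p <- population[i, ]
    simulate_agent(qparams(p$q_lr, p$q_dr, p$q_it, p$q_init), task_config,
                   n_blocks = blocks_per_condition,
                   participant_id = p$participant)
  })
  dataset_from_records(records, steps = task_config$conditions, task = "mdp",
                       metadata = c(seed = seed, generator = "qlearning_population",
                                    n = nrow(population),
                                    p_trans = task_config$p_trans))
}

#' Specification of a perceptual agent population
#'
#' Individuality model for the synthetic perceptual task: agent `i`
#' accumulates shared evidence scaled by gain `g_i` with private noise
#' `sigma_i`, responds at the first step where the running posterior's
#' maximum exceeds threshold `theta_i` (else at the final step), and lapses
#' to a uniform random action with probability `lambda_i`.
#'
#' @param n number of agents.
#' @param gain,noise,threshold,lapse distribution descriptors (see
#'   [population_spec()]); thresholds must lie in `(1/K, 1)`, lapse rates in
#'   `[0, 0.5)`.
#' @param seed integer seed.
#' @return list of class `perc_population_spec`.
#' @export
perceptual_population_spec <- function(n, gain = list("lnorm", 0, 0.25),
                                       noise = list("lnorm", log(0.4), 0.3),
                                       threshold = list("unif", 0.5, 0.95),
                                       lapse = list("unif", 0, 0.15),
                                       seed = 1) {
  structure(list(n = as.integer(n), gain = gain, noise = noise,
                 threshold = threshold, lapse = lapse, seed = as.integer(seed)),
            class = "perc_population_spec")
}

#' Sample perceptual agents
#' @param spec a [perceptual_population_spec()].
#' @return data.frame `participant, gain, noise, threshold, lapse`.
#' @export
sample_perceptual_population <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n
  out <- data.frame(participant = sprintf("p%04d", seq_len(n)),
                    gain = rdist(spec$gain, n),
                    noise = pmax(rdist(spec$noise, n), 1e-6),
                    threshold = pmin(pmax(rdist(spec$threshold, n), 0.1 + 1e-6),
                                     1 - 1e-6),
                    lapse = pmin(pmax(rdist(spec$lapse, n), 0), 0.5 - 1e-6))
  out
}

# one synthetic perceptual trial for agent row `p`
perc_agent_trial <- function(p, src, true_label) {
  E <- src$sample(true_label)
  S <- src$S; K <- src$K
  x <- numeric(K)
  t_resp <- S - 1L
  post <- NULL
  for (t in seq_len(S) - 1L) {
    x <- x + p$gain * E[, t + 1] + rnorm(K, 0, p$noise)
    post <- exp(x - max(x)); post <- post / sum(post)
    if (max(post) > p$threshold) { t_resp <- t; break }
  }
  action <- which.max(post) - 1L
  if (runif(1) < p$lapse) action <- sample.int(K, 1) - 1L
  list(action = action, rt = t_resp / 10)
}

#' Build a complete synthetic perceptual dataset
#'
#' @param population data.frame from [sample_perceptual_population()].
#' @param sources named list of [evidence_source()] objects, one per
#'   condition (shared across individuals; difficulty lives here).
#' @param trials_per_condition trials per agent per condition.
#' @param seed integer seed.
#' @return a validated perceptual `behavioral_dataset`.
#' @export
build_perceptual_dataset <- function(population, sources,
                                     trials_per_condition = 50, seed = 1) {
  force(population); force(sources)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(population))) {
    p <- population[i, ]
    for (cond in names(sources)) {
      src <- sources[[cond]]
      for (u in seq_len(trials_per_condition)) {
        lbl <- sample.int(src$K, 1) - 1L
        tr <- perc_agent_trial(p, src, lbl)
        rows[[length(rows) + 1L]] <-
          data.frame(participant = p$participant, condition = cond,
                     block = 0L, trial = u - 1L,
                     stimulus_id = sprintf("syn%d_%04d", lbl, u),
                     true_label = lbl, action = tr$action, rt = tr$rt)
      }
    }
  }
  new_behavioral_dataset(do.call(rbind, rows), task = "perceptual",
                         metadata = c(seed = seed,
                                      generator = "perceptual_population",
                                      n = nrow(population)))
}
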