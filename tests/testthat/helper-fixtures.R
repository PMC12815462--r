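# Shared fixtures, memoized across test files (built once per test run).

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# full entry table of an M-step environment with one shared p1
flat_env_entries <- function(M, p1 = 0.8) {
  env <- list(M = as.integer(M), p_trans = 0,
              trans = lapply(seq_len(M - 1), function(m)
                matrix(p1, 2^(m - 1), 2)),
              reward = matrix(p1, 2^(M - 1), 2))
  class(env) <- "mdp_env"
  env_entry_table(env)
}

# hand-crafted block: actions/rewards given, cues all zero after step 1
make_mdp_block <- function(condition, M, actions, rewards, rt = NA_real_,
                           p1 = 0.8) {
  n_ep <- length(actions) / M
  stopifnot(n_ep == round(n_ep), length(rewards) == n_ep)
  trials <- data.frame(episode = rep(seq_len(n_ep) - 1L, each = M),
                       step = rep(seq_len(M), n_ep),
                       cue = 0L, action = as.integer(actions),
                       reward = NA_integer_, rt = rt)
  trials$reward[trials$step == M] <- as.integer(rewards)
  structure(list(condition = condition, M = as.integer(M), trials = trials,
                 env_init = flat_env_entries(M, p1),
                 env_events = data.frame(episode = integer(), kind = character(),
                                         step = integer(), node = integer(),
                                         action = integer(), p1 = numeric())),
            class = "block_record")
}

make_record <- function(id, blocks)
  structure(list(participant_id = id, blocks = blocks),
            class = "individual_record")

# small fast synthetic pool for unit tests
tiny_mdp_dataset <- function(n = 6, episodes = 15, seed = 101) {
  pop <- sample_qpopulation(population_spec(n, seed = seed))
  build_mdp_dataset(pop, mdp_task_config(episodes_per_block = episodes),
                    seed = seed + 1)
}

# ---- study-scale fixtures shared by the acceptance tests -------------------
# One 100-agent population: agents 1..60 form the training pool, 61..100 the
# held-out pool.  The trained transfer models are reused across criteria.

acc_population <- function()
  memo_fixture("acc_population", sample_qpopulation(population_spec(100, seed = 11)))

acc_pool_ds <- function()
  memo_fixture("acc_pool_ds",
               build_mdp_dataset(acc_population()[1:60, ], seed = 12))

acc_holdout_ds <- function()
  memo_fixture("acc_holdout_ds",
               build_mdp_dataset(acc_population()[61:100, ], seed = 13))

acc_train_config <- function()
  eidt_config(lr = 0.005, lr_decay = 0.99, max_epochs = 150, patience = 30,
              seed = 21)

acc_model_23 <- function()
  memo_fixture("acc_model_23",
               train_eidt(acc_pool_ds(), "2step", "3step", acc_train_config()))

acc_model_32 <- function()
  memo_fixture("acc_model_32",
               train_eidt(acc_pool_ds(), "3step", "2step", acc_train_config()))
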