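test_that("dataset writing and reading round-trips exactly and is byte-stable", {
  ds <- tiny_mdp_dataset(n = 3, episodes = 8)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_dataset(ds, f1)
  ds2 <- read_dataset(f1)
  expect_equal(ds2$trials, ds$trials)
  expect_equal(ds2$envs, ds$envs)
  expect_identical(ds2$steps, ds$steps)
  expect_identical(ds2$metadata, ds$metadata)
  write_dataset(ds2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("an empty dataset with a valid header reads back with 0 individuals", {
  empty <- data.frame(participant = character(), condition = character(),
                      block = integer(), episode = integer(), step = integer(),
                      cue = integer(), action = integer(), reward = integer(),
                      rt = numeric())
  envs <- data.frame(participant = character(), condition = character(),
                     block = integer(), episode = integer(), kind = character(),
                     step = integer(), node = integer(), action = integer(),
                     p1 = numeric())
  ds <- new_behavioral_dataset(empty, envs, steps = c("2step" = 2, "3step" = 3))
  f <- withr::local_tempfile()
  write_dataset(ds, f)
  expect_length(individual_ids(read_dataset(f)), 0)
})

test_that("malformed files raise parse errors naming the line", {
  f <- withr::local_tempfile()
  writeLines(c("#eidt-dataset v1", "#task mdp", "#condition 2step 2",
               "#columns trials participant condition block episode step cue action reward rt",
               "p1\t2step\t0\t0\t1\t0\t0\tNA"), f)  # 8 fields, not 9
  expect_error(read_dataset(f), "line 5")
  writeLines("not a dataset", f)
  expect_error(read_dataset(f), "line 1")
})

test_that("reward on a non-final step is rejected", {
  blk <- make_mdp_block("2step", 2, actions = c(0, 1), rewards = 1)
  blk$trials$reward <- c(1L, 1L)  # reward leaked onto step 1
  expect_error(
    dataset_from_records(list(make_record("p1", list(blk))),
                         steps = c("2step" = 2)),
    "non-final")
})

test_that("unknown condition labels and duplicate ids are rejected", {
  blk <- make_mdp_block("4step?", 2, actions = c(0, 1), rewards = 1)
  expect_error(dataset_from_records(list(make_record("p1", list(blk))),
                                    steps = c("2step" = 2)),
               "condition")
  blk2 <- make_mdp_block("2step", 2, actions = c(0, 1), rewards = 1)
  expect_error(dataset_from_records(list(make_record("p1", list(blk2)),
                                         make_record("p1", list(blk2))),
                                    steps = c("2step" = 2)),
               "duplicate")
})

test_that("participant_stats summarizes reward, bias, and response time per block", {
  all_rewarded <- make_mdp_block("2step", 2, actions = rep(0:1, 10),
                                 rewards = rep(1, 10))
  st <- participant_stats(make_record("p", list(all_rewarded)))
  expect_equal(st$mean_reward, 1.0)
  expect_equal(st$bias_pct, 50)  # alternating actions
  # 50-episode 2-step block with 30 rewards
  blk <- make_mdp_block("2step", 2, actions = rep(0, 100),
                        rewards = rep(c(1, 0), c(30, 20)))
  st <- participant_stats(make_record("p", list(blk)))
  expect_equal(st$mean_reward, 0.6)
  expect_equal(st$bias_pct, 100)
  expect_error(participant_stats(make_record("p", list())), "blocks")
})

test_that("iqr_ranges follows the linear-interpolation quartile convention", {
  expect_equal(unname(iqr_ranges(rep(3.5, 10))), c(3.5, 3.5))
  r <- iqr_ranges(c(1, 2, 3, 4, 100), k = 1.5)
  expect_equal(unname(r), c(-1, 7))   # Q1 = 2, Q3 = 4 under type-7 quartiles
  expect_true(100 > r["high"])
  expect_error(iqr_ranges(numeric(0)), "empty")
  # translation equivariance
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(20); c0 <- rnorm(1)
    expect_equal(unname(iqr_ranges(x + c0)), unname(iqr_ranges(x)) + c0)
  }
})

test_that("exclusion removes individuals whose any block breaks any bound", {
  ok_actions <- rep(c(0, 1, 1, 0), 5)             # bias 50%
  biased <- rep(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1), 2)  # bias 90%
  recs <- c(
    lapply(1:3, function(i)
      make_record(paste0("ok", i),
                  list(make_mdp_block("2step", 2, ok_actions, rewards = rep(1, 10))))),
    lapply(1:2, function(i)
      make_record(paste0("bad", i),
                  list(make_mdp_block("2step", 2, ok_actions, rewards = rep(1, 10)),
                       make_mdp_block("2step", 2, biased, rewards = rep(1, 10))))))
  ds <- dataset_from_records(recs, steps = c("2step" = 2))
  thr <- list(reward = list("2step" = c(0, 1)), bias = c(26.3, 73.3), rt = NULL)
  res <- apply_exclusion(ds, thr)
  expect_length(individual_ids(res$dataset), 3)
  expect_setequal(res$report$excluded$participant, c("bad1", "bad2"))
  expect_true(all(res$report$excluded$reason == "bias"))
  # retained + excluded = input; idempotent on the retained set
  expect_equal(length(individual_ids(res$dataset)) + nrow(res$report$excluded),
               length(individual_ids(ds)))
  res2 <- apply_exclusion(res$dataset, thr)
  expect_equal(res2$dataset$trials, res$dataset$trials)
  expect_equal(nrow(res2$report$excluded), 0)
})

test_that("exclusion reasons follow the fixed reward > bias > response-time order", {
  # one agent violating both reward and bias bounds reports the reward reason
  blk <- make_mdp_block("2step", 2, rep(0, 20), rewards = rep(0, 10))
  ds <- dataset_from_records(list(make_record("p1", list(blk))),
                             steps = c("2step" = 2))
  thr <- list(reward = list("2step" = c(0.4, 1)), bias = c(26.3, 73.3), rt = NULL)
  res <- apply_exclusion(ds, thr)
  expect_equal(res$report$excluded$reason, "reward")
})

test_that("data-driven thresholds flag planted outliers", {
  set.seed(42)
  # identical reward/bias profiles so only response time can trigger
  acts <- rep(c(0, 1), 20)
  rews <- rep(c(1, 0), 10)
  recs <- lapply(1:12, function(i) {
    make_record(paste0("a", i),
                make_mdp_block("2step", 2, acts, rewards = rews,
                               rt = runif(40, 0.4, 0.8)) |> list())
  })
  # plant one extreme-RT individual
  slow <- make_mdp_block("2step", 2, acts, rewards = rews, rt = rep(9.5, 40))
  recs[[13]] <- make_record("slow", list(slow))
  ds <- dataset_from_records(recs, steps = c("2step" = 2))
  thr <- compute_exclusion_thresholds(ds)
  res <- apply_exclusion(ds, thr)
  expect_true("slow" %in% res$report$excluded$participant)
  expect_equal(res$report$excluded$reason[res$report$excluded$participant == "slow"],
               "response_time")
})
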