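test_that("response-time binning rounds at 10 steps per second and clips", {
  expect_identical(rt_to_step(0.765), 8L)
  expect_identical(rt_to_step(0), 0L)
  expect_identical(rt_to_step(3.0, S = 16), 15L)
  expect_identical(rt_to_step(0.25), 2L)  # ties go to even
  expect_error(rt_to_step(-0.1), "non-negative")
  # monotone non-decreasing
  b <- sort(runif(50, 0, 2))
  expect_true(all(diff(rt_to_step(b)) >= 0))
})

test_that("evidence sources meet the stochastic contract", {
  src <- gaussian_evidence_source(gain = 1, noise = 0.5)
  set.seed(70)
  E1 <- src$sample(3); E2 <- src$sample(3)
  expect_equal(dim(E1), c(10, 16))
  expect_false(identical(E1, E2))
  expect_gt(mean(E1[4, ]), mean(E1[5, ]))  # signal on the true class
})

test_that("the accumulator normalizes and matches the reference recurrence", {
  arch <- accumulator_arch()
  set.seed(71)
  w <- solver_weights(rnorm(arch$n_weights, 0, 0.5), arch)
  E <- matrix(rnorm(16 * 10), 16, 10)  # S x K
  P <- accumulate(w, E)
  expect_equal(dim(P), c(16, 10))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_identical(P, accumulate(w, E))
  Pref <- ref_solver_probs(w$theta, arch$I, arch$Q, arch$K, t(E))
  expect_lt(max(abs(P - Pref)), 1e-10)
  # zero readout: uniform 0.1 at every step
  w0 <- w
  w0$theta[(arch$n_weights - arch$K * arch$Q + 1):arch$n_weights] <- 0
  expect_true(all(abs(accumulate(w0, E) - 0.1) < 1e-12))
  expect_error(accumulate(w, E[, 1:3]), "columns")
})

test_that("trial likelihood reads the probability at the binned step", {
  P <- matrix(1 / 10, 16, 10)
  expect_equal(trial_likelihood(P, list(action = 4, rt = 0.5)), 0.1)
  P2 <- P; P2[9, 4] <- 0.42  # step t~ = 8, action 3
  expect_equal(trial_likelihood(P2, list(action = 3, rt = 0.765)), 0.42)
  P3 <- matrix(0, 16, 10); P3[1, 1] <- 1
  expect_equal(trial_likelihood(P3, list(action = 0, rt = 0)), 1)
})

# minimal perceptual model with random weights for inference-path tests
random_perc_model <- function(seed = 72) {
  sources <- list(easy = gaussian_evidence_source(1, 0.4),
                  difficult = gaussian_evidence_source(0.4, 0.4))
  cfg <- eidt_config(encoder_cells = 16, head_hidden = integer(0), seed = seed)
  m <- eidt:::new_perc_model("easy", "difficult", sources, cfg)
  set.seed(seed)
  m$par <- eidt:::init_eidt_par(m)
  m
}

test_that("set encoding averages hidden states over trials", {
  m <- random_perc_model()
  trials <- data.frame(true_label = c(2, 7, 4), action = c(2, 7, 1),
                       rt = c(0.3, 0.8, 1.2))
  set.seed(73)
  ev <- lapply(trials$true_label, m$sources$easy$sample)
  z <- set_encode(m, trials, evidence = ev)
  expect_length(z, 2)
  # permuting trial order leaves z unchanged (evidence held fixed)
  perm <- c(3, 1, 2)
  expect_equal(set_encode(m, trials[perm, ], evidence = ev[perm]), z,
               tolerance = 1e-12)
  # duplicated trials equal the single-trial encoding (mean invariance)
  z1 <- set_encode(m, trials[1, , drop = FALSE], evidence = ev[1])
  z1d <- set_encode(m, trials[c(1, 1), ], evidence = ev[c(1, 1)])
  expect_equal(z1d, z1, tolerance = 1e-12)
  # the gated action channel is zero off the response step
  sl <- eidt:::perc_encoder_slice(ev[[1]], action = 2, tstep = 3, K = 10)
  expect_equal(sl[13, 4], 1)
  expect_true(all(sl[11:20, -4] == 0))
})

test_that("synthetic perceptual agents behave per their individuality model", {
  src <- list(easy = gaussian_evidence_source(gain = 30, noise = 0.3))
  sharp <- data.frame(participant = "s1", gain = 5, noise = 1e-6,
                      threshold = 0.5, lapse = 0)
  set.seed(74)
  ds <- build_perceptual_dataset(sharp, src, trials_per_condition = 30)
  expect_true(all(ds$trials$action == ds$trials$true_label))
  expect_true(all(ds$trials$rt == 0))
  # higher thresholds produce stochastically slower responses
  spec <- perceptual_population_spec(1)
  lo <- data.frame(participant = "t1", gain = 1, noise = 0.4,
                   threshold = 0.55, lapse = 0)
  hi <- data.frame(participant = "t2", gain = 1, noise = 0.4,
                   threshold = 0.995, lapse = 0)
  srcs <- list(easy = gaussian_evidence_source(0.5, 0.4))
  set.seed(75)
  ds_lo <- build_perceptual_dataset(lo, srcs, trials_per_condition = 400)
  set.seed(76)
  ds_hi <- build_perceptual_dataset(hi, srcs, trials_per_condition = 400)
  expect_gt(median(ds_hi$trials$rt), median(ds_lo$trials$rt))
  # determinism
  set.seed(77); a <- build_perceptual_dataset(lo, srcs, 20)
  set.seed(77); b <- build_perceptual_dataset(lo, srcs, 20)
  expect_identical(a, b)
})

test_that("perceptual transfer training beats a group-agnostic solver", {
  # two planted groups: fast guessers and slow accurates
  pop <- data.frame(participant = sprintf("g%02d", 1:16),
                    gain = rep(c(0.45, 1.3), each = 8),
                    noise = 0.35,
                    threshold = rep(c(0.55, 0.93), each = 8),
                    lapse = rep(c(0.25, 0.02), each = 8))
  sources <- list(easy = gaussian_evidence_source(1, 0.35),
                  difficult = gaussian_evidence_source(0.45, 0.35))
  ds <- build_perceptual_dataset(pop, sources, trials_per_condition = 40,
                                 seed = 78)
  m <- train_perceptual_eidt(ds, "easy", "difficult", sources,
                             config = eidt_config(encoder_cells = 16,
                                                  head_hidden = integer(0),
                                                  lr = 0.01, max_epochs = 80,
                                                  patience = 80, seed = 79))
  base <- train_perceptual_baseline(ds, "easy", sources,
                                    list(max_epochs = 120, seed = 80))
  set.seed(81)
  wins <- 0
  for (id in individual_ids(ds)) {
    tr <- ds$trials
    srcd <- tr[tr$participant == id & tr$condition == "easy", ]
    tgtd <- tr[tr$participant == id & tr$condition == "difficult", ]
    z <- set_encode(m, srcd)
    lik_e <- predict_perceptual(m, z, tgtd)
    lik_b <- vapply(seq_len(nrow(tgtd)), function(u) {
      probs <- accumulate(base, t(sources$difficult$sample(tgtd$true_label[u])))
      trial_likelihood(probs, tgtd[u, ])
    }, 0)
    wins <- wins + (mean(-log(pmax(lik_e, 1e-12))) <
                      mean(-log(pmax(lik_b, 1e-12))))
  }
  expect_gte(wins / 16, 0.6)
})

test_that("perceptual training is deterministic given its seed", {
  pop <- sample_perceptual_population(perceptual_population_spec(10, seed = 82))
  sources <- list(easy = gaussian_evidence_source(1, 0.4),
                  difficult = gaussian_evidence_source(0.5, 0.4))
  ds <- build_perceptual_dataset(pop, sources, trials_per_condition = 10,
                                 seed = 83)
  cfg <- eidt_config(encoder_cells = 16, head_hidden = integer(0),
                     max_epochs = 3, patience = 3, seed = 84)
  m1 <- train_perceptual_eidt(ds, "easy", "difficult", sources, cfg)
  m2 <- train_perceptual_eidt(ds, "easy", "difficult", sources, cfg)
  expect_identical(m1$par, m2$par)
  expect_equal(min(m1$log$val), m1$log$val[m1$log$epoch == which.min(m1$log$val)][1])
})
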