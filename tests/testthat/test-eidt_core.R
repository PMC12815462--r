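# An untrained model with seeded random parameters: inference-path behavior
# (purity, affine identities) must hold for any parameter values.
random_eidt_model <- function(seed = 50, source = "2step", target = "3step") {
  cfg <- eidt_config(seed = seed)
  m <- eidt:::new_eidt_model(source, target, c("2step" = 2, "3step" = 3), cfg)
  set.seed(seed)
  m$par <- eidt:::init_eidt_par(m)
  m
}

sample_block <- function(M = 2, cond = "2step", seed = 51, n = 10) {
  run_block(init_environment(M, 0.2, seed = seed),
            function(s, c) c(0.5, 0.5), n, condition = cond)
}

test_that("encoding is pure and driven by the head parameters", {
  m <- random_eidt_model()
  blk <- sample_block()
  z1 <- encode_sequence(m, blk)
  expect_identical(z1, encode_sequence(m, blk))
  expect_length(z1, 2)
  # zero head weights: z equals the output-layer bias for every block
  d <- eidt:::eidt_dims(m)
  hs <- m$head_sizes
  n_head <- sum(hs[-1] * hs[-length(hs)] + hs[-1])
  m0 <- m
  m0$par[(d$n_enc - n_head + 1):d$n_enc] <- 0
  bias_idx <- (d$n_enc - hs[length(hs)] + 1):d$n_enc
  m0$par[bias_idx] <- c(0.3, -0.2)
  expect_equal(encode_sequence(m0, blk), c(0.3, -0.2))
  expect_equal(encode_sequence(m0, sample_block(seed = 52)), c(0.3, -0.2))
  # a single changed action changes the latent under generic weights
  blk2 <- blk
  blk2$trials$action[7] <- 1L - blk2$trials$action[7]
  expect_false(isTRUE(all.equal(z1, encode_sequence(m, blk2))))
  expect_error(encode_sequence(m, sample_block(3, "3step", 53)), "source")
})

test_that("the decoder is affine with the documented identities", {
  m <- random_eidt_model()
  z0 <- decode_weights(m, c(0, 0))$theta
  z1 <- c(0.7, -0.3); z2 <- c(-1.1, 0.4)
  lhs <- decode_weights(m, z1 + z2)$theta - z0
  rhs <- (decode_weights(m, z1)$theta - z0) + (decode_weights(m, z2)$theta - z0)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  expect_length(z0, m$arch_tgt$n_weights)
  expect_error(decode_weights(m, c(1, 2, 3)), "dimension")
})

test_that("individual latents average the per-block encodings", {
  m <- random_eidt_model()
  b1 <- sample_block(seed = 54); b2 <- sample_block(seed = 55)
  b3 <- sample_block(seed = 56)
  rec1 <- make_record("r1", list(b1))
  expect_equal(individual_latent(m, rec1), encode_sequence(m, b1))
  recdup <- make_record("r2", list(b1, b1))
  expect_equal(individual_latent(m, recdup), encode_sequence(m, b1))
  rec3 <- make_record("r3", list(b1, b2, b3))
  zc <- (encode_sequence(m, b1) + encode_sequence(m, b2) +
           encode_sequence(m, b3)) / 3
  expect_equal(individual_latent(m, rec3), zc)
})

test_that("transfer predictions normalize and depend only on source behavior", {
  m <- random_eidt_model()
  src <- sample_block(seed = 57)
  tgt <- sample_block(3, "3step", 58)
  recA <- make_record("A", list(src))
  recB <- make_record("B", list(src))
  P <- transfer_predict(m, recA, tgt)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_identical(P, transfer_predict(m, recB, tgt))
  expect_error(transfer_predict(m, recA, src), "target")
})

test_that("the pair loss is the mean per-trial cross-entropy", {
  m <- random_eidt_model()
  src <- sample_block(seed = 59)
  tgt <- sample_block(3, "3step", 60)
  # zero decoder -> solver weights all zero -> uniform predictions -> ln 2
  d <- eidt:::eidt_dims(m)
  m0 <- m
  m0$par[(d$n_enc + 1):length(m0$par)] <- 0
  expect_equal(eidt_loss(m0, src, tgt), log(2), tolerance = 1e-12)
  # consistency with the inference path
  w <- decode_weights(m, encode_sequence(m, src))
  expect_equal(eidt_loss(m, src, tgt),
               nll_metric(forward_teacher(w, tgt), tgt$trials$action),
               tolerance = 1e-12)
})

test_that("training is deterministic and improves validation loss", {
  ds <- tiny_mdp_dataset(n = 10, episodes = 8, seed = 61)
  cfg <- eidt_config(max_epochs = 3, patience = 3, seed = 62)
  m1 <- train_eidt(ds, "2step", "3step", cfg)
  m2 <- train_eidt(ds, "2step", "3step", cfg)
  expect_identical(m1$par, m2$par)
  expect_lte(min(m1$log$val), m1$log$val[1])
  expect_error(train_eidt(tiny_mdp_dataset(n = 4, episodes = 5, seed = 63),
                          "2step", "3step", cfg), "at least 10")
})

test_that("transfer carries planted choice tendencies to held-out individuals", {
  # two groups with opposite static action biases, identical in both
  # conditions; the pipeline must route each held-out individual's bias
  # from its source blocks to its target-condition predictions
  bias_record <- function(id, p_c1, seed) {
    set.seed(seed)
    blocks <- list()
    for (cond in c("2step", "3step")) {
      M <- if (cond == "2step") 2 else 3
      for (b in 1:3) {
        blk <- run_block(init_environment(M, 0.2),
                         function(s, c) c(p_c1, 1 - p_c1), 20,
                         condition = cond)
        blocks[[length(blocks) + 1L]] <- blk
      }
    }
    make_record(id, blocks)
  }
  train_recs <- lapply(1:14, function(i)
    bias_record(paste0("t", i), if (i <= 7) 0.85 else 0.15, 500 + i))
  ds <- dataset_from_records(train_recs, steps = c("2step" = 2, "3step" = 3))
  m <- train_eidt(ds, "2step", "3step",
                  eidt_config(max_epochs = 40, patience = 40, lr = 0.005,
                              seed = 66))
  ok <- 0
  for (i in 1:6) {
    up <- i <= 3
    rec <- bias_record(paste0("h", i), if (up) 0.85 else 0.15, 600 + i)
    tgt <- Filter(function(b) identical(b$condition, "3step"), rec$blocks)[[1]]
    P <- transfer_predict(m, rec, tgt)
    ok <- ok + ((mean(P[, 1]) > 0.5) == up)
  }
  expect_gte(ok, 5)
})
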