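test_that("the trial-wise metrics behave per their closed forms", {
  P <- matrix(c(0.8, 0.2,
                0.5, 0.5,
                0.3, 0.7), 3, 2, byrow = TRUE)
  acts <- c(0L, 0L, 1L)
  expect_equal(nll_metric(P[1:2, ], c(0L, 0L)), -(log(0.8) + log(0.5)) / 2)
  expect_equal(round(nll_metric(P[1:2, ], c(0L, 0L)), 4), 0.4581)
  expect_equal(nll_metric(matrix(0.5, 4, 2), rep(0L, 4)), log(2))
  perfect <- matrix(c(1, 0), 3, 2, byrow = TRUE)
  expect_equal(nll_metric(perfect, rep(0L, 3)), 0)
  expect_equal(match_rate(perfect, rep(0L, 3)), 1)
  expect_equal(match_rate(perfect, rep(1L, 3)), 0)
  expect_equal(match_rate(P, c(0L, 0L, 1L)), 1)   # tie at trial 2 -> C1
  expect_equal(match_rate(P, c(0L, 1L, 1L)), 2 / 3)
  # 3 of 4 matched
  P4 <- matrix(c(0.9, 0.1, 0.9, 0.1, 0.9, 0.1, 0.1, 0.9), 4, 2, byrow = TRUE)
  expect_equal(match_rate(P4, c(0L, 0L, 0L, 0L)), 0.75)
  # permutation equivariance of the means
  set.seed(90)
  p1 <- runif(20)
  Pr <- cbind(p1, 1 - p1)
  a <- rbinom(20, 1, 0.5)
  o <- sample(20)
  expect_equal(nll_metric(Pr[o, ], a[o]), nll_metric(Pr, a))
  expect_equal(match_rate(Pr[o, ], a[o]), match_rate(Pr, a))
  expect_error(nll_metric(Pr, a[1:3]), "mismatch")
  # zero probability on a taken action flags infinity unless clamped
  P0 <- matrix(c(0, 1), 1, 2)
  expect_equal(nll_metric(P0, 0L), Inf)
  expect_lt(nll_metric(P0, 0L, clamp = 1e-10), Inf)
})

test_that("cross-individual matrices have symmetric distances and a zero diagonal", {
  ds <- tiny_mdp_dataset(n = 4, episodes = 6, seed = 91)
  cfg <- eidt_config(seed = 92)
  m <- eidt:::new_eidt_model("2step", "3step", ds$steps, cfg)
  set.seed(92)
  m$par <- eidt:::init_eidt_par(m)
  res <- cross_individual_matrix(m, ds)
  expect_equal(diag(res$d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(res$d, t(res$d))
  # y_{k,l} agrees with the direct transfer computation for one pair
  ids <- res$ids
  rec_k <- get_individual(ds, ids[2])
  w_l <- decode_weights(m, res$z[3, ])
  blocks <- Filter(function(b) identical(b$condition, "3step"), rec_k$blocks)
  P <- do.call(rbind, lapply(blocks, function(b) forward_teacher(w_l, b)))
  acts <- unlist(lapply(blocks, function(b) b$trials$action))
  expect_equal(res$nll[2, 3], nll_metric(P, acts), tolerance = 1e-12)
  expect_equal(res$match[2, 3], match_rate(P, acts))
})

test_that("the distance regression recovers a planted coefficient", {
  # simulate from the fitted family: y ~ Gamma(mean = exp(b0 + bk + bd * d))
  gen <- function(seed, beta_d) {
    set.seed(seed)
    npart <- 40; per <- 25
    bk <- rnorm(npart, 0, 0.2); bk <- bk - mean(bk)
    d <- abs(rnorm(npart * per, 1, 0.5))
    k <- rep(seq_len(npart), each = per)
    mu <- exp(-0.5 + bk[k] + beta_d * d)
    shape <- 8
    y <- rgamma(length(mu), shape = shape, rate = shape / mu)
    list(ids = sprintf("p%02d", seq_len(npart)),
         y = y, d = d, k = k)
  }
  fit_one <- function(sim) {
    df <- data.frame(y = sim$y, d = sim$d,
                     participant = factor(sim$ids[sim$k]))
    fit <- glm(y ~ participant + d, data = df, family = Gamma(link = "log"),
               contrasts = list(participant = "contr.sum"))
    s <- summary(fit)$coefficients["d", ]
    c(est = s[["Estimate"]], se = s[["Std. Error"]], p = s[["Pr(>|t|)"]])
  }
  cover <- 0
  for (r in 1:100) {
    f <- fit_one(gen(1000 + r, beta_d = 0.3))
    ci <- f[["est"]] + c(-1.96, 1.96) * f[["se"]]
    cover <- cover + (ci[1] <= 0.3 && 0.3 <= ci[2])
  }
  expect_gte(cover, 90)
  # null: no distance effect
  nulls <- vapply(1:60, function(r) {
    f <- fit_one(gen(3000 + r, beta_d = 0))
    abs(f[["est"]] / f[["se"]])
  }, 0)
  expect_gte(mean(nulls < 3), 0.95)
})

test_that("fit_distance_glm rejects a singular design", {
  fake <- structure(list(ids = c("a", "b", "c"),
                         z = matrix(0, 3, 2),
                         nll = matrix(0.5, 3, 3),
                         match = matrix(0.5, 3, 3),
                         d = matrix(0, 3, 3)),
                    class = "cross_individual_result")
  expect_error(fit_distance_glm(fake, "nll"), "constant")
})

test_that("on-policy comparisons correlate matched behavior", {
  set.seed(93)
  blocks <- lapply(1:6, function(i)
    run_block(init_environment(2, 0.3), function(s, c) c(0.5, 0.5), 20,
              condition = "2step"))
  res <- onpolicy_compare(blocks, blocks)
  expect_equal(res$reward_cor$r, 1)
  expect_equal(res$high_rate_cor$r, 1)
  expect_true(all(res$table$reward_orig == res$table$reward_model))
  expect_error(onpolicy_compare(blocks, blocks[1:3]), "paired")
  # shuffling the model column kills the correlation
  set.seed(94)
  many <- lapply(1:60, function(i)
    run_block(init_environment(2, 0.3),
              function(s, c) if (i %% 2) c(0.8, 0.2) else c(0.3, 0.7), 15,
              condition = "2step"))
  shuf <- onpolicy_compare(many, many[sample(60)])
  expect_lt(abs(shuf$reward_cor$r), 0.45)
})

test_that("the latent-parameter regression recovers a planted mapping", {
  set.seed(95)
  n <- 120
  params <- data.frame(q_lr = runif(n, 0.1, 0.9), q_it = rlnorm(n, 1, 0.4))
  z <- cbind(2 * params$q_lr + rnorm(n, 0, 0.05),
             rnorm(n, 0, 0.05))
  lp <- latent_param_glm(z, params)
  co <- lp$coef$z1
  expect_lt(abs(co["q_lr", "Estimate"] - 2), 0.3)
  expect_lt(co["q_lr", "Pr(>|t|)"], 1e-6)
  expect_gt(co["q_it", "Pr(>|t|)"], 1e-4)
  expect_error(latent_param_glm(z[1:10, ], params[1:10, ]), "20")
  degen <- params; degen$q_lr <- 0.5
  expect_error(latent_param_glm(z, degen), "degenerate")
})
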