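test_that("weight initialization honours topology, scaling and seed", {
  cfg <- esn_config(n_reservoir = 36L, spectral_radius = 0.66, seed = 4,
                    k = 4L, p = 0)
  w <- init_esn(cfg)
  # spectral-radius contract after rescaling
  ev <- eigen(w$W, only.values = TRUE)$values
  expect_equal(max(Mod(ev)), 0.66, tolerance = 1e-9)
  # p = 0 Watts-Strogatz: a ring lattice where every node has 4 neighbours
  degree <- rowSums(w$W != 0)
  expect_true(all(degree == 4))
  expect_true(all(w$W == t(w$W) | (w$W != 0) == t(w$W != 0)))
  # determinism
  w2 <- init_esn(cfg)
  expect_identical(w$W, w2$W)
  expect_identical(w$W_in, w2$W_in)
  expect_identical(w$W_fb, w2$W_fb)
  # readout starts empty
  expect_identical(w$W_out, matrix(0, 1, 37))

  wr <- init_esn(esn_config(n_reservoir = 50L, topology = "random",
                            density = 0.1, spectral_radius = 0.3, seed = 1))
  expect_equal(max(Mod(eigen(wr$W, only.values = TRUE)$values)), 0.3,
               tolerance = 1e-9)
  expect_lt(mean(wr$W != 0), 0.2)
})

test_that("the state update follows the typeset (non-premultiplied) form", {
  cfg <- esn_config(n_reservoir = 2L, leak_rate = 0.5, seed = 1,
                    topology = "random", density = 1)
  w <- init_esn(cfg)
  w$W <- matrix(c(0, 0, 1, 0), 2, 2)  # W[1,2] = 1
  w$W_in <- matrix(0, 2, 1)
  w$W_fb <- matrix(0, 2, 1)
  x <- esn_step(c(0, 0.5), 0, 0, w)
  expect_equal(x, c(tanh(0.5), 0.25))

  # conventional leaky form premultiplies the activation by a
  w$config$conventional_leak <- TRUE
  xc <- esn_step(c(0, 0.5), 0, 0, w)
  expect_equal(xc, c(0.5 * tanh(0.5), 0.25))

  # a = 1, zero weights: the state collapses to tanh(0) = 0
  cfg0 <- esn_config(n_reservoir = 3L, leak_rate = 1, seed = 1,
                     topology = "random", density = 1)
  w0 <- init_esn(cfg0)
  w0$W[] <- 0; w0$W_in[] <- 0; w0$W_fb[] <- 0
  expect_equal(esn_step(c(1, -1, 2), 5, 3, w0), c(0, 0, 0))
})

test_that("teacher forcing is deterministic and zero stays zero", {
  cfg <- esn_config(n_reservoir = 8L, seed = 2, bias_level = 0)
  w <- init_esn(cfg)
  tr0 <- teacher_force(w, rep(0, 20))
  expect_identical(tr0$states, matrix(0, 20, 8))

  teach <- sin(seq(0, 4, length.out = 50))
  tr1 <- teacher_force(w, teach)
  tr2 <- teacher_force(w, teach)
  expect_identical(tr1$states, tr2$states)
  expect_equal(nrow(tr1$states), 50)
  # tanh update with a = 1 keeps states inside (-1, 1)
  expect_true(all(abs(tr1$states) < 1))
})

test_that("readout fitting recovers exact linear targets and shrinks", {
  cfg <- esn_config(n_reservoir = 6L, seed = 5, washout = 5L,
                    ridge_lambda = 0)
  w <- init_esn(cfg)
  teach <- sin(seq(0, 10, length.out = 80))
  tr <- teacher_force(w, teach)
  W_true <- matrix(rnorm(7), 1, 7)
  targets <- drop(W_true %*% t(cbind(tr$states, tr$inputs)))
  W_hat <- fit_readout(tr, targets = targets, config = cfg)
  expect_equal(W_hat, W_true, tolerance = 1e-8)

  # ridge shrinkage: the coefficient norm never grows with lambda
  norms <- sapply(c(0, 1e-6, 1e-3, 1), function(l) {
    cfg$ridge_lambda <- l
    sqrt(sum(fit_readout(tr, config = cfg)^2))
  })
  expect_true(all(diff(norms) <= 1e-8))

  # fitted readout beats the zero readout on the training data
  W_fit <- fit_readout(tr, config = cfg)
  Z <- cbind(tr$states, tr$inputs)[6:80, ]
  expect_lt(mean((teach[6:80] - drop(Z %*% t(W_fit)))^2),
            mean(teach[6:80]^2))
})

test_that("a rank-deficient design with no ridge advises regularisation", {
  cfg <- esn_config(n_reservoir = 4L, seed = 1, washout = 2L,
                    ridge_lambda = 0, topology = "random", density = 1)
  w <- init_esn(cfg)
  w <- lesion_esn(w, 1:4)  # dead reservoir: state columns all zero
  tr <- teacher_force(w, sin(seq_len(30) / 3), input = rep(0, 30))
  expect_error(fit_readout(tr, config = cfg), class = "tsmsa_numerical_rank")
})

test_that("lesioning zeroes a node's rows and columns and nothing else", {
  cfg <- esn_config(n_reservoir = 10L, seed = 7)
  w <- init_esn(cfg)
  les <- lesion_esn(w, 3L)
  expect_true(all(les$W[3, ] == 0))
  expect_true(all(les$W[, 3] == 0))
  expect_true(all(les$W_in[3, ] == 0))
  expect_true(all(les$W_fb[3, ] == 0))
  keep <- setdiff(1:10, 3)
  expect_identical(les$W[keep, keep], w$W[keep, keep])
  expect_identical(les$W_in[keep, , drop = FALSE],
                   w$W_in[keep, , drop = FALSE])
  # original untouched; idempotent; strict-W-only flag leaves inputs alive
  expect_false(all(w$W[3, ] == 0))
  expect_identical(lesion_esn(les, 3L), les)
  strict <- lesion_esn(w, 3L, include_io = FALSE)
  expect_identical(strict$W_in, w$W_in)
  expect_error(lesion_esn(w, 11L), class = "tsmsa_invalid_argument")
})

test_that("free run without recurrence or feedback settles immediately", {
  cfg <- esn_config(n_reservoir = 5L, seed = 9, bias_level = 0.3)
  w <- init_esn(cfg)
  w$W[] <- 0; w$W_fb[] <- 0
  w$W_out <- matrix(rnorm(6), 1, 6)
  run <- free_run(w, 10)
  expect_false(run$divergent)
  expect_equal(drop(run$output)[2:10], rep(drop(run$output)[2], 9))
})

test_that("divergent free runs are flagged and clamped, not errors", {
  cfg <- esn_config(n_reservoir = 4L, seed = 2, topology = "random",
                    density = 1)
  w <- init_esn(cfg)
  w$W_out <- matrix(1e8, 1, 5)  # absurd readout forces guard violation
  run <- free_run(w, 5, guard = 1e6)
  expect_true(run$divergent)
  expect_true(all(is.finite(run$output)))
  expect_true(all(abs(run$output) <= 1e6))
})

test_that("the ESN game is consistent with the intact network", {
  trained <- tiny_trained_esn(seed = 6, n_reservoir = 12L, n_train = 400L)
  game <- esn_game(trained, horizon = 100L)
  intact <- continue_esn(trained, 100L)
  # no-op lesion reproduces the intact free run bitwise
  expect_identical(game$play(integer()), drop(intact$output))
  # deterministic on repeat
  expect_identical(game$play(c(2L, 5L)), game$play(c(2L, 5L)))
  # full lesion: output carried by the bias-through-readout path only
  dead <- game$play(seq_len(12L))
  expect_equal(length(dead), 100L)
  expect_lt(sd(dead[-1]), 1e-10)
})

test_that("training records a reproducible MSE and tidy readout", {
  trained <- tiny_trained_esn(seed = 8, n_reservoir = 12L, n_train = 400L)
  g <- glance(trained)
  expect_equal(g$n_reservoir, 12L)
  expect_true(g$train_mse >= 0 && is.finite(g$train_mse))
  td <- tidy(trained)
  expect_equal(nrow(td), 13L)  # 12 reservoir + 1 input weight
  expect_equal(td$estimate, drop(trained$weights$W_out))
})

test_that("grid search reports every cell and finds the echo-state regime", {
  teach <- mackey_glass(700)$value - 1
  cfg <- esn_config(n_reservoir = 12L, conventional_leak = TRUE)
  gs <- grid_search_esn(cfg, rho_grid = c(0.5, 0.9), leak_grid = c(0.3, 1),
                        n_instances = 3, seed = 21,
                        eval_fun = function(c) mg_instance_mse(c, teach, 200))
  expect_equal(nrow(tidy(gs)), 12)  # 4 cells x 3 instances
  expect_true(gs$best_rho %in% c(0.5, 0.9))
  # single-cell grid returns that cell
  gs1 <- grid_search_esn(cfg, 0.7, 1, n_instances = 2, seed = 3,
                         eval_fun = function(c) mg_instance_mse(c, teach, 200))
  expect_equal(gs1$best_rho, 0.7)
  expect_equal(gs1$best_leak, 1)
})
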