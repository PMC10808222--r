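test_that("ordering samples are permutations, reproducible, enumerable", {
  ex <- sample_orderings(3, exhaustive = TRUE)
  expect_equal(ex$m, 6)
  expect_equal(length(unique(lapply(ex$orderings, paste, collapse = ""))), 6)

  s1 <- sample_orderings(5, m = 10, seed = 11)
  s2 <- sample_orderings(5, m = 10, seed = 11)
  expect_identical(s1$orderings, s2$orderings)
  for (o in s1$orderings) expect_equal(sort(o), 1:5)

  expect_error(sample_orderings(9, exhaustive = TRUE),
               class = "tsmsa_invalid_argument")
  expect_error(sample_orderings(3, m = 0), class = "tsmsa_invalid_argument")
})

test_that("an ordering expands into its nested lesion chain", {
  # players (A,B,C,D) = 1:4, ordering (B,C,A,D)
  chain <- coalitions_from_ordering(c(2L, 3L, 1L, 4L))
  expect_equal(chain, list(1:4, c(1L, 3L, 4L), c(1L, 4L), 4L, integer()))
  # first set is everyone, last is nobody, consecutive sets differ by the
  # ordering's k-th player
  ordering <- c(3L, 1L, 4L, 2L, 5L)
  chain <- coalitions_from_ordering(ordering)
  expect_equal(chain[[1]], 1:5)
  expect_equal(chain[[6]], integer())
  for (k in 1:5) {
    expect_equal(setdiff(chain[[k]], chain[[k + 1]]), ordering[k])
  }
  expect_error(coalitions_from_ordering(c(1L, 1L, 2L)),
               class = "tsmsa_invalid_argument")
})

test_that("coalition evaluation caches each distinct lesion set once", {
  bank <- toy_bank_small(3)
  game <- toy_game(bank, "tanh")
  orderings <- sample_orderings(3, exhaustive = TRUE)
  calls <- 0L
  counting <- msa_game(3, function(lesioned) {
    calls <<- calls + 1L
    game$play(lesioned)
  }, game$outcome_length)
  cache <- msa_cache()
  evaluate_coalitions(counting, orderings, cache)
  # 6 orderings x 4 sets = 24 requests but at most 2^3 = 8 distinct sets
  expect_equal(calls, 8L)
  expect_equal(cache$misses, 8L)
  expect_equal(cache$hits + cache$misses, 24L)
  # warm cache: zero new evaluations
  evaluate_coalitions(counting, orderings, cache)
  expect_equal(calls, 8L)
})

test_that("marginals telescope to v(N) - v(empty) within each ordering", {
  bank <- toy_bank_small(4)
  game <- toy_game(bank, "tanh")
  orderings <- sample_orderings(4, m = 6, seed = 2)
  cache <- msa_cache()
  evaluate_coalitions(game, orderings, cache)
  marg <- marginal_contributions(cache, orderings)
  span <- play_game(game) - play_game(game, 1:4)
  for (d in marg$delta) {
    expect_equal(colSums(d), span, tolerance = 1e-13)
  }
})

test_that("additive and scaled games are recovered exactly for any m", {
  bank <- toy_bank_small(5)
  values <- bank_values(bank)
  for (m in c(1, 7)) {
    res <- run_msa(toy_game(bank, "sum"), m = m, seed = m)
    expect_equal(res$gamma, unname(values), tolerance = 1e-13)
    res2 <- run_msa(toy_game(bank, "scaled"), m = m, seed = m + 1)
    expect_equal(res2$gamma, 2 * unname(values), tolerance = 1e-13)
  }
})

test_that("sampled estimates match exact enumeration on the tanh game", {
  bank <- toy_bank_small(3)
  game <- toy_game(bank, "tanh")
  exact <- shapley_exact(game)
  ex <- run_msa(game, exhaustive = TRUE)
  expect_equal(ex$gamma, exact, tolerance = 1e-12)
  expect_equal(ex$m, 6)
  # efficiency, exactly, for sampled runs too
  sam <- run_msa(game, m = 3, seed = 5)
  expect_lt(max(abs(sam$efficiency_residual)), 1e-12)
  expect_equal(colSums(sam$gamma), play_game(game), tolerance = 1e-12)
})

test_that("the sampler is unbiased: seed-averaged gamma converges to exact", {
  bank <- toy_bank_small(4, 20)
  game <- toy_game(bank, "tanh")
  exact <- run_msa(game, exhaustive = TRUE)$gamma
  n_seeds <- 80
  acc <- array(0, c(dim(exact), n_seeds))
  for (s in seq_len(n_seeds)) {
    acc[, , s] <- run_msa(game, m = 4, seed = 1000 + s)$gamma
  }
  bias <- apply(acc, c(1, 2), mean) - exact
  se <- apply(acc, c(1, 2), sd) / sqrt(n_seeds)
  # every (node, time) bias within 4 standard errors
  expect_lt(max(abs(bias) / pmax(se, 1e-15)), 4)
})

test_that("duplicate players share gamma and null players get zero", {
  tb <- seq(0, 2 * pi, length.out = 30)
  x <- cos(1.3 * tb)
  values <- rbind(x, x, 0 * x, 2 * x)
  game <- msa_game(4, function(lesioned) {
    keep <- setdiff(1:4, lesioned)
    tanh(colSums(values[keep, , drop = FALSE]))
  }, length(tb))
  res <- run_msa(game, exhaustive = TRUE)
  expect_equal(res$gamma[1, ], res$gamma[2, ], tolerance = 1e-13)
  expect_equal(res$gamma[3, ], rep(0, 30), tolerance = 1e-13)
})

test_that("null-contrast mode yields exactly zero contributions", {
  bank <- toy_bank_small(4)
  res <- run_msa(toy_game(bank, "tanh"), m = 5, seed = 3,
                 null_contrast = TRUE)
  expect_identical(res$gamma, matrix(0, 4, ncol(bank_values(bank))))
})

test_that("tidiers and serialization expose the contribution matrix", {
  bank <- toy_bank_small(3, 15)
  res <- run_msa(toy_game(bank, "sum"), m = 4, seed = 1)
  long <- tidy(res)
  expect_equal(nrow(long), 45)
  expect_equal(long$contribution[long$node == 2], res$gamma[2, ])
  g <- glance(res)
  expect_equal(g$n_players, 3)
  expect_lt(g$max_abs_efficiency_residual, 1e-12)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_contributions(res, path)
  wide <- read_contributions(path)
  expect_equal(unname(as.matrix(wide[, -1])), res$gamma, tolerance = 1e-12)
  manifest <- jsonlite::read_json(sub("\\.tsv$", ".json", path))
  expect_equal(manifest$m, 4)
})
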