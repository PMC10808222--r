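test_that("bank construction matches the analytic cosine form", {
  tb <- seq(0, 2 * pi, length.out = 100)
  bank <- sine_bank(c(0.2, 0.6, 1, 1.4, 1.8), c(1, 2.5, 4, 5.5, 7, 8.5),
                    phase = pi / 2, timebase = tb)
  expect_s3_class(bank, "sine_bank")
  expect_equal(nrow(bank), 30)

  # lexicographic (amplitude, frequency) ordering
  expect_equal(bank$amplitude, rep(c(0.2, 0.6, 1, 1.4, 1.8), each = 6))
  expect_equal(bank$frequency, rep(c(1, 2.5, 4, 5.5, 7, 8.5), times = 5))

  values <- bank_values(bank)
  expect_equal(dim(values), c(30, 100))
  # first sample of a unit signal at phase pi/2 is cos(pi/2) = 0
  unit <- which(bank$amplitude == 1 & bank$frequency == 1)
  expect_equal(values[unit, 1], cos(pi / 2))
  # every row reproduces its stored spec exactly
  for (i in c(1, 13, 30)) {
    expect_identical(values[i, ],
                     bank$amplitude[i] *
                       cos(bank$frequency[i] * tb + bank$phase[i]))
  }
})

test_that("invalid bank parameters are rejected", {
  expect_error(sine_bank(numeric(), 1), class = "tsmsa_invalid_argument")
  expect_error(sine_bank(1, numeric()), class = "tsmsa_invalid_argument")
  expect_error(sine_bank(-1, 1), class = "tsmsa_invalid_argument")
  expect_error(sine_bank(1, Inf), class = "tsmsa_invalid_argument")
  expect_error(sine_bank(1, 1, timebase = c(1, 1, 2)),
               class = "tsmsa_invalid_argument")
})

test_that("toy games implement lesioning as omission before the transform", {
  bank <- toy_bank_small(3)
  values <- bank_values(bank)

  sum_game <- toy_game(bank, "sum")
  expect_equal(play_game(sum_game), colSums(values))
  expect_equal(play_game(sum_game, 1:3), rep(0, ncol(values)))
  expect_equal(play_game(sum_game, 2L), colSums(values[-2, , drop = FALSE]))

  scaled <- toy_game(bank, "scaled", scale_factor = 2)
  expect_equal(play_game(scaled), 2 * colSums(values))

  tanh_game <- toy_game(bank, "tanh")
  out <- play_game(tanh_game, 3L)
  expect_equal(out, tanh(colSums(values[-3, , drop = FALSE])))
  expect_true(all(abs(out) < 1))
  # tanh applied AFTER summation, not per signal
  expect_false(isTRUE(all.equal(out, colSums(tanh(values[-3, , drop = FALSE])))))

  expect_error(play_game(sum_game, 99L), class = "tsmsa_invalid_argument")
  expect_error(play_game(sum_game, c(1L, 1L)),
               class = "tsmsa_invalid_argument")
})

test_that("marginal of the additive game is the player's own signal", {
  bank <- toy_bank_small(4)
  values <- bank_values(bank)
  game <- toy_game(bank, "sum")
  for (i in 1:4) {
    others <- setdiff(1:4, i)
    for (k in 0:2) {
      s <- others[seq_len(k)]
      marg <- play_game(game, setdiff(1:4, c(s, i))) -
        play_game(game, setdiff(1:4, s))
      expect_equal(marg, values[i, ], tolerance = 1e-14)
    }
  }
})

test_that("a bank round-trips through its delimited-text form", {
  bank <- toy_bank_small(3, 25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sine_bank(bank, path)
  back <- read_sine_bank(path)
  expect_equal(back$amplitude, bank$amplitude)
  expect_equal(back$frequency, bank$frequency)
  expect_equal(bank_timebase(back), bank_timebase(bank))
  expect_equal(bank_values(back), bank_values(bank))
})

test_that("tidy() gives one row per signal per sample", {
  bank <- toy_bank_small(2, 10)
  long <- tidy(bank)
  expect_equal(nrow(long), 20)
  expect_named(long, c("signal", "amplitude", "frequency", "phase",
                       "time", "value"))
  expect_equal(long$value[long$signal == 2],
               unname(bank_values(bank)[2, ]))
})
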