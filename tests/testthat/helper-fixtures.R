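# Shared fixtures, built in code at test time.

# The full 30-signal cosine bank used in the toy experiments.
toy_bank_full <- function(n_samples = 500) {
  sine_bank(c(0.2, 0.6, 1, 1.4, 1.8), c(1, 2.5, 4, 5.5, 7, 8.5),
            phase = pi / 2,
            timebase = seq(0, 2 * pi, length.out = n_samples))
}

# A small bank on a coarse grid: cheap enough for exhaustive enumeration.
toy_bank_small <- function(n_signals = 3, n_samples = 40) {
  amps <- c(0.5, 1, 1.5, 0.8, 1.2)[seq_len(n_signals)]
  sine_bank(amps, 1.7, timebase = seq(0, 2 * pi, length.out = n_samples))
}

# Direct Shapley values by subset enumeration (independent of the
# permutation-sampling estimator): gamma_i = sum over S not containing i of
# |S|! (n-|S|-1)! / n! * (v(S+i) - v(S)), computed sample-wise.
shapley_exact <- function(game) {
  n <- game$n_players
  players <- seq_len(n)
  gamma <- matrix(0, n, game$outcome_length)
  subsets <- lapply(0:(2^n - 1), function(bits) {
    players[bitwAnd(bits, 2^(players - 1)) > 0]
  })
  key <- function(s) paste0("S", paste(sort(s), collapse = ","))
  v <- lapply(subsets, function(s) game$play(setdiff(players, s)))
  names(v) <- vapply(subsets, key, character(1))
  for (i in players) {
    for (s in subsets) {
      if (i %in% s) next
      w <- factorial(length(s)) * factorial(n - length(s) - 1) / factorial(n)
      gamma[i, ] <- gamma[i, ] +
        w * (v[[key(c(s, i))]] - v[[key(s)]])
    }
  }
  gamma
}

# A tiny trained generative ESN on a short Mackey-Glass stretch; cheap enough
# for MSA in tests.
tiny_trained_esn <- function(seed = 3, n_reservoir = 16L, n_train = 1000L,
                             series = NULL) {
  series <- series %||% (mackey_glass(n_train + 300L)$value - 1)
  cfg <- esn_config(n_reservoir = n_reservoir, spectral_radius = 0.9,
                    leak_rate = 0.4, conventional_leak = TRUE,
                    ridge_lambda = 1e-6, seed = seed)
  train_esn(cfg, series[seq_len(n_train)])
}

`%||%` <- rlang::`%||%`
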