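#' Build a bank of cosine building-block signals
#'
#' Generates one signal per (amplitude, frequency) pair on a shared timebase,
#' each of the form `A * cos(w * t + phase)`. These banks are the inputs of the
#' toy attribution games: each signal is one "player" whose causal contribution
#' to a combined output is to be recovered.
#'
#' Signals are ordered lexicographically by (amplitude, frequency) so that
#' player indices are reproducible across runs.
#'
#' @param amplitudes Numeric vector of amplitudes, all `> 0`.
#' @param frequencies Numeric vector of angular frequencies (radians per time
#'   unit), all `> 0`.
#' @param phase Single phase offset in radians shared by all signals.
#' @param timebase Strictly increasing numeric vector of sample times. The
#'   default covers `[0, 2*pi]` with 500 uniform samples, i.e. one full period
#'   of the slowest default frequency.
#'
#' @return A tibble of class `sine_bank` with one row per signal and columns
#'   `signal`, `amplitude`, `frequency`, `phase`. The sample times and the
#'   evaluated signal matrix (signals x time) are carried in the `timebase`
#'   and `values` attributes; access them with [bank_timebase()] and
#'   [bank_values()].
#'
#' @examples
#' bank <- sine_bank(c(0.5, 1), c(1, 2))
#' bank
#' dim(bank_values(bank))
#' @export
sine_bank <- function(amplitudes,
                      frequencies,
                      phase = pi / 2,
                      timebase = seq(0, 2 * pi, length.out = 500)) {
  if (length(amplitudes) == 0 || length(frequencies) == 0) {
    abort("`amplitudes` and `frequencies` must be non-empty.",
          class = "tsmsa_invalid_argument")
  }
  if (length(timebase) == 0) {
    abort("`timebase` must be non-empty.", class = "tsmsa_invalid_argument")
  }
  if (!all(is.finite(amplitudes)) || !all(is.finite(frequencies)) ||
      !all(is.finite(phase)) || !all(is.finite(timebase))) {
    abort("Signal parameters and timebase must all be finite.",
          class = "tsmsa_invalid_argument")
  }
  if (any(amplitudes <= 0) || any(frequencies <= 0)) {
    abort("Amplitudes and frequencies must be strictly positive.",
          class = "tsmsa_invalid_argument")
  }
  if (length(phase) != 1) {
    abort("`phase` must be a single value.", class = "tsmsa_invalid_argument")
  }
  if (any(diff(timebase) <= 0)) {
    abort("`timebase` must be strictly increasing.",
          class = "tsmsa_invalid_argument")
  }

  specs <- tidyr::expand_grid(
    amplitude = sort(unique(amplitudes)),
    frequency = sort(unique(frequencies))
  )
  specs <- dplyr::mutate(specs, signal = dplyr::row_number(), phase = phase)
  specs <- dplyr::select(specs, "signal", "amplitude", "frequency", "phase")

  values <- eval_sine_specs(specs, timebase)
  tibble::new_tibble(
    specs,
    timebase = as.numeric(timebase),
    values = values,
    class = "sine_bank"
  )
}

# Evaluate A*cos(w*t + phase) for each spec row; rows of the result follow
# the spec rows, columns follow the timebase.
eval_sine_specs <- function(specs, timebase) {
  outer(seq_len(nrow(specs)), seq_along(timebase),
        function(i, j) {
          specs$amplitude[i] *
            cos(specs$frequency[i] * timebase[j] + specs$phase[i])
        })
}

#' @rdname sine_bank
#' @param bank A `sine_bank`.
#' @export
bank_values <- function(bank) {
  stopifnot(inherits(bank, "sine_bank"))
  attr(bank, "values")
}

#' @rdname sine_bank
#' @export
bank_timebase <- function(bank) {
  stopifnot(inherits(bank, "sine_bank"))
  attr(bank, "timebase")
}

#' Turn a signal bank into a long tibble
#'
#' @param x A [sine_bank()].
#' @param ... Unused.
#' @return A tibble with columns `signal`, `amplitude`, `frequency`, `phase`,
#'   `time`, `value` (one row per signal per sample).
#' @method tidy sine_bank
#' @export
tidy.sine_bank <- function(x, ...) {
  values <- bank_values(x)
  tb <- bank_timebase(x)
  long <- tidyr::expand_grid(signal = x$signal, time = tb)
  long$value <- as.vector(t(values))
  dplyr::left_join(tibble::as_tibble(unclass_bank(x)), long, by = "signal")
}

unclass_bank <- function(bank) {
  tibble::as_tibble(as.data.frame(bank))
}

#' Write and read a signal bank as delimited text
#'
#' The bank round-trips through a TSV file in long format (one row per signal
#' per sample) written at full precision, so `read_sine_bank(write_sine_bank(
#' bank, path))` reproduces the bank exactly.
#'
#' @param bank A [sine_bank()].
#' @param path File path.
#' @return `write_sine_bank()` returns `path` invisibly; `read_sine_bank()`
#'   returns a `sine_bank`.
#' @export
write_sine_bank <- function(bank, path) {
  long <- tidy.sine_bank(bank)
  write_tsv_full(long, path)
  invisible(path)
}

#' @rdname write_sine_bank
#' @export
read_sine_bank <- function(path) {
  long <- utils::read.delim(path, sep = "\t")
  specs <- dplyr::distinct(
    tibble::as_tibble(long),
    .data$signal, .data$amplitude, .data$frequency, .data$phase
  )
  specs <- dplyr::arrange(specs, .data$signal)
  timebase <- sort(unique(long$time))
  values <- eval_sine_specs(specs, timebase)
  tibble::new_tibble(specs, timebase = timebase, values = values,
                     class = "sine_bank")
}

#' Construct a toy attribution game over a signal bank
#'
#' The three toy games model a single downstream unit that combines `n`
#' input signals: `sum` adds them, `scaled` adds them and multiplies the sum
#' by `scale_factor`, and `tanh` adds them and passes the sum through a
#' saturating hyperbolic tangent. Lesioning a player omits its signal from the
#' sum *before* the downstream transformation — the order of operations is
#' what makes the saturating game's contributions non-trivial.
#'
#' @param bank A [sine_bank()]; each signal is one player.
#' @param kind `"sum"`, `"scaled"` or `"tanh"`.
#' @param scale_factor Multiplier applied after summation when
#'   `kind = "scaled"`.
#' @return An [msa_game] whose outcome is the combined time series on the
#'   bank's timebase.
#'
#' @examples
#' bank <- sine_bank(1, c(1, 2, 4))
#' game <- toy_game(bank, "tanh")
#' out <- play_game(game, lesioned = 2L)
#' range(out)
#' @export
toy_game <- function(bank, kind = c("sum", "scaled", "tanh"),
                     scale_factor = 2) {
  stopifnot(inherits(bank, "sine_bank"))
  kind <- rlang::arg_match(kind)
  if (!is.finite(scale_factor)) {
    abort("`scale_factor` must be finite.", class = "tsmsa_invalid_argument")
  }
  values <- bank_values(bank)
  n <- nrow(values)
  transform <- switch(kind,
    sum = identity,
    scaled = function(s) scale_factor * s,
    tanh = tanh
  )
  msa_game(
    n_players = n,
    play = function(lesioned = integer()) {
      keep <- setdiff(seq_len(n), lesioned)
      s <- if (length(keep) == 0) {
        rep(0, ncol(values))
      } else {
        colSums(values[keep, , drop = FALSE])
      }
      transform(s)
    },
    outcome_length = ncol(values),
    label = paste0("toy-", kind)
  )
}
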