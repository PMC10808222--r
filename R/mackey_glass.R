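#' Integrate the Mackey-Glass delay differential equation
#'
#' Produces the chaotic teacher/test sequences for the time-series prediction
#' task by integrating
#' \deqn{dr/dt = \beta \, r(t-\tau) / (1 + r(t-\tau)^n) - \gamma \, r(t)}
#' with a fixed-step fourth-order Runge-Kutta scheme. The delayed term is
#' obtained by linear interpolation on the stored fine integration grid. With
#' the default delay `tau = 17` the system is in its classic chaotic regime.
#'
#' Some transcriptions of the system place the decay term inside the
#' denominator bracket; `decay_in_denominator = TRUE` integrates that variant
#' literally. The canonical two-term form is the default and is the one whose
#' `tau = 17` regime is chaotic.
#'
#' @param length Number of retained samples, taken at unit time spacing after
#'   the washout.
#' @param tau Delay, in time units (default 17).
#' @param production_coeff,decay_coeff,exponent The constants \eqn{\beta}
#'   (0.2), \eqn{\gamma} (0.1) and \eqn{n} (10).
#' @param dt Integration step; must divide 1 exactly so unit-time sampling
#'   lands on grid points (default 0.1).
#' @param history_value Constant pre-history level `r(t <= 0)` (default 1.2).
#' @param washout_steps Fine integration steps discarded before sampling
#'   begins (default 1000, i.e. 100 time units); must cover at least one
#'   delay, `washout_steps * dt >= tau`.
#' @param decay_in_denominator Integrate the variant with the decay term
#'   inside the denominator (default `FALSE`).
#'
#' @return A tibble of class `mackey_glass` with columns `time` (unit-spaced,
#'   starting after the washout) and `value`. Integration parameters are
#'   attached as the `params` attribute.
#'
#' @examples
#' mg <- mackey_glass(200)
#' range(mg$value)
#' @export
mackey_glass <- function(length,
                         tau = 17,
                         production_coeff = 0.2,
                         decay_coeff = 0.1,
                         exponent = 10,
                         dt = 0.1,
                         history_value = 1.2,
                         washout_steps = 1000L,
                         decay_in_denominator = FALSE) {
  if (length < 1) abort("`length` must be positive.",
                        class = "tsmsa_invalid_argument")
  if (tau <= 0 || dt <= 0 || exponent <= 0) {
    abort("`tau`, `dt` and `exponent` must be positive.",
          class = "tsmsa_invalid_argument")
  }
  if (dt > tau) {
    abort("`dt` must not exceed the delay `tau`.",
          class = "tsmsa_invalid_argument")
  }
  steps_per_unit <- 1 / dt
  if (abs(steps_per_unit - round(steps_per_unit)) > 1e-9) {
    abort("`dt` must divide 1 so unit-time sampling is exact.",
          class = "tsmsa_invalid_argument")
  }
  steps_per_unit <- as.integer(round(steps_per_unit))
  if (washout_steps * dt < tau) {
    abort("`washout_steps * dt` must cover at least one delay `tau`.",
          class = "tsmsa_invalid_argument")
  }

  n_fine <- washout_steps + length * steps_per_unit
  r <- numeric(n_fine + 1)
  r[1] <- history_value
  lag_steps <- tau / dt  # possibly non-integer; interpolated below

  # r at fine index (0-based, possibly fractional); pre-history is constant
  delayed <- function(idx) {
    if (idx <= 0) return(history_value)
    lo <- floor(idx)
    frac <- idx - lo
    if (frac == 0) return(r[lo + 1])
    r[lo + 1] * (1 - frac) + r[lo + 2] * frac
  }

  deriv <- if (decay_in_denominator) {
    function(r_now, r_lag) {
      production_coeff * r_lag / (1 + r_lag^exponent - decay_coeff * r_now)
    }
  } else {
    function(r_now, r_lag) {
      production_coeff * r_lag / (1 + r_lag^exponent) - decay_coeff * r_now
    }
  }

  for (j in seq_len(n_fine)) {
    # stages at t, t + dt/2, t + dt; delayed values interpolated on the grid
    y <- r[j]
    lag0 <- delayed(j - 1 - lag_steps)
    lag_half <- delayed(j - 0.5 - lag_steps)
    lag1 <- delayed(j - lag_steps)
    k1 <- deriv(y, lag0)
    k2 <- deriv(y + dt / 2 * k1, lag_half)
    k3 <- deriv(y + dt / 2 * k2, lag_half)
    k4 <- deriv(y + dt * k3, lag1)
    r[j + 1] <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(r[j + 1])) {
      abort("Mackey-Glass integration diverged (non-finite state).",
            class = "tsmsa_integration_failure")
    }
  }

  keep <- washout_steps + steps_per_unit * seq_len(length) + 1
  out <- tibble::new_tibble(
    tibble::tibble(
      time = washout_steps * dt + seq_len(length),
      value = r[keep]
    ),
    params = list(tau = tau, production_coeff = production_coeff,
                  decay_coeff = decay_coeff, exponent = exponent, dt = dt,
                  history_value = history_value,
                  washout_steps = washout_steps,
                  decay_in_denominator = decay_in_denominator),
    class = "mackey_glass"
  )
  out
}

#' Write and read a Mackey-Glass series as delimited text
#'
#' Single value column, full precision, with the integration parameters
#' recorded as `#`-prefixed header comment lines.
#'
#' @param series A [mackey_glass()] tibble.
#' @param path File path.
#' @return `write_mackey_glass()` returns `path` invisibly;
#'   `read_mackey_glass()` returns a tibble with columns `time`, `value` and
#'   the recovered `params` attribute.
#' @export
write_mackey_glass <- function(series, path) {
  stopifnot(inherits(series, "mackey_glass"))
  params <- attr(series, "params")
  header <- vapply(names(params), function(nm) {
    sprintf("# %s = %s", nm, format(params[[nm]], digits = 17))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("time\tvalue", con)
  writeLines(sprintf("%s\t%s",
                     format(series$time, digits = 17, trim = TRUE),
                     format(series$value, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_mackey_glass
#' @export
read_mackey_glass <- function(path) {
  lines <- readLines(path)
  header <- grepl("^#", lines)
  params <- list()
  for (line in lines[header]) {
    kv <- strsplit(sub("^# ", "", line), " = ")[[1]]
    val <- suppressWarnings(as.numeric(kv[2]))
    params[[kv[1]]] <- if (is.na(val)) as.logical(kv[2]) else val
  }
  body <- utils::read.delim(textConnection(lines[!header]), sep = "\t")
  tibble::new_tibble(tibble::as_tibble(body), params = params,
                     class = "mackey_glass")
}
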