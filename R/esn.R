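#' Echo state network configuration
#'
#' Collects every knob of a leaky-integrator ESN. The reservoir activation is
#' a hyperbolic tangent; the readout activation is identity or tanh. The state
#' update follows
#' `x(t) = (1 - a) x(t-1) + f(W_in u(t) + W x(t-1) + W_fb y(t-1))`,
#' i.e. the new activation term is *not* premultiplied by the leakage rate
#' `a`; set `conventional_leak = TRUE` for the textbook form
#' `(1 - a) x(t-1) + a f(...)`.
#'
#' @param n_reservoir Number of reservoir units `N_x`.
#' @param n_inputs,n_outputs Input and output dimensions `N_u`, `N_y`.
#' @param leak_rate Leakage rate `a` in `(0, 1]`.
#' @param spectral_radius Target spectral radius `rho` of the reservoir
#'   matrix (`> 0`; below 1 for the echo-state regime).
#' @param readout_activation `"identity"` or `"tanh"`; when `"tanh"`, the
#'   readout is fitted by linear regression on atanh-transformed targets.
#' @param topology `"small_world"` (Watts-Strogatz ring lattice with `k`
#'   neighbours rewired with probability `p`) or `"random"` (each entry
#'   nonzero independently with probability `density`).
#' @param k,p Watts-Strogatz parameters (`k` even).
#' @param density Connection density for `topology = "random"`.
#' @param weight_scale_in,weight_scale_fb Multipliers on the uniform
#'   `[-0.5, 0.5]` input and feedback weights.
#' @param bias_level Amplitude of the constant DC bias fed to the input
#'   channel when no external input is supplied.
#' @param washout Initial steps discarded before fitting the readout.
#' @param ridge_lambda Ridge penalty for the readout fit (`>= 0`); the small
#'   default keeps lesioned, rank-deficient reservoirs solvable.
#' @param seed Integer seed controlling weight initialization.
#' @param conventional_leak Use the textbook leaky-integrator update.
#' @return A list of class `esn_config`.
#' @export
esn_config <- function(n_reservoir = 36L,
                       n_inputs = 1L,
                       n_outputs = 1L,
                       leak_rate = 1,
                       spectral_radius = 0.9,
                       readout_activation = c("identity", "tanh"),
                       topology = c("small_world", "random"),
                       k = 4L,
                       p = 0.1,
                       density = 0.1,
                       weight_scale_in = 1,
                       weight_scale_fb = 1,
                       bias_level = 0.2,
                       washout = 100L,
                       ridge_lambda = 1e-8,
                       seed = NULL,
                       conventional_leak = FALSE) {
  readout_activation <- rlang::arg_match(readout_activation)
  topology <- rlang::arg_match(topology)
  if (leak_rate <= 0 || leak_rate > 1) {
    abort("`leak_rate` must lie in (0, 1].", class = "tsmsa_invalid_argument")
  }
  if (spectral_radius <= 0) {
    abort("`spectral_radius` must be positive.",
          class = "tsmsa_invalid_argument")
  }
  if (n_reservoir < 1) {
    abort("`n_reservoir` must be at least 1.",
          class = "tsmsa_invalid_argument")
  }
  if (ridge_lambda < 0) {
    abort("`ridge_lambda` must be non-negative.",
          class = "tsmsa_invalid_argument")
  }
  structure(
    list(n_reservoir = as.integer(n_reservoir),
         n_inputs = as.integer(n_inputs),
         n_outputs = as.integer(n_outputs),
         leak_rate = leak_rate,
         spectral_radius = spectral_radius,
         readout_activation = readout_activation,
         topology = topology, k = as.integer(k), p = p, density = density,
         weight_scale_in = weight_scale_in,
         weight_scale_fb = weight_scale_fb,
         bias_level = bias_level,
         washout = as.integer(washout),
         ridge_lambda = ridge_lambda,
         seed = seed,
         conventional_leak = conventional_leak),
    class = "esn_config"
  )
}

readout_fn <- function(config) {
  switch(config$readout_activation, identity = identity, tanh = tanh)
}

spectral_radius_of <- function(W) {
  max(Mod(eigen(W, only.values = TRUE)$values))
}

#' Initialize an ESN's weight matrices
#'
#' The reservoir matrix `W` is sparse according to the configured topology,
#' with nonzero entries drawn uniformly on `[-0.5, 0.5]` and then rescaled so
#' its spectral radius equals `config$spectral_radius` exactly. Input and
#' feedback matrices are dense uniform `[-0.5, 0.5]` times their scale
#' factors. The readout `W_out` is zero until trained. Deterministic given
#' `config$seed`.
#'
#' @param config An [esn_config()].
#' @return A list of class `esn_weights` with elements `W`
#'   (`N_x x N_x`), `W_in` (`N_x x N_u`), `W_fb` (`N_x x N_y`), `W_out`
#'   (`N_y x (N_x + N_u)`) and `config`.
#' @export
init_esn <- function(config) {
  stopifnot(inherits(config, "esn_config"))
  build <- function() {
    N <- config$n_reservoir
    mask <- switch(config$topology,
      small_world = {
        if (N < config$k + 1) {
          abort("`n_reservoir` too small for the requested lattice degree.",
                class = "tsmsa_invalid_argument")
        }
        g <- igraph::sample_smallworld(1, N, config$k / 2, config$p)
        as.matrix(igraph::as_adjacency_matrix(g)) > 0
      },
      random = matrix(runif(N * N) < config$density, N, N)
    )
    if (!any(mask)) {
      abort("Topology produced an empty reservoir graph.",
            class = "tsmsa_invalid_argument")
    }
    W <- matrix(0, N, N)
    W[mask] <- runif(sum(mask), -0.5, 0.5)
    sr <- spectral_radius_of(W)
    if (sr == 0) {
      abort("Reservoir matrix has zero spectral radius; cannot rescale.",
            class = "tsmsa_invalid_argument")
    }
    W <- W * (config$spectral_radius / sr)
    W_in <- matrix(runif(N * config$n_inputs, -0.5, 0.5), N) *
      config$weight_scale_in
    W_fb <- matrix(runif(N * config$n_outputs, -0.5, 0.5), N) *
      config$weight_scale_fb
    list(W = W, W_in = W_in, W_fb = W_fb,
         W_out = matrix(0, config$n_outputs, N + config$n_inputs),
         config = config)
  }
  wts <- if (is.null(config$seed)) build() else
    withr::with_seed(as.integer(config$seed), build())
  structure(wts, class = "esn_weights")
}

#' One reservoir state update
#'
#' `x(t) = (1 - a) x(t-1) + tanh(W_in u(t) + W x(t-1) + W_fb y(t-1))`
#' (or the `conventional_leak` variant with the tanh term scaled by `a`).
#'
#' @param x_prev Previous reservoir state (`N_x`-vector).
#' @param u_t Current input (`N_u`-vector).
#' @param y_prev Previous output (`N_y`-vector).
#' @param weights An [init_esn()] weight set.
#' @return The new state `x(t)`.
#' @export
esn_step <- function(x_prev, u_t, y_prev, weights) {
  config <- weights$config
  pre <- weights$W_in %*% u_t + weights$W %*% x_prev + weights$W_fb %*% y_prev
  act <- tanh(pre)
  if (config$conventional_leak) act <- config$leak_rate * act
  drop((1 - config$leak_rate) * x_prev + act)
}

as_input_matrix <- function(u, n_steps, config) {
  if (is.null(u)) {
    return(matrix(config$bias_level, n_steps, config$n_inputs))
  }
  u <- if (is.matrix(u)) u else matrix(u, ncol = config$n_inputs)
  if (nrow(u) != n_steps) {
    abort("Input series length mismatch.", class = "tsmsa_invalid_argument")
  }
  u
}

#' Run the reservoir under teacher forcing
#'
#' Iterates the state update with the feedback channel driven by the teacher
#' signal `d(t - 1)` rather than the network's own output, from a zero (or
#' supplied) initial state. This is the training regime: the reservoir is
#' excited by the target signal through the feedback weights and produces the
#' internal activation traces the readout is then fitted on.
#'
#' @param weights An [init_esn()] weight set.
#' @param teacher Teacher series (`T`-vector or `T x N_y` matrix).
#' @param input Optional input series (`T x N_u`); defaults to the constant
#'   DC bias of the configuration.
#' @param init_state,init_output State and output used at the first step.
#' @return A list of class `esn_trace`: `states` (`T x N_x`), `inputs`
#'   (`T x N_u`), `teacher` (`T x N_y`).
#' @export
teacher_force <- function(weights, teacher, input = NULL,
                          init_state = NULL, init_output = NULL) {
  config <- weights$config
  d <- if (is.matrix(teacher)) teacher else matrix(teacher, ncol = config$n_outputs)
  n_steps <- nrow(d)
  u <- as_input_matrix(input, n_steps, config)
  x <- init_state %||% numeric(config$n_reservoir)
  y_prev <- init_output %||% numeric(config$n_outputs)
  states <- matrix(0, n_steps, config$n_reservoir)
  for (t in seq_len(n_steps)) {
    x <- esn_step(x, u[t, ], y_prev, weights)
    states[t, ] <- x
    y_prev <- d[t, ]
  }
  structure(list(states = states, inputs = u, teacher = d),
            class = "esn_trace")
}

#' Fit the linear readout on a teacher-forced trace
#'
#' Minimises the post-washout squared error between `g^{-1}(target)` and
#' `W_out z(t)` over the extended states `z(t) = [x(t); u(t)]`, with an
#' optional ridge penalty. With `ridge_lambda = 0` the exact least-squares
#' solution is returned and a rank-deficient design raises an error advising
#' a positive ridge.
#'
#' @param trace An `esn_trace` from [teacher_force()].
#' @param targets Target series (defaults to the trace's teacher).
#' @param config An [esn_config()]; supplies `washout`, `ridge_lambda` and
#'   the readout activation.
#' @param fit_end Last trace row used in the regression (default: the whole
#'   trace). Because teacher forcing is causal, fitting on rows up to
#'   `fit_end` of a longer trace is identical to fitting on a trace truncated
#'   there — this is how a readout validated on a held-out tail is deployed
#'   unchanged on the full sequence.
#' @return The fitted `W_out`, an `N_y x (N_x + N_u)` matrix.
#' @export
fit_readout <- function(trace, targets = NULL, config, fit_end = NULL) {
  stopifnot(inherits(trace, "esn_trace"))
  d <- targets %||% trace$teacher
  d <- if (is.matrix(d)) d else matrix(d, ncol = config$n_outputs)
  n_steps <- fit_end %||% nrow(trace$states)
  stopifnot(n_steps <= nrow(trace$states))
  if (config$washout >= n_steps) {
    abort("`washout` must be smaller than the trace length.",
          class = "tsmsa_invalid_argument")
  }
  keep <- (config$washout + 1):n_steps
  Z <- cbind(trace$states, trace$inputs)[keep, , drop = FALSE]
  y <- d[keep, , drop = FALSE]
  if (config$readout_activation == "tanh") {
    y <- atanh(pmin(pmax(y, -1 + 1e-6), 1 - 1e-6))
  }
  lambda <- config$ridge_lambda
  if (lambda == 0) {
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      abort(paste0("Readout design matrix is rank deficient; ",
                   "set `ridge_lambda > 0` to regularise."),
            class = "tsmsa_numerical_rank")
    }
    W_out <- t(qr.coef(qrz, y))
  } else {
    A <- crossprod(Z) + diag(lambda, ncol(Z))
    W_out <- t(solve(A, crossprod(Z, y)))
  }
  unname(W_out)
}

#' Run the network freely on its own output feedback
#'
#' After training the teacher is disconnected: the feedback channel carries
#' the network's own previous output `y(t-1) = g(W_out z(t-1))`. Divergence
#' (output magnitude beyond `guard`) does not raise an error — the run is
#' flagged and the output clamped — because a lesioned network's poor outcome
#' is still a valid game outcome.
#'
#' @param weights A trained weight set (`W_out` populated).
#' @param n_steps Number of free-running steps.
#' @param input Optional input series (`n_steps x N_u`); defaults to the
#'   constant DC bias.
#' @param init_state,init_output Continuation point, typically the final
#'   teacher-forced state and the last teacher value.
#' @param guard Output magnitude beyond which the run is flagged divergent.
#' @return A list of class `esn_run`: `output` (`n_steps x N_y`), `states`
#'   (`n_steps x N_x`), `divergent` flag.
#' @export
free_run <- function(weights, n_steps, input = NULL,
                     init_state = NULL, init_output = NULL, guard = 1e6) {
  config <- weights$config
  g <- readout_fn(config)
  u <- as_input_matrix(input, n_steps, config)
  x <- init_state %||% numeric(config$n_reservoir)
  y_prev <- init_output %||% numeric(config$n_outputs)
  states <- matrix(0, n_steps, config$n_reservoir)
  output <- matrix(0, n_steps, config$n_outputs)
  divergent <- FALSE
  for (t in seq_len(n_steps)) {
    x <- esn_step(x, u[t, ], y_prev, weights)
    states[t, ] <- x
    y <- drop(g(weights$W_out %*% c(x, u[t, ])))
    if (any(!is.finite(y)) || any(abs(y) > guard)) {
      divergent <- TRUE
      y[!is.finite(y)] <- 0
      y <- pmin(pmax(y, -guard), guard)
    }
    output[t, ] <- y
    y_prev <- y
  }
  structure(list(output = output, states = states, divergent = divergent),
            class = "esn_run")
}

#' Train an ESN in teacher-forced mode
#'
#' Initializes weights (unless supplied), runs the reservoir under teacher
#' forcing, fits the readout, and records everything needed to replay or
#' lesion the network: the training data, the trace, and the continuation
#' point for free-running prediction.
#'
#' @param config An [esn_config()].
#' @param teacher Teacher series (`T`-vector or matrix).
#' @param input Optional input series; defaults to the constant DC bias.
#' @param weights Optional pre-initialized [init_esn()] weight set.
#' @param fit_end Last teacher-forced step used in the readout regression
#'   (see [fit_readout()]); the reservoir still runs through the whole
#'   teacher, so the continuation point reflects the full sequence.
#' @return A list of class `trained_esn` with elements `config`, `weights`
#'   (readout populated), `trace`, `teacher`, `input`, `train_mse`,
#'   `fit_end`, `final_state`, `final_output`.
#' @export
train_esn <- function(config, teacher, input = NULL, weights = NULL,
                      fit_end = NULL) {
  stopifnot(inherits(config, "esn_config"))
  weights <- weights %||% init_esn(config)
  trace <- teacher_force(weights, teacher, input)
  W_out <- fit_readout(trace, config = config, fit_end = fit_end)
  weights$W_out <- W_out
  g <- readout_fn(config)
  keep <- (config$washout + 1):(fit_end %||% nrow(trace$states))
  Z <- cbind(trace$states, trace$inputs)
  fitted <- t(g(W_out %*% t(Z)))
  train_mse <- mean((fitted[keep, ] - trace$teacher[keep, ])^2)
  structure(
    list(config = config, weights = weights, trace = trace,
         teacher = trace$teacher, input = trace$inputs,
         train_mse = train_mse, fit_end = fit_end,
         final_state = trace$states[nrow(trace$states), ],
         final_output = trace$teacher[nrow(trace$teacher), ]),
    class = "trained_esn"
  )
}

#' @export
print.trained_esn <- function(x, ...) {
  cat(sprintf(
    "<trained_esn: %d units, rho = %.3g, a = %.3g, train MSE = %.3g>\n",
    x$config$n_reservoir, x$config$spectral_radius, x$config$leak_rate,
    x$train_mse))
  invisible(x)
}

#' Free-run a trained network from the end of its training data
#'
#' @param trained A [train_esn()] result.
#' @param n_steps Steps to generate.
#' @param input Optional test input series; defaults to the constant DC bias.
#' @param ... Passed to [free_run()].
#' @return An `esn_run`.
#' @export
continue_esn <- function(trained, n_steps, input = NULL, ...) {
  stopifnot(inherits(trained, "trained_esn"))
  free_run(trained$weights, n_steps, input = input,
           init_state = trained$final_state,
           init_output = trained$final_output, ...)
}

#' Lesion reservoir nodes
#'
#' Virtually removes each node in `nodes` by zeroing row and column `i` of
#' the reservoir matrix — its incoming and outgoing recurrent weights — and
#' (by default) its rows of the input and feedback matrices, so a dead node
#' neither receives nor transmits signal. The matrix is *not* rescaled after
#' lesioning: the perturbation acts on the initialized/trained weights
#' directly. The original weight set is left untouched.
#'
#' @param weights An `esn_weights` set.
#' @param nodes Integer vector of reservoir node indices to lesion.
#' @param include_io Also zero the lesioned rows of `W_in` and `W_fb`
#'   (default `TRUE`); `FALSE` restricts the lesion to the recurrent matrix.
#' @return A new `esn_weights` set.
#' @export
lesion_esn <- function(weights, nodes, include_io = TRUE) {
  stopifnot(inherits(weights, "esn_weights"))
  nodes <- check_players(nodes, weights$config$n_reservoir)
  if (length(nodes) == 0) return(weights)
  weights$W[nodes, ] <- 0
  weights$W[, nodes] <- 0
  if (include_io) {
    weights$W_in[nodes, ] <- 0
    weights$W_fb[nodes, ] <- 0
  }
  weights
}

#' Expose a trained ESN as a lesionable game
#'
#' The game's players are the reservoir nodes; `play(lesioned)` lesions them,
#' optionally refits the readout by re-running teacher forcing on the stored
#' training data with the lesioned reservoir (the recurrent weights stay
#' lesioned and otherwise frozen), then free-runs `horizon` steps and returns
#' the output series — the characteristic-function value of the coalition of
#' intact nodes. Readout retraining keeps the network functional after
#' non-severe perturbations.
#'
#' @param trained A [train_esn()] result.
#' @param horizon Free-run length defining the outcome.
#' @param retrain Refit the readout after each lesion (default `TRUE`).
#' @param test_input Optional input series for the free-run phase.
#' @param include_io Passed to [lesion_esn()].
#' @return An [msa_game] over `n_reservoir` players whose outcome is the
#'   `horizon`-step output.
#' @export
esn_game <- function(trained, horizon = 500L, retrain = TRUE,
                     test_input = NULL, include_io = TRUE) {
  stopifnot(inherits(trained, "trained_esn"))
  config <- trained$config
  play <- function(lesioned = integer()) {
    wts <- lesion_esn(trained$weights, lesioned, include_io = include_io)
    if (retrain) {
      trace <- teacher_force(wts, trained$teacher, trained$input)
      wts$W_out <- fit_readout(trace, config = config,
                               fit_end = trained$fit_end)
      init_state <- trace$states[nrow(trace$states), ]
    } else {
      init_state <- trained$final_state
    }
    run <- free_run(wts, horizon, input = test_input,
                    init_state = init_state,
                    init_output = trained$final_output)
    drop(run$output)
  }
  msa_game(n_players = config$n_reservoir, play = play,
           outcome_length = horizon,
           label = sprintf("esn-%dunits", config$n_reservoir))
}

#' Mean squared error between a prediction and its reference
#'
#' @param prediction,reference Numeric vectors or single-column matrices of
#'   equal length.
#' @return The mean of squared sample-wise differences.
#' @export
esn_mse <- function(prediction, reference) {
  prediction <- drop(as.matrix(prediction))
  reference <- drop(as.matrix(reference))
  if (length(prediction) != length(reference)) {
    abort("Prediction and reference lengths differ.",
          class = "tsmsa_invalid_argument")
  }
  mean((prediction - reference)^2)
}

#' Broom-style summaries of a trained ESN
#'
#' `tidy()` returns one row per readout weight (reservoir units first, then
#' input channels); `glance()` returns a one-row summary.
#'
#' @param x A `trained_esn`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy trained_esn
#' @export
tidy.trained_esn <- function(x, ...) {
  N <- x$config$n_reservoir
  K <- ncol(x$weights$W_out)
  tibble::tibble(
    term = c(paste0("node_", seq_len(N)),
             paste0("input_", seq_len(K - N))),
    kind = rep(c("reservoir", "input"), c(N, K - N)),
    estimate = as.vector(x$weights$W_out[1, ])
  )
}

#' @rdname tidy.trained_esn
#' @method glance trained_esn
#' @export
glance.trained_esn <- function(x, ...) {
  tibble::tibble(
    n_reservoir = x$config$n_reservoir,
    spectral_radius = x$config$spectral_radius,
    leak_rate = x$config$leak_rate,
    topology = x$config$topology,
    washout = x$config$washout,
    ridge_lambda = x$config$ridge_lambda,
    train_mse = x$train_mse
  )
}
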