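#' The lesionable-game contract
#'
#' A game is the object MSA operates on: a set of `n_players` players and a
#' deterministic map from "which players are lesioned" to an outcome time
#' series `v` of fixed length. The grand-coalition outcome is
#' `play(integer())` (nobody lesioned) and the empty-coalition baseline is
#' `play(1:n_players)` (everybody lesioned).
#'
#' @param n_players Number of players (positive integer).
#' @param play Function of one argument, a sorted integer vector of lesioned
#'   player indices (subset of `1:n_players`), returning a numeric outcome
#'   vector of length `outcome_length`. Must be deterministic.
#' @param outcome_length Length of the outcome vector returned by `play`.
#' @param label Short human-readable tag used in printing and manifests.
#' @return An object of class `msa_game`.
#' @export
msa_game <- function(n_players, play, outcome_length, label = "game") {
  stopifnot(is.numeric(n_players), n_players >= 1, is.function(play),
            outcome_length >= 1)
  structure(
    list(
      n_players = as.integer(n_players),
      play = play,
      outcome_length = as.integer(outcome_length),
      label = label
    ),
    class = "msa_game"
  )
}

#' @export
print.msa_game <- function(x, ...) {
  cat(sprintf("<msa_game '%s': %d players, outcome length %d>\n",
              x$label, x$n_players, x$outcome_length))
  invisible(x)
}

#' Evaluate a game under a lesion configuration
#'
#' @param game An [msa_game].
#' @param lesioned Integer vector of lesioned players (may be empty).
#' @return Numeric outcome vector of length `game$outcome_length`.
#' @export
play_game <- function(game, lesioned = integer()) {
  stopifnot(inherits(game, "msa_game"))
  lesioned <- check_players(lesioned, game$n_players)
  out <- game$play(lesioned)
  if (length(out) != game$outcome_length) {
    abort("Game returned an outcome of unexpected length.",
          class = "tsmsa_internal_error")
  }
  out
}

check_players <- function(lesioned, n_players) {
  if (length(lesioned) == 0) return(integer())
  lesioned <- as.integer(lesioned)
  if (anyNA(lesioned) || any(lesioned < 1L) || any(lesioned > n_players)) {
    abort(sprintf("Player indices must lie in 1..%d.", n_players),
          class = "tsmsa_invalid_argument")
  }
  if (anyDuplicated(lesioned)) {
    abort("Player indices must be unique.", class = "tsmsa_invalid_argument")
  }
  sort(lesioned)
}

#' Wrap a game so that lesions are ignored (null-contrast control)
#'
#' In the null-contrast control the lesion operator is the identity: every
#' coalition is "played" with the full, intact system, so every marginal
#' contrast compares two identical outcomes and all contributions must be
#' exactly zero. Used as a sanity check of the estimator's contrast step.
#'
#' @param game An [msa_game].
#' @return An [msa_game] whose `play` ignores its lesion argument.
#' @export
null_contrast_game <- function(game) {
  stopifnot(inherits(game, "msa_game"))
  msa_game(
    n_players = game$n_players,
    play = function(lesioned = integer()) game$play(integer()),
    outcome_length = game$outcome_length,
    label = paste0(game$label, "-null-contrast")
  )
}

# ---- orderings ------------------------------------------------------------

#' Sample player orderings
#'
#' Draws `m` player permutations uniformly and independently (with
#' replacement across draws), or enumerates all `n!` permutations when
#' `exhaustive = TRUE`. Each sampled ordering later contributes one full
#' telescoping chain of marginal contributions, which is what makes the
#' permutation-sampling Shapley estimator unbiased for any `m >= 1`.
#'
#' @param n_players Number of players.
#' @param m Number of orderings to draw (ignored when `exhaustive = TRUE`).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param exhaustive Enumerate all `n!` orderings instead of sampling.
#' @param exhaustive_cap Largest `n_players` for which enumeration is allowed
#'   (default 8, i.e. at most 40320 orderings).
#' @return An object of class `msa_orderings`: a list with elements
#'   `orderings` (list of integer permutations of `1:n_players`), `m`, `seed`
#'   and `exhaustive`.
#' @examples
#' sample_orderings(3, exhaustive = TRUE)$m  # 3! = 6
#' @export
sample_orderings <- function(n_players, m = 100L, seed = NULL,
                             exhaustive = FALSE, exhaustive_cap = 8L) {
  n_players <- as.integer(n_players)
  stopifnot(n_players >= 1)
  if (exhaustive) {
    if (n_players > exhaustive_cap) {
      abort(sprintf(paste0(
        "Exhaustive enumeration of %d! orderings refused (cap %d players); ",
        "use sampling with `exhaustive = FALSE` and a sample size `m`."),
        n_players, exhaustive_cap), class = "tsmsa_invalid_argument")
    }
    orderings <- all_permutations(n_players)
  } else {
    if (!is.numeric(m) || m < 1) {
      abort("`m` must be a positive integer.",
            class = "tsmsa_invalid_argument")
    }
    draw <- function() {
      lapply(seq_len(m), function(i) sample.int(n_players))
    }
    orderings <- if (is.null(seed)) draw() else
      withr::with_seed(as.integer(seed), draw())
  }
  structure(
    list(orderings = orderings, m = length(orderings),
         seed = seed, exhaustive = exhaustive),
    class = "msa_orderings"
  )
}

# All permutations of 1..n as a list, lexicographic order.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  rec <- function(items) {
    if (length(items) == 1) return(list(items))
    out <- list()
    for (i in seq_along(items)) {
      rest <- rec(items[-i])
      out <- c(out, lapply(rest, function(p) c(items[i], p)))
    }
    out
  }
  rec(seq_len(n))
}

#' Expand an ordering into its chain of nested lesion sets
#'
#' Position `k` of the chain (for `k = 0..n`) is the lesion set containing the
#' players *not* among the first `k` of the ordering: the chain runs from
#' "everyone lesioned" (the empty coalition) to "no one lesioned" (the grand
#' coalition), and consecutive sets differ by exactly the ordering's k-th
#' player. Contrasting consecutive outcomes therefore isolates that player's
#' marginal contribution to the coalition formed by its predecessors.
#'
#' @param ordering Integer permutation of `1:n`.
#' @return List of `n + 1` sorted integer vectors (lesion sets).
#' @examples
#' coalitions_from_ordering(c(2L, 3L, 1L))
#' @export
coalitions_from_ordering <- function(ordering) {
  n <- length(ordering)
  if (!setequal(ordering, seq_len(n))) {
    abort("`ordering` must be a permutation of 1..n.",
          class = "tsmsa_invalid_argument")
  }
  lapply(0:n, function(k) sort(setdiff(seq_len(n), ordering[seq_len(k)])))
}

# ---- coalition cache ------------------------------------------------------

coalition_key <- function(lesioned) {
  paste0("L:", paste(lesioned, collapse = ","))
}

#' Create an empty coalition-outcome cache
#'
#' Keys are canonical (sorted) lesion sets; values are outcome vectors. A
#' cache can be reused across [run_msa()] calls on the same game to avoid
#' re-evaluating coalitions.
#'
#' @return An environment of class `msa_cache` with hit/miss counters.
#' @export
msa_cache <- function() {
  cache <- new.env(parent = emptyenv())
  cache$store <- new.env(parent = emptyenv())
  cache$hits <- 0L
  cache$misses <- 0L
  class(cache) <- "msa_cache"
  cache
}

#' Evaluate every coalition required by a set of orderings
#'
#' Walks all lesion chains of the orderings and plays the game once per
#' *distinct* lesion set, memoising outcomes, so the number of game
#' evaluations is bounded by the number of distinct coalitions rather than by
#' `m * (n + 1)`.
#'
#' @param game An [msa_game].
#' @param orderings An `msa_orderings` from [sample_orderings()].
#' @param cache An [msa_cache()] (a warm cache performs no new evaluations
#'   for already-seen coalitions).
#' @return The populated cache, invisibly carrying hit/miss statistics.
#' @export
evaluate_coalitions <- function(game, orderings, cache = msa_cache()) {
  stopifnot(inherits(game, "msa_game"), inherits(orderings, "msa_orderings"),
            inherits(cache, "msa_cache"))
  for (ordering in orderings$orderings) {
    for (lesioned in coalitions_from_ordering(ordering)) {
      key <- coalition_key(lesioned)
      if (is.null(cache$store[[key]])) {
        cache$misses <- cache$misses + 1L
        out <- game$play(lesioned)
        if (length(out) != game$outcome_length || anyNA(out)) {
          abort(sprintf("Game evaluation failed for lesion set {%s}.", key),
                class = "tsmsa_game_failure")
        }
        assign(key, out, envir = cache$store)
      } else {
        cache$hits <- cache$hits + 1L
      }
    }
  }
  invisible(cache)
}

cache_lookup <- function(cache, lesioned) {
  out <- cache$store[[coalition_key(lesioned)]]
  if (is.null(out)) {
    abort("Missing cache entry; evaluate_coalitions() must run first.",
          class = "tsmsa_internal_error")
  }
  out
}

cache_size <- function(cache) length(ls(cache$store))

# ---- marginals and averaging ---------------------------------------------

#' Marginal contributions along each sampled ordering
#'
#' For ordering `R` and its k-th player `i`, the marginal contribution is the
#' sample-wise difference between the outcome with the first `k` players
#' intact and the outcome with only the first `k - 1` intact:
#' `delta_i = v(S union i) - v(S)` where `S` is the coalition of predecessors.
#' Within each ordering the marginals telescope exactly to
#' `v(N) - v(empty)`.
#'
#' @param cache A populated [msa_cache()].
#' @param orderings The `msa_orderings` the cache was populated for.
#' @return A list of class `msa_marginals`: `delta` is a list (one element per
#'   ordering) of `n_players x T` matrices, rows indexed by player.
#' @export
marginal_contributions <- function(cache, orderings) {
  stopifnot(inherits(cache, "msa_cache"), inherits(orderings, "msa_orderings"))
  delta <- lapply(orderings$orderings, function(ordering) {
    chain <- coalitions_from_ordering(ordering)
    outcomes <- lapply(chain, function(s) cache_lookup(cache, s))
    n <- length(ordering)
    d <- matrix(0, nrow = n, ncol = length(outcomes[[1]]))
    for (k in seq_len(n)) {
      d[ordering[k], ] <- outcomes[[k + 1]] - outcomes[[k]]
    }
    d
  })
  structure(list(delta = delta, orderings = orderings),
            class = "msa_marginals")
}

#' Average marginals into time-resolved Shapley values
#'
#' The contribution of player `i` is the mean over sampled orderings of its
#' marginal contribution, taken independently at each outcome sample — one
#' contribution time series per player. Averaging is performed in ordering
#' index order so floating-point sums are reproducible regardless of how
#' coalitions were evaluated.
#'
#' @param marginals An `msa_marginals` from [marginal_contributions()].
#' @param v_full,v_empty Outcomes of the grand and empty coalitions, used to
#'   compute the efficiency residual `sum_i gamma_i - (v(N) - v(empty))`.
#' @param seed,label Metadata recorded on the result.
#' @return An object of class `msa` — see [run_msa()].
#' @export
shapley_from_marginals <- function(marginals, v_full, v_empty,
                                   seed = NULL, label = "game") {
  stopifnot(inherits(marginals, "msa_marginals"))
  delta <- marginals$delta
  m <- length(delta)
  gamma <- Reduce(`+`, delta) / m
  residual <- colSums(gamma) - (v_full - v_empty)
  new_msa(gamma = gamma, v_full = v_full, v_empty = v_empty,
          efficiency_residual = residual, m = m, seed = seed, label = label)
}

new_msa <- function(gamma, v_full, v_empty, efficiency_residual, m,
                    seed = NULL, label = "game", cache_stats = NULL,
                    exhaustive = FALSE) {
  structure(
    list(
      gamma = gamma,
      v_full = v_full,
      v_empty = v_empty,
      efficiency_residual = efficiency_residual,
      m = m,
      seed = seed,
      exhaustive = exhaustive,
      label = label,
      cache_stats = cache_stats
    ),
    class = "msa"
  )
}

# ---- orchestration --------------------------------------------------------

#' Run multi-perturbation Shapley value analysis on a game
#'
#' Orchestrates the full estimator: sample (or enumerate) player orderings,
#' expand each into its chain of nested lesion sets, evaluate the game once
#' per distinct coalition, contrast consecutive outcomes into marginal
#' contributions, and average them into an `n_players x T` matrix of
#' time-resolved Shapley values.
#'
#' Because every sampled ordering contributes a complete telescoping chain,
#' the efficiency axiom holds *exactly* (to floating-point accumulation) for
#' any `m >= 1`: the contributions sum, sample-wise, to
#' `v(N) - v(empty)`.
#'
#' @inheritParams sample_orderings
#' @param game An [msa_game].
#' @param null_contrast If `TRUE`, run the control in which the lesion
#'   operator is the identity (see [null_contrast_game()]); all contributions
#'   are then exactly zero.
#' @param cache Optional warm [msa_cache()].
#' @return An object of class `msa` with elements `gamma` (players x T
#'   contribution matrix), `v_full`, `v_empty`, `efficiency_residual`
#'   (T-vector), `m`, `seed`, `label` and `cache_stats` (game evaluation
#'   counts). Use [tidy.msa()], [glance.msa()] and [autoplot.msa()] to
#'   explore it.
#'
#' @examples
#' bank <- sine_bank(c(0.5, 1), c(1, 3), timebase = seq(0, 2 * pi, length.out = 64))
#' res <- run_msa(toy_game(bank, "sum"), m = 5, seed = 1)
#' glance(res)
#' max(abs(res$gamma - bank_values(bank)))  # additive game: exact recovery
#' @export
run_msa <- function(game, m = 100L, seed = NULL, exhaustive = FALSE,
                    null_contrast = FALSE, cache = msa_cache()) {
  stopifnot(inherits(game, "msa_game"))
  played <- if (null_contrast) null_contrast_game(game) else game
  orderings <- sample_orderings(game$n_players, m = m, seed = seed,
                                exhaustive = exhaustive)
  evaluate_coalitions(played, orderings, cache)
  marginals <- marginal_contributions(cache, orderings)
  v_full <- cache_lookup(cache, integer())
  v_empty <- cache_lookup(cache, seq_len(game$n_players))
  res <- shapley_from_marginals(marginals, v_full = v_full, v_empty = v_empty,
                                seed = seed, label = played$label)
  res$exhaustive <- exhaustive
  res$cache_stats <- list(
    evaluations = cache$misses,
    hits = cache$hits,
    distinct_coalitions = cache_size(cache)
  )
  res
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf(
    "<msa '%s': %d players x %d samples, m = %d%s>\n",
    x$label, nrow(x$gamma), ncol(x$gamma), x$m,
    if (isTRUE(x$exhaustive)) " (exhaustive)" else ""
  ))
  cat(sprintf("  max |efficiency residual| = %.3g\n",
              max(abs(x$efficiency_residual))))
  invisible(x)
}

#' Tidy a contribution matrix into long format
#'
#' @param x An `msa` object.
#' @param ... Unused.
#' @return A tibble with columns `node`, `time` (sample index) and
#'   `contribution`.
#' @method tidy msa
#' @export
tidy.msa <- function(x, ...) {
  gamma <- x$gamma
  tibble::tibble(
    node = rep(seq_len(nrow(gamma)), each = ncol(gamma)),
    time = rep(seq_len(ncol(gamma)), times = nrow(gamma)),
    contribution = as.vector(t(gamma))
  )
}

#' One-row summary of an MSA run
#'
#' @param x An `msa` object.
#' @param ... Unused.
#' @return A tibble with the run's dimensions, sampling settings, efficiency
#'   residual and game-evaluation accounting.
#' @method glance msa
#' @export
glance.msa <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    n_players = nrow(x$gamma),
    n_samples = ncol(x$gamma),
    m = x$m,
    exhaustive = isTRUE(x$exhaustive),
    max_abs_efficiency_residual = max(abs(x$efficiency_residual)),
    game_evaluations = x$cache_stats$evaluations %||% NA_integer_,
    cache_hits = x$cache_stats$hits %||% NA_integer_
  )
}

#' Plot contribution time series
#'
#' One line per player, the grand-coalition outcome overlaid in grey.
#'
#' @param object An `msa` object.
#' @param nodes Optional subset of player indices to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msa
#' @export
autoplot.msa <- function(object, nodes = NULL, ...) {
  long <- tidy.msa(object)
  if (!is.null(nodes)) long <- dplyr::filter(long, .data$node %in% nodes)
  outcome <- tibble::tibble(time = seq_along(object$v_full),
                            value = object$v_full)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$contribution,
                                     group = .data$node,
                                     colour = factor(.data$node))) +
    ggplot2::geom_line(data = outcome,
                       ggplot2::aes(.data$time, .data$value),
                       inherit.aes = FALSE, colour = "grey60",
                       linewidth = 1) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "sample", y = "contribution", colour = "node",
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Export contributions as a delimited table
#'
#' Long format (`node`, `time`, `contribution`) TSV at full precision,
#' alongside a JSON manifest recording `m`, the seed and the baseline
#' outcome.
#'
#' @param msa An `msa` object.
#' @param path Path of the TSV to write; the manifest is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_contributions <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  write_tsv_full(tidy.msa(msa), path)
  manifest <- list(
    label = msa$label,
    n_players = nrow(msa$gamma),
    n_samples = ncol(msa$gamma),
    m = msa$m,
    seed = msa$seed,
    exhaustive = isTRUE(msa$exhaustive),
    max_abs_efficiency_residual = max(abs(msa$efficiency_residual)),
    v_empty = msa$v_empty,
    cache_stats = msa$cache_stats
  )
  jsonlite::write_json(manifest, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_contributions
#' @export
read_contributions <- function(path) {
  long <- tibble::as_tibble(utils::read.delim(path, sep = "\t"))
  tidyr::pivot_wider(long, names_from = "time", values_from = "contribution")
}
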