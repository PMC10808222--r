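#' Check that contributions reconstruct the outcome
#'
#' By the efficiency property, summing all per-node contributions and adding
#' the empty-coalition baseline must reproduce the intact system's output
#' sample-wise. The residual series quantifies how exactly this holds; for a
#' correct decomposition it is floating-point accumulation noise only.
#'
#' @param msa An [run_msa()] result, or a plain contribution matrix
#'   (nodes x T).
#' @param reference_output The intact output series (defaults to the `msa`
#'   object's grand-coalition outcome).
#' @param v_empty Baseline outcome with every node lesioned (defaults to the
#'   `msa` object's; zero for the toy games).
#' @return A tibble with columns `time`, `residual`, and attributes
#'   `max_abs_residual` and `max_abs_relative` (relative to the reference's
#'   scale).
#' @export
reconstruction_residual <- function(msa, reference_output = NULL,
                                    v_empty = NULL) {
  if (inherits(msa, "msa")) {
    gamma <- msa$gamma
    reference_output <- reference_output %||% msa$v_full
    v_empty <- v_empty %||% msa$v_empty
  } else {
    gamma <- as.matrix(msa)
  }
  if (is.null(reference_output)) {
    abort("`reference_output` is required for a bare contribution matrix.",
          class = "tsmsa_invalid_argument")
  }
  v_empty <- v_empty %||% numeric(ncol(gamma))
  if (ncol(gamma) != length(reference_output) ||
      length(v_empty) != length(reference_output)) {
    abort("Contribution, reference and baseline lengths must match.",
          class = "tsmsa_invalid_argument")
  }
  residual <- colSums(gamma) + v_empty - reference_output
  scale <- max(abs(reference_output), 1e-12)
  tibble::new_tibble(
    tibble::tibble(time = seq_along(residual), residual = residual),
    max_abs_residual = max(abs(residual)),
    max_abs_relative = max(abs(residual)) / scale,
    class = "tsmsa_residual"
  )
}

#' Correlate each node's activity with its causal contribution
#'
#' Computes, per node, the Pearson correlation between its activity trace and
#' its contribution series over the same (test-phase) window, together with
#' the standard deviations of both series. Nodes whose activity or
#' contribution has zero variance get `pearson_r = NA` and `defined = FALSE`
#' rather than an error, so downstream histograms can state their
#' denominator.
#'
#' @param activity Activity matrix, either `T x N` (states, as stored in an
#'   `esn_run`) or `N x T`; `N` must match the contribution matrix.
#' @param msa An [run_msa()] result (or a nodes x T contribution matrix).
#' @return A tibble with one row per node: `node`, `pearson_r`, `defined`,
#'   `activity_sd`, `contribution_sd`.
#' @export
contribution_activity_correlations <- function(activity, msa) {
  gamma <- if (inherits(msa, "msa")) msa$gamma else as.matrix(msa)
  activity <- as.matrix(activity)
  n <- nrow(gamma)
  if (nrow(activity) != n && ncol(activity) == n) activity <- t(activity)
  if (nrow(activity) != n || ncol(activity) != ncol(gamma)) {
    abort("Activity and contribution dimensions do not match.",
          class = "tsmsa_invalid_argument")
  }
  purrr::map_dfr(seq_len(n), function(i) {
    a_sd <- sd(activity[i, ])
    c_sd <- sd(gamma[i, ])
    defined <- a_sd > 0 && c_sd > 0
    tibble::tibble(
      node = i,
      pearson_r = if (defined) cor(activity[i, ], gamma[i, ]) else NA_real_,
      defined = defined,
      activity_sd = a_sd,
      contribution_sd = c_sd
    )
  })
}

#' Rank nodes by readout weight and contribution spread
#'
#' Joins the per-node summaries with the trained readout weights, computes
#' the spread ratio (contribution sd over activity sd), sorts by absolute
#' weight, and flags the three focal nodes: largest, smallest and median
#' absolute weight (lower median for even counts; ties broken by node
#' index).
#'
#' @param summaries A [contribution_activity_correlations()] tibble.
#' @param w_out The trained readout matrix (or its reservoir-weight vector);
#'   only the first `N` reservoir entries are used.
#' @return The summaries tibble with added columns `readout_weight`,
#'   `abs_weight`, `spread_ratio` and `focus`
#'   (`"max"`/`"min"`/`"median"`/`NA`), sorted by decreasing `abs_weight`.
#' @export
weight_spread_table <- function(summaries, w_out) {
  n <- nrow(summaries)
  w <- if (is.matrix(w_out)) w_out[1, seq_len(n)] else w_out[seq_len(n)]
  tab <- dplyr::mutate(
    summaries,
    readout_weight = w,
    abs_weight = abs(w),
    spread_ratio = .data$contribution_sd / .data$activity_sd
  )
  # ascending |weight| with node-index tie-break, so degenerate all-equal
  # weights still yield a deterministic focal selection
  asc <- order(tab$abs_weight, tab$node)
  min_node <- tab$node[asc[1]]
  max_node <- tab$node[order(-tab$abs_weight, tab$node)[1]]
  median_pos <- if (n %% 2 == 0) n %/% 2 else (n + 1) %/% 2  # lower median
  median_node <- tab$node[asc[median_pos]]
  tab$focus <- NA_character_
  tab$focus[tab$node == max_node] <- "max"
  tab$focus[tab$node == min_node] <- "min"
  if (is.na(tab$focus[tab$node == median_node])) {
    tab$focus[tab$node == median_node] <- "median"
  }
  dplyr::arrange(tab, dplyr::desc(.data$abs_weight))
}

#' Histogram of activity-contribution correlations
#'
#' @param summaries A [contribution_activity_correlations()] tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot; the subtitle states how many nodes had an undefined
#'   (zero-variance) correlation.
#' @export
plot_correlation_histogram <- function(summaries, bins = 20) {
  n_undef <- sum(!summaries$defined)
  ggplot2::ggplot(dplyr::filter(summaries, .data$defined),
                  ggplot2::aes(.data$pearson_r)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(
      x = "Pearson r (activity vs. contribution)", y = "nodes",
      subtitle = sprintf("%d of %d nodes defined (%d zero-variance)",
                         sum(summaries$defined), nrow(summaries), n_undef)
    ) +
    ggplot2::theme_minimal()
}

#' Contribution-activity phase-space scatter for the focal nodes
#'
#' Plots each focal node's trajectory in the plane spanned by its activity
#' (x) and its contribution (y); a large readout weight stretches the cloud
#' along the contribution axis, a small one along the activity axis.
#'
#' @param activity Activity matrix (`T x N` or `N x T`).
#' @param msa An [run_msa()] result.
#' @param spread_table A [weight_spread_table()] tibble identifying the focal
#'   nodes.
#' @return A ggplot.
#' @export
plot_contribution_activity <- function(activity, msa, spread_table) {
  gamma <- msa$gamma
  activity <- as.matrix(activity)
  if (nrow(activity) != nrow(gamma)) activity <- t(activity)
  focal <- dplyr::filter(spread_table, !is.na(.data$focus))
  long <- purrr::map_dfr(seq_len(nrow(focal)), function(j) {
    i <- focal$node[j]
    tibble::tibble(node = i, focus = focal$focus[j],
                   activity = activity[i, ], contribution = gamma[i, ])
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$activity, .data$contribution,
                                     colour = .data$focus)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(max = "firebrick",
                                            median = "skyblue",
                                            min = "navy")) +
    ggplot2::labs(x = "activity", y = "contribution",
                  colour = "|readout weight|") +
    ggplot2::theme_minimal()
}
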