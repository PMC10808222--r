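#' Run one of the packaged end-to-end experiments
#'
#' Reproducible pipelines over the package's building blocks:
#'
#' * `"toys"` — builds the 30-signal cosine bank (amplitudes 0.2-1.8,
#'   angular frequencies 1-8.5, phase pi/2), runs MSA on the sum, scaled and
#'   tanh games, and writes one contribution artifact per game.
#' * `"mackey-glass"` — integrates the chaotic series, grid-searches and
#'   trains the small-world ESN, runs MSA over its reservoir nodes (readout
#'   retraining after each lesion), and writes contribution, activity and
#'   summary artifacts.
#' * `"freq-gen"` — trains the 100-unit random-topology frequency generator,
#'   runs MSA over its nodes, and writes the same artifact set.
#'
#' Every run writes a JSON manifest capturing the merged configuration, all
#' derived seeds, the package version and content hashes of each artifact, so
#' a rerun with the same configuration reproduces identical hashes.
#'
#' @param name `"toys"`, `"mackey-glass"` or `"freq-gen"`.
#' @param out_dir Artifact directory (created if missing).
#' @param seed Master seed; every stage seed is derived from it.
#' @param m Number of sampled orderings for MSA.
#' @param null_contrast Run the identity-lesion control instead of real
#'   lesions (all contributions must then be zero).
#' @param retrain Refit the readout after each lesion (ESN experiments).
#' @param small Use the reduced profile (12-unit reservoirs, shortened
#'   series) for fast runs and enumeration-scale oracles.
#' @param config Named list of overrides merged over the experiment's
#'   defaults (the merged result is what the manifest records).
#' @return Invisibly, a list with the manifest (also written to
#'   `manifest.json`), the `msa` result(s) and the artifact paths.
#' @export
run_experiment <- function(name = c("toys", "mackey-glass", "freq-gen"),
                           out_dir,
                           seed = 1L,
                           m = 50L,
                           null_contrast = FALSE,
                           retrain = TRUE,
                           small = FALSE,
                           config = list()) {
  name <- rlang::arg_match(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 4)
  runner <- switch(name,
    "toys" = run_toys_experiment,
    "mackey-glass" = run_mg_experiment,
    "freq-gen" = run_freq_gen_experiment
  )
  started <- Sys.time()
  result <- runner(out_dir = out_dir, seeds = seeds, m = m,
                   null_contrast = null_contrast, retrain = retrain,
                   small = small, config = config)
  manifest <- list(
    experiment = name,
    package_version = as.character(utils::packageVersion("tsmsa")),
    seed = seed,
    derived_seeds = seeds,
    m = m,
    null_contrast = null_contrast,
    retrain = retrain,
    small = small,
    config = result$config,
    artifacts = lapply(result$artifacts, function(p) {
      list(path = basename(p), sha = rlang::hash(readLines(p)))
    }),
    stats = result$stats,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), started, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(c(result, list(manifest = manifest)))
}

merge_config <- function(defaults, overrides) {
  defaults[names(overrides)] <- overrides
  defaults
}

run_toys_experiment <- function(out_dir, seeds, m, null_contrast, retrain,
                                small, config) {
  cfg <- merge_config(list(
    amplitudes = c(0.2, 0.6, 1, 1.4, 1.8),
    frequencies = c(1, 2.5, 4, 5.5, 7, 8.5),
    phase = pi / 2,
    n_samples = if (small) 100L else 500L,
    scale_factor = 2
  ), config)
  bank <- sine_bank(cfg$amplitudes, cfg$frequencies, cfg$phase,
                    timebase = seq(0, 2 * pi, length.out = cfg$n_samples))
  artifacts <- file.path(out_dir, "bank.tsv")
  write_sine_bank(bank, artifacts)
  results <- list()
  stats <- list()
  for (kind in c("sum", "scaled", "tanh")) {
    game <- toy_game(bank, kind, scale_factor = cfg$scale_factor)
    res <- run_msa(game, m = m, seed = seeds[1],
                   null_contrast = null_contrast)
    path <- file.path(out_dir, paste0("contributions-", kind, ".tsv"))
    write_contributions(res, path)
    artifacts <- c(artifacts, path)
    results[[kind]] <- res
    stats[[kind]] <- list(
      max_abs_efficiency_residual = max(abs(res$efficiency_residual)),
      game_evaluations = res$cache_stats$evaluations
    )
  }
  list(config = cfg, artifacts = as.list(artifacts), stats = stats,
       msa = results, bank = bank)
}

run_mg_experiment <- function(out_dir, seeds, m, null_contrast, retrain,
                              small, config) {
  cfg <- merge_config(list(
    n_reservoir = if (small) 12L else 36L,
    n_train = if (small) 800L else 2500L,
    n_test = if (small) 200L else 500L,
    n_validate = if (small) 500L else 1500L,
    rho_grid = c(0.9, 1.1, 1.3),
    leak_grid = c(0.2, 0.4),
    n_instances = if (small) 5L else 50L
  ), config)
  bench <- mg_benchmark(
    seed = seeds[1], n_train = cfg$n_train, n_test = cfg$n_test,
    n_validate = cfg$n_validate, rho_grid = cfg$rho_grid,
    leak_grid = cfg$leak_grid, n_instances = cfg$n_instances,
    config = esn_config(n_reservoir = cfg$n_reservoir,
                        topology = "small_world",
                        conventional_leak = TRUE)
  )
  game <- esn_game(bench$trained, horizon = cfg$n_test, retrain = retrain)
  res <- run_msa(game, m = m, seed = seeds[2], null_contrast = null_contrast)
  finish_esn_experiment(out_dir, cfg, bench$trained, bench$run, res,
                        extra_stats = list(
                          test_mse = bench$test_mse,
                          best_rho = bench$search$best_rho,
                          best_leak = bench$search$best_leak
                        ))
}

run_freq_gen_experiment <- function(out_dir, seeds, m, null_contrast,
                                    retrain, small, config) {
  cfg <- merge_config(list(
    n_reservoir = if (small) 12L else 100L,
    n_train = if (small) 700L else 2100L,
    n_test = if (small) 300L else 900L,
    rho = 0.26,
    input_scale = 5
  ), config)
  task <- freq_gen_signal(cfg$n_train + cfg$n_test, seed = seeds[1])
  esn_cfg <- esn_config(n_reservoir = cfg$n_reservoir, leak_rate = 1,
                        topology = "random", density = 0.1,
                        readout_activation = "tanh",
                        spectral_radius = cfg$rho, seed = seeds[2])
  u <- matrix(task$input * cfg$input_scale, ncol = 1)
  trained <- train_esn(esn_cfg, task$target[seq_len(cfg$n_train)],
                       input = u[seq_len(cfg$n_train), , drop = FALSE])
  test_u <- u[(cfg$n_train + 1):nrow(task), , drop = FALSE]
  run <- free_run(trained$weights, cfg$n_test, input = test_u,
                  init_state = trained$final_state,
                  init_output = trained$final_output)
  game <- esn_game(trained, horizon = cfg$n_test, retrain = retrain,
                   test_input = test_u)
  res <- run_msa(game, m = m, seed = seeds[3], null_contrast = null_contrast)
  finish_esn_experiment(out_dir, cfg, trained, run, res,
                        extra_stats = list(
                          test_mse = esn_mse(
                            run$output,
                            task$target[(cfg$n_train + 1):nrow(task)])
                        ))
}

# Shared tail of the ESN experiments: reconstruction check, summaries,
# artifact writing.
finish_esn_experiment <- function(out_dir, cfg, trained, run, res,
                                  extra_stats = list()) {
  resid <- reconstruction_residual(res, reference_output = drop(run$output))
  summaries <- contribution_activity_correlations(run$states, res)
  spread <- weight_spread_table(summaries, trained$weights$W_out)
  paths <- c(
    contributions = file.path(out_dir, "contributions.tsv"),
    summaries = file.path(out_dir, "node-summaries.tsv"),
    output = file.path(out_dir, "output.tsv")
  )
  write_contributions(res, paths[["contributions"]])
  write_tsv_full(spread, paths[["summaries"]])
  write_tsv_full(tibble::tibble(time = seq_len(nrow(run$output)),
                                output = drop(run$output)),
                 paths[["output"]])
  stats <- c(list(
    max_abs_efficiency_residual = max(abs(res$efficiency_residual)),
    max_abs_reconstruction_residual = attr(resid, "max_abs_residual"),
    game_evaluations = res$cache_stats$evaluations
  ), extra_stats)
  list(config = cfg, artifacts = as.list(unname(paths)), stats = stats,
       msa = res, trained = trained, run = run, spread = spread)
}
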