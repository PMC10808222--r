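test_that("reconstruction holds for toy games and breaks under shuffling", {
  bank <- toy_bank_small(4)
  for (kind in c("sum", "tanh")) {
    res <- run_msa(toy_game(bank, kind), m = 5, seed = 2)
    resid <- reconstruction_residual(res)
    expect_lt(attr(resid, "max_abs_residual"), 1e-12)
    expect_equal(resid$residual, res$efficiency_residual)
  }
  # negative control: permuting one contribution row breaks reconstruction
  res <- run_msa(toy_game(bank, "tanh"), m = 5, seed = 2)
  broken <- res
  broken$gamma[2, ] <- sample(broken$gamma[2, ])
  resid <- reconstruction_residual(broken$gamma,
                                   reference_output = res$v_full)
  expect_gt(attr(resid, "max_abs_residual"), 1e-6)
  expect_error(reconstruction_residual(res$gamma,
                                       reference_output = res$v_full[-1]),
               class = "tsmsa_invalid_argument")
})

test_that("correlations are exact for aligned, negated and scaled rows", {
  set.seed(1)
  activity <- matrix(rnorm(3 * 50), 3, 50)
  gamma <- rbind(activity[1, ],          # identical -> r = 1
                 -activity[2, ],         # negated   -> r = -1
                 3 * activity[3, ] + 2)  # positive affine -> r = 1
  res <- structure(list(gamma = gamma), class = "msa")
  summ <- contribution_activity_correlations(activity, res)
  expect_equal(summ$pearson_r, c(1, -1, 1), tolerance = 1e-12)
  expect_true(all(summ$defined))
  # the scaled toy game preserves correlation exactly
  bank <- toy_bank_small(3)
  scaled <- run_msa(toy_game(bank, "scaled"), m = 4, seed = 9)
  s2 <- contribution_activity_correlations(bank_values(bank), scaled)
  expect_equal(s2$pearson_r, rep(1, 3), tolerance = 1e-10)
})

test_that("zero-variance rows are flagged undefined, not dropped", {
  activity <- rbind(rep(1, 20), rnorm(20))
  gamma <- rbind(rnorm(20), rep(0, 20))
  res <- structure(list(gamma = gamma), class = "msa")
  summ <- contribution_activity_correlations(activity, res)
  expect_equal(summ$defined, c(FALSE, FALSE))
  expect_true(all(is.na(summ$pearson_r)))
  expect_equal(nrow(summ), 2)
})

test_that("the weight-spread table ranks nodes and flags focal ones", {
  summaries <- tibble::tibble(
    node = 1:5,
    pearson_r = runif(5, -1, 1),
    defined = TRUE,
    activity_sd = c(1, 2, 1, 2, 1),
    contribution_sd = c(2, 2, 3, 1, 5)
  )
  w <- c(-3, 0.5, 2, -0.1, 1)
  tab <- weight_spread_table(summaries, w)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$node[1], 1)  # largest |weight| first
  expect_equal(tab$focus[tab$node == 1], "max")
  expect_equal(tab$focus[tab$node == 4], "min")
  # lower median of |{3, 2, 1, 0.5, 0.1}| sorted ascending is position 3 -> |w|=1
  expect_equal(tab$focus[tab$node == 5], "median")
  expect_equal(tab$spread_ratio, tab$contribution_sd / tab$activity_sd)

  # degenerate all-equal weights fall back to index order
  tab2 <- weight_spread_table(summaries, rep(1, 5))
  expect_equal(tab2$node[tab2$focus == "min" & !is.na(tab2$focus)], 1)
})

test_that("plots build without error", {
  bank <- toy_bank_small(3)
  res <- run_msa(toy_game(bank, "tanh"), m = 4, seed = 1)
  summ <- contribution_activity_correlations(bank_values(bank), res)
  tab <- weight_spread_table(summ, c(0.1, 1, 0.5))
  expect_s3_class(plot_correlation_histogram(summ), "ggplot")
  expect_s3_class(plot_contribution_activity(bank_values(bank), res, tab),
                  "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
})
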