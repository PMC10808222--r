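# tsmsa — time-resolved multi-perturbation Shapley value analysis

A node's recorded activity and its causal contribution to a network's output
are not the same thing: downstream transformations — readout weights,
summation by other units, saturating nonlinearities — can make a nearly
silent node carry a large share of the output. `tsmsa` measures what each
node *causally* contributes, at every time point, by combining multi-site
virtual lesions with Shapley value attribution. It is aimed at
computational-neuroscience and network-inference work where "which unit is
doing what, and when" must be answered with perturbations rather than read
off activity traces.

## The method

The network is treated as a cooperative game. Players are the nodes, the
characteristic function `v(S)` is the output time series produced when the
complement of the coalition `S` is lesioned (a node's incoming and outgoing
connection weights zeroed), and the contribution of node *i* given a
coalition `S` is

```
Δ_i(S) = v(S ∪ i) − v(S)            (sample-wise, a time series)
```

The time-resolved Shapley value of node *i* averages `Δ_i` over orderings in
which coalitions can be assembled:

```
γ_i(t) = (1/|𝓡|) Σ_{R ∈ 𝓡} Δ_i(S_i(R))(t)
```

Enumerating all `N!` orderings is infeasible, so `run_msa()` samples `m`
orderings uniformly (an unbiased estimator), expands each into its chain of
nested lesion sets, evaluates the game once per *distinct* coalition
(memoised), contrasts consecutive outcomes, and averages. Because every
sampled ordering contributes a full telescoping chain, the efficiency axiom

```
Σ_i γ_i(t) = v(N)(t) − v(∅)(t)
```

holds exactly (to floating-point accumulation) for any `m ≥ 1` — summing the
contributions reconstructs the network's output.

The package ships the testbeds this framework is demonstrated on:

* **Toy games** (`sine_bank()`, `toy_game()`): 30 cosine signals combined by
  a sum, a doubled sum, or a tanh-saturated sum.
* **Mackey–Glass prediction** (`mackey_glass()`, `mg_benchmark()`): a
  36-unit small-world echo state network (ESN) trained in generative mode on
  the chaotic delay-differential series (τ = 17).
* **Frequency generator** (`freq_gen_signal()`, `freq_gen_benchmark()`): a
  100-unit random-topology ESN turning a slow random step command
  (1/25–1/5 Hz) into a sine of the commanded frequency.
* **Diagnostics** (`reconstruction_residual()`,
  `contribution_activity_correlations()`, `weight_spread_table()`, plus
  `tidy()`/`glance()`/`autoplot()` methods and ggplot2 helpers) for the
  activity-versus-contribution comparison.

## Worked example

Thirty sinusoids feed a unit that sums them and applies `tanh`; MSA recovers
each input's (warped) causal contribution:

```r
library(tsmsa)

bank <- sine_bank(c(0.2, 0.6, 1, 1.4, 1.8), c(1, 2.5, 4, 5.5, 7, 8.5))
game <- toy_game(bank, "tanh")
res  <- run_msa(game, m = 20, seed = 1)
res
#> <msa 'toy-tanh': 30 players x 500 samples, m = 20>
#>   max |efficiency residual| = 9.99e-16

glance(res)
#>   label    n_players n_samples  m exhaustive max_abs_efficiency_residual game_evaluations cache_hits
#> 1 toy-tanh        30       500 20      FALSE                9.992007e-16              568         52
```

The efficiency residual at machine precision says the 30 contribution time
series sum, sample for sample, to the warped output — the decomposition is
exact, not approximate. The cache accounting shows 568 distinct lesion
configurations were evaluated instead of the 620 requested. Contributions
are *not* the activities:

```r
summ <- contribution_activity_correlations(bank_values(bank), res)
head(summ, 3)
#>   node pearson_r defined activity_sd contribution_sd
#> 1    1 0.922     TRUE        0.141          0.0437
#> 2    2 0.890     TRUE        0.139          0.0421
#> 3    3 0.895     TRUE        0.141          0.0487
```

Each signal's contribution correlates imperfectly with its activity and is
compressed (sd 0.04 vs 0.14) — the saturating downstream transform warps
every input's effective contribution. For an additive game (`kind = "sum"`)
the same call returns `pearson_r = 1` and `γ_i(t) = x_i(t)` exactly.

The same pipeline runs on trained networks: `train_esn()` +
`esn_game()` expose a reservoir as a lesionable game (with the readout
retrained after each lesion), and `run_experiment("mackey-glass", ...)`
orchestrates generate → train → MSA → analyse end-to-end, writing TSV
artifacts and a JSON manifest of seeds and content hashes.

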