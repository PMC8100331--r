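# crba

Unsupervised competitive learning with a rate-based, one-pass approximation
of competitive spiking neural networks — plus the time-stepped spiking
network it approximates, so the approximation itself can be tested.

## Who this is for

Competitive spiking networks (two layers of leaky integrate-and-fire neurons
with lateral inhibition, Poisson rate coding, STDP and adaptive firing
thresholds) learn class prototypes without labels, but simulating thousands
of sub-millisecond time steps per sample presentation makes them painfully
slow on conventional hardware. This package is for people who want the
learning behavior of such a network at in-memory K-means-like speed — and
for people who want to study the approximation: every rate-based shortcut
here has its spiking counterpart in the same package, with closed-form
oracles connecting the two.

## The algorithm

For a sample `x` (non-negative, rescaled to `[0, 1]`) and weight matrix `W`
(one column per neuron, columns normalized to sum λ), one presentation does:

1. `rate_j = ⟨x, W_j⟩ / θ_j` — dot-product ranking scaled by each neuron's
   adaptive threshold. Under a constant-rate drive the LIF first-spike time
   is `t_f = τ_u [log S − log(S − θ)]` with `S = τ_u β ⟨x, w⟩`, so ranking by
   rate reproduces the spiking network's firing order.
2. The top `n` rates win (`n = 1` under strong inhibition).
3. Winner `k` at rank `i` is predicted to fire
   `spikes_k = α_s · t · rate_k · e^(−5i/n)` spikes.
4. `W_k ← W_k + α_w · spikes_k · x` and `θ_k ← θ_k + α_θ · spikes_k`; all
   thresholds then decay one step toward their resting value. The weight
   update plus renormalization is a sequential discrete-EM step: each column
   tracks the centroid of the samples its neuron wins, which is the same
   prototype STDP extracts in the spiking network.
5. Columns renormalize to sum λ.

Neurons are then labeled by per-class activity and predict by maximum voting
(average response per label group). A trained model can initialize the
spiking network directly: weights copy verbatim, thresholds rescale linearly
onto 35–60 mV.

## Worked example

```r
library(crba)

data <- make_synthetic(k = 10, p = 196, per_class = 500, seed = 42)
fit  <- crba_fit(data, crba_config(m = 40, n = 1, seed = 42),
                 presentations = 20000, metrics_every = 5000)
fit$metrics
#> # A tibble: 4 × 5
#>   presentation mean_theta min_theta max_theta mean_winner_spikes
#>          <dbl>      <dbl>     <dbl>     <dbl>              <dbl>
#> 1         5000       105.      113.      227.              22.2
#> 2        10000       183.      155.      312.              10.6
#> 3        15000       231.      185.      373.               8.38
#> 4        20000       266.      208.      420.               7.25
```

Thresholds rise while predicted winner spike counts fall — the homeostatic
signature of the competition settling. Labeling and evaluating on the same
fixture:

```r
fit <- crba_label(fit, data)
crba_evaluate(fit, data)
#> # A tibble: 1 × 3
#>   accuracy n_correct     n
#>      <dbl>     <int> <int>
#> 1        1      5000  5000
```

With 40 neurons over 10 clusters every class ends up represented and the
separable fixture is classified perfectly. (With `m` equal to the number of
clusters, sample-based initialization can leave clusters unrepresented — see
the vignette's limitations section.) Transferring into the spiking network
and simulating a few presentations:

```r
state <- transfer_parameters(fit)
state
#> <csnn_state: 40 neurons, 196 channels, thresholds 35.00 .. 60.00 mV>
csnn_simulate(head(data, 20), state, learning = FALSE, seed = 1)$results
#> # A tibble: 20 × 3  (first rows shown)
#>   sample winner n_spikes
#> 1      1     20        7
#> 2      2      1        5
#> 3      3      6        5
```

`winner` is the first neuron to spike in the simulated network; agreement
with the rate model's argmax is the package's transfer-fidelity measure.

A command-line interface wrapping the same functions ships at
`inst/cli/crba` (subcommands `make-data`, `train`, `label`, `predict`,
`evaluate`, `simulate`, `transfer`).

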