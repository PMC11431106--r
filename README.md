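# patsep

Controlled evaluation of spike-train pattern-separation indices on a
two-neuron statistical manifold.

## The problem

Pattern separation — a circuit (classically the hippocampal dentate gyrus)
mapping similar input patterns to more dissimilar output patterns — is
measured in the literature with many different dissimilarity indices, and
different indices can disagree about whether, and how much, separation
happened. `patsep` provides a maximally controlled testbed for such indices:
a two-neuron system whose joint spiking law is known in closed form, so the
*kind* and *degree* of separation between two pattern-generating
distributions can be dialled exactly, and any index can be scored against
that ground truth.

## The model

A pair of binary neurons in one time bin has joint law
`q_mn = P(x1 = m, x2 = n)`, `m, n ∈ {0, 1}`. The three-dimensional family of
such laws is parameterized by the mixed coordinates

- `η1 = q10 + q11`, `η2 = q01 + q11` — each neuron's marginal firing
  probability per bin;
- `θ = log(q11 q00 / (q10 q01))` — the log odds ratio measuring
  within-ensemble correlation (0 = independence, ±∞ = maximal
  (anti-)correlation).

Under the Fisher information metric `g(ξi, ξj) = E[∂i log p · ∂j log p]`,
the rate coordinates `(η1, η2)` are orthogonal to `θ`:
`g(η1, θ) = g(η2, θ) = 0`. The squared infinitesimal distance between two
nearby laws is the quadratic form `ds² = Σ g(ξi, ξj) dξi dξj`, which equals
twice the Kullback–Leibler divergence to first order. Orthogonality means a
pure `dθ` step gives `ds² = g(θ, θ) dθ²` and a pure `dη2` step gives
`ds² = g(η2, η2) dη2²` — the two separation mechanisms (changing *how much*
neurons fire vs changing their *relative timing/coincidence*) can be probed
independently.

Patterns are sampled as `2 × Nbins` binary matrices (one categorical draw
over `{00, 10, 01, 11}` per bin) and converted to spike trains by placing a
time stamp at each active bin's center within a 0–16 ms window.

Eight indices are implemented: Pearson correlation, cosine similarity,
scaling factor (norm ratio), bin-wise Hamming distance, SPIKE similarity
(time-averaged Kreuz dissimilarity profile), nearest-neighbour estimated
mutual information over Wasserstein distances between pattern segments,
plug-in transfer entropy on the binned representation, and relative
redundancy reduction `(R(T1) − R(T2)) / MI(T1, T2)`.

Two sweep experiments apply all indices to sampled control/comparison
pattern pairs: the **correlation sweep** (`build_dtheta_sweep()`) holds both
marginals fixed at `η1` and `1 − η1` and moves only `θ`; the **rate sweep**
(`build_deta2_sweep()`) holds `θ = 0` and `η1` fixed and raises `η2` from
0.1 by `dη2`.

## Worked example

```r
library(patsep)

# Fisher metric at an interior point: rate/correlation orthogonality
fisher_information(coords(0.5, 0.3, 0.7))
#>            eta1      eta2    theta
#> eta1   4.102405 -0.707198 0.000000
#> eta2  -0.707198  4.883816 0.000000
#> theta  0.000000  0.000000 0.050165

# A small rate sweep: 5 increments, 5 trials of 500-bin patterns each
spec <- build_deta2_sweep(eta1 = 0.5, deta2_grid = seq(0, 0.8, 0.2),
                          n_bins = 500, n_trials = 5, seed = 42)
r <- run_sweep(spec, indices = c("hamming", "spike", "scaling_factor"))
dplyr::select(tibble::as_tibble(r), increment, hamming_mean, hamming_sem,
              spike_mean, scaling_factor_mean)
#>   increment hamming_mean hamming_sem spike_mean scaling_factor_mean
#> 1       0          0.343     0.00675      0.726               1.02
#> 2       0.2        0.425     0.00823      0.710               0.856
#> 3       0.4        0.497     0.00457      0.694               0.786
#> 4       0.6        0.583     0.00533      0.681               0.687
#> 5       0.8        0.660     0.00887      0.669               0.652

summarize_trends(r)
#>   index          rank_correlation p_value n_points defined
#> 1 hamming                       1  0.0165        5 TRUE
#> 2 spike                        -1  0.0160        5 TRUE
#> 3 scaling_factor               -1  0.0180        5 TRUE
```

The Hamming distance grows and the SPIKE similarity and scaling factor fall
as neuron 2's rate diverges from the control — every index responds to
rate-driven separation. Running the correlation sweep instead
(`build_dtheta_sweep(eta1 = 0.5)`) shows the classic indices flat in `dθ`:
they do not register separation that changes only the neurons' coincidence
structure, even though the information distance `g(θ,θ) dθ²` between the
generating laws grows just the same.

`autoplot(r)` draws the mean ± SEM panels per index; `tidy(r)` and
`glance(r)` give long-format and one-row summaries. A command-line wrapper
for the sweeps and indices lives at `inst/cli/patsep.R`.

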