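---
title: "Methods: the two-neuron manifold and the index testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-neuron manifold and the index testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patsep)
```

## The model and its assumptions

`patsep` treats a pattern separator as a statistical manifold: each input is
a coordinate point, the point is a probability law over output patterns, and
separation between two inputs is the distance between their laws. The
concrete instance is the simplest non-trivial one: two binary neurons in
discrete time. Per time bin the joint law is the four probabilities
$q_{mn} = P(x_1 = m, x_2 = n)$; bins are i.i.d. (the law is
time-independent), and a neuron emits at most one spike per bin. These are
deliberate simplifications — there is no refractoriness, no burstiness, no
rate drift — chosen so that every quantity of interest has a closed form.

The mixed coordinates are $\eta_1 = q_{10}+q_{11}$,
$\eta_2 = q_{01}+q_{11}$ (marginal firing probabilities per bin,
dimensionless in $(0,1)$) and the log odds ratio
$\theta = \log\frac{q_{11}q_{00}}{q_{10}q_{01}}$ (dimensionless, unbounded).
$(\eta_1,\eta_2)$ and $\theta$ are orthogonal under the Fisher metric, which
is what makes the testbed controlled: a sweep can move correlation without
touching rates, or one rate without touching correlation.

## Numerical choices on the manifold

**Inverting the coordinates.** `law_of()` must solve for the coincidence
probability $q_{11}$ given $(\eta_1,\eta_2,\theta)$. With $A = e^\theta$
this is the quadratic $(A-1)q_{11}^2 - [(A-1)(\eta_1+\eta_2)+1]q_{11} +
A\eta_1\eta_2 = 0$. The root is taken with the numerically stable two-root
formula and accepted only inside the Fréchet interval
$[\max(0,\eta_1+\eta_2-1), \min(\eta_1,\eta_2)]$; because $\theta$ is
strictly increasing in $q_{11}$ on that interval the admissible root is
unique, and a bisection on $\theta(q_{11})$ serves as fallback when the
quadratic is ill-conditioned (e.g. $|\theta|$ very large). At
$|\theta| < 10^{-12}$ the independence solution $q_{11}=\eta_1\eta_2$ is
used directly. Round-tripping law → coordinates → law is tested to
$10^{-10}$ per component.

**Fisher matrix.** The expectation in
$g(\xi_i,\xi_j) = E[\partial_i \log p\, \partial_j \log p]$ is exact (a
4-term sum); only the scores are numeric, by central finite differences with
step $10^{-6}$ through `law_of()`. That step balances truncation
($\sim\!10^{-12}$) against cancellation ($\sim\!10^{-10}$) for
double-precision log-probabilities; the independent-case closed form
$g(\eta,\eta) = 1/(\eta(1-\eta))$ and the orthogonality zeros are recovered
to well below $10^{-6}$. Points with any $q_{mn} < 10^{-4}$, or a marginal
within $10^{-4}$ of 0 or 1, are rejected as ill-conditioned rather than
returning an inaccurate metric; sampling does not need the metric, so
near-boundary laws remain usable for pattern generation.

**Distances.** `squared_distance()` is the quadratic form against the full
3×3 matrix; orthogonality makes the pure-$d\theta$ and pure-$d\eta_2$
specializations exact, and the suite verifies $ds^2 \approx 2\,\mathrm{KL}$
with first-order convergence in the step size.

## What the generator emulates — and what it does not

`sample_pattern()` draws `n_bins` i.i.d. categorical outcomes and fills a
`2 × n_bins` 0/1 matrix; `to_spike_times()` stamps each active bin at its
center on a 0–16 ms window. The defaults mirror the study conditions the
sweeps are built for: 1000 bins, 10 control/comparison pairs per grid point,
a 16 ms window. Bin-center placement keeps trains symmetric under time
reversal of the pattern; a left-edge option exists for users who prefer
alignment with bin onsets. One master seed per sweep yields deterministic
child seeds per (grid point, trial, member) —
`(seed + 1000003·point + 7919·trial + 500009·member) mod (2^31 − 1)` — so
any single trial can be reproduced in isolation.

Because bins are i.i.d. and spikes sit on a lattice of bin centers, the
synthetic trains lack inter-spike-interval structure, refractoriness and
jitter. Passing tests therefore certify an index's response to *rate* and
*coincidence* differences under noise-free timing conventions, not its
behaviour on irregular biological trains.

## The sweeps

The correlation sweep fixes $\eta_2 = 1-\eta_1$ (constant total firing; this
requires $\eta_1 \le 0.5$ under the $\eta_2 \ge \eta_1$ convention) and
shifts $q_{00}, q_{11}$ up and $q_{10}, q_{01}$ down by a common $dq_{11}$,
which provably leaves both marginals untouched. The grid is 21 values of
$q_{11}$ evenly spaced on $[10^{-2}, \eta_1 - 10^{-2}]$ — under
$\eta_1+\eta_2=1$ the anti-correlated end automatically has
$q_{00}=q_{11}=10^{-2}$ and the correlated end $q_{10}=10^{-2}$. The rate
sweep fixes $\theta = 0$ (so $q_{11} = \eta_1\eta_2$) and raises $\eta_2$
from the sparse baseline 0.1 by 17 evenly spaced increments up to 0.8. Grid
densities are package choices (the underlying construction only prescribes
the endpoints); both are configurable. Each trial resamples the control
pattern as well as the comparison — error bars on every index then reflect
variability in both pair members, and SEM over trials is the reported
uncertainty.

## Index conventions

**SPIKE similarity.** The Kreuz dissimilarity profile $D(t)$ needs
preceding/following spikes at every $t$; auxiliary spikes at $t=0$ and
$t=\tau$ on both trains (the convention of the original SPIKE-distance
literature) make the profile total. Two silent trains then compare as
identical ($\delta_S = 1$). The ambiguous normalization in $D(t)$ is read as
the squared mean of the two instantaneous ISIs,
$2\langle x_{ISI}\rangle^2$, following the cited SPIKE-distance definition.
The time integral uses the midpoint rule on a uniform grid (default 16
points per pattern bin), whose nodes never coincide with lattice spike
times; agreement with a $10^6$-point brute-force quadrature oracle is tested
to $10^{-3}$.

**Wasserstein segment distance.** Each period's spikes carry mass $1/n$;
equal counts reduce to the mean absolute difference of sorted times, unequal
counts use the quantile-function integral. An empty period against a
non-empty one is scored at the period length (maximal displacement) — a
convention, flagged as such, chosen so that presence/absence of activity is
maximally informative to the estimator; two empty periods are at distance 0.
Multi-neuron segments sum per-neuron distances (alternatives such as max or
mean would only rescale the neighbour ranking the estimator consumes).

**Estimated mutual information.** Patterns are cut into $N = 50$ periods
and smoothed with $h = 3$ (defaults; the estimator is exposed through
`estimator_config()` and the identity $\hat d_M(T,T) = \log(N/h)$ holds for
every $N, h$). Discrete spike lattices make distance ties common, so
neighbours are ordered by (distance, period index) and the self pair is
always counted: $C_i \ge 1$, the logarithm never diverges, the estimator is
exactly symmetric, and the identical-pattern value is analytic. The price is
bias: for independent patterns $C_i \ge 1$ forces
$E[\hat d_M] \ge \log(N/h^2) > 0$. The estimate is therefore interpreted
*relatively* — against a permutation/decoupling null, or as differences, as
in redundancy reduction — never as an absolute information content.

**Transfer entropy.** Computed as plug-in conditional mutual information on
the binned joint-state sequences with history length $k=1$ bin by default
(the underlying definition does not fix an embedding; binarized bins with a
short history are the natural choice for lattice patterns), reported in
bits. The plug-in form is non-negative by construction and directional.
Estimated MI uses natural log by default; both units are configurable.

**Undefined values.** Zero-variance or zero-norm inputs yield an explicit
invalid flag (`index_value()`), and `run_sweep()` excludes such trials from
the mean with a decremented `n` and a warning — never silent imputation.

## Known limitations

- Two neurons only; the log-linear family is not implemented for larger
  ensembles, and no geodesic (finite) distances are integrated.
- The MI estimator's bias floor means redundancy reduction inherits a
  systematic component whenever one pattern carries more within-ensemble
  correlation than the other; its sweep profile should be read against the
  estimator's own null rather than as an unbiased information difference.
- Rank-correlation trend calls on a default-sized sweep (10 trials per
  point) can be perturbed by sampling noise where the index response per
  grid step is smaller than its SEM (the top of the SPIKE similarity curve
  in the rate sweep is the canonical example); the suite's monotonicity
  checks therefore use grids coarse enough for the step response to clear
  the noise.
- Problem sizes in the test suite (pattern lengths of 200–1000 bins,
  20-seed estimator simulations, $2\times10^5$-point oracle quadratures) are
  the package's chosen compromise between statistical resolution and a test
  run measured in a couple of minutes.
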