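---
title: "Classifying patterns with one spiking neuron trained by an artificial bee colony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying patterns with one spiking neuron trained by an artificial bee colony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikebee)
library(ggplot2)
```

## The method

spikebee implements a rate-coding classification scheme built on a *single*
Izhikevich spiking neuron. Given a labeled dataset of $p$ patterns
$\mathbf{x}^i \in \mathbb{R}^n$ with classes $k \in \{1,\dots,K\}$:

1. **Current transform.** A pattern does not stimulate the neuron directly;
   each feature acts as the presynaptic potential of a receptive field, and
   the constant stimulation current is $I = \mathbf{x} \cdot \mathbf{w}$,
   where $\mathbf{w} \in \mathbb{R}^n$ is the synaptic weight vector being
   learned.
2. **Simulation.** The neuron is integrated for $T$ ms under that constant
   current and its firing rate is $fr = N_{sp}/T$, the number of spikes in
   the window divided by the window length.
3. **Decision rule.** During training, the average firing rate of each
   class, $\mathrm{AFR}_k$, is the mean rate over that class's patterns. A
   pattern with rate $fr$ is assigned to
   $\arg\min_k |\mathrm{AFR}_k - fr|$ — the nearest class prototype on the
   one-dimensional rate axis.
4. **Learning.** The artificial bee colony (ABC) algorithm minimizes the
   in-sample classification error $1 - \mathrm{performance}(\mathbf{w}, D)$
   over the weight box, so that same-class patterns evoke similar rates and
   different classes evoke discriminable rates.

The working hypothesis is that a weight vector exists under which the
rate-current map of the neuron pulls the classes apart. Because the decision
space is one-dimensional (a firing rate), the single neuron is in effect
learning a projection of feature space onto a line followed by a nearest
prototype rule — nonlinear in the current because of the neuron's f-I curve.

## The neuron model

The Izhikevich simple model is a two-variable quadratic
integrate-and-fire system,

$$C\dot v = k(v - v_r)(v - v_t) - u + I, \qquad
  \dot u = a\bigl(b(v - v_r) - u\bigr),$$

with the after-spike reset: if $v \ge v_{peak}$, then $v \leftarrow c$ and
$u \leftarrow u + d$. `regular_spiking()` returns the cortical
regular-spiking (RS) regime used throughout: $C = 100$, $k = 0.7$,
$v_r = -60$, $v_t = -40$, $v_{peak} = 35$, $a = 0.03$, $b = -2$, $c = -50$,
$d = 100$ (voltages in mV, time in ms, currents in pA, all used
dimensionlessly). The RS regime exhibits class 1 excitability — the firing
rate grows smoothly from zero with the injected current — which is exactly
the property the classifier exploits:

```{r fi-curve}
fi_curve(seq(0, 200, by = 20))
```

The printed model equations are sometimes typeset with the recovery
dynamics nested inside the reset clause; this package implements the
standard form above (continuous $u$ dynamics, reset touching only the
threshold event), which is also how the RS simulation example writes the
equations out explicitly.

### Numerical choices

* **Integration.** Forward Euler with `dt = 1` ms over `t_window = 1000` ms
  (the defaults used by every training run). Both derivatives are evaluated
  on the current state and both variables advanced together; the threshold
  test runs on the updated state; the spike is stamped at that step's time,
  before the reset. The update order is pinned so that an independently
  written step-by-step reference reproduces the spike train exactly — the
  test suite asserts spike-for-spike agreement against such an oracle.
* **Initial conditions.** `v0 = v_r`, `u0 = 0`, the model's resting
  equilibrium. The rate-coding scheme does not prescribe the initial state;
  starting at rest is this package's choice (flagged in
  `simulation_config()`) and makes zero input current provably produce zero
  spikes — both derivatives vanish identically there, so the trace is
  constant.
* **Refractoriness.** The discrete reset admits at most one spike per step,
  so `firing_rate()` is bounded by `1/dt`.
* **Failure mode.** Euler integration of a quadratic model can blow up for
  extreme parameters; a non-finite state aborts with an error naming the
  step rather than propagating NaNs.
* The membrane trace records the raw pre-reset potential; `v` is not
  clamped to `v_peak` for display. Clamping is cosmetic and spike counts do
  not depend on it.

## The optimizer

`abc_optimize()` is a classical artificial bee colony over a box. Each
cycle:

* **Employed phase.** Every food source $\mathbf{x}_i$ (a candidate weight
  vector) produces one neighbour $v_{ij} = x_{ij} + \phi\,(x_{ij} - x_{kj})$
  in a single randomly chosen dimension $j$, with a random partner
  $k \ne i$ and $\phi \sim U[-1, 1]$, clipped to the bounds. A candidate
  with *equal or better* objective replaces the source and resets its trial
  counter; otherwise the counter increments.
* **Onlooker phase.** `n_sources` roulette draws proportional to the nectar
  $fit_i = 1/(1 + f_i)$ (for $f \ge 0$; $1 + |f|$ otherwise), each applying
  the same neighbour-and-replace move to the selected source.
* **Scout phase.** The single source with the largest trial counter, if it
  exceeds `limit`, is re-drawn uniformly in the box,
  $x_{ij} = l_j + \mathrm{rand}(0,1)(u_j - l_j)$ — the same formula that
  initializes the population.

Where the classical description leaves latitude, this package fixes:
one perturbed dimension per candidate, `n_sources` onlooker actions per
cycle, at most one scout per cycle, and ties replacing the incumbent. The
tie rule is taken literally from the usual "equal or better nectar"
phrasing; it also protects against stagnation on plateaus, which matters
here because the classification-error objective is piecewise constant in
$\mathbf{w}$. One seeded generator drives the run with a fixed draw order
(dimension, partner, $\phi$; one uniform per onlooker), so results are
exactly reproducible.

Defaults are the settings used for all classifier experiments:
`n_sources = 40`, `max_cycles = 1000`, `limit = 100`, weight bounds
$[-10, 10]$.

```{r abc-sphere}
sphere <- function(x) sum(x^2)
res <- abc_optimize(sphere, abc_config(dim = 10, max_cycles = 300, seed = 1))
glance(res)
autoplot(res) + scale_y_log10()
```

## Synthetic data

Two generators cover testing without external downloads. Neither tries to
recreate the feature distributions of real benchmark data — only structure
the method can be validated against.

* `make_gaussian_clusters()` emulates the *shape* of UCI-style problems:
  `K` isotropic Gaussian clusters with means at mutual distance
  `separation` (vertices of a regular simplex, which requires
  `K <= features + 1`) and balanced classes within one pattern.
  `separation = 0` gives the hardest, identically distributed case.
* `make_planted()` operationalizes the method's own hypothesis: a known
  weight vector `w_star` maps every class-`k` pattern *exactly* to a target
  current `level_k ± jitter` (the component along `w_star` realizes the
  current; Gaussian noise lives in the orthogonal complement and cannot
  change it). Under `w_star` the classes are therefore separable by
  construction, which makes recovery testable: training should reach the
  planted ceiling, and the per-class AFR ordering should match the planted
  current ordering.

Planted defaults, chosen once: current levels evenly spaced on
$[60, 140]$ pA — inside the RS regime's monotonically increasing rate
region, bracketing the 70 and 100 pA step currents of the classic RS
illustration — with `jitter = 2` pA (small against the 40 pA level gaps)
and $\|\mathbf{w}^\ast\| = 5$, comfortably inside the $[-10,10]$ training
box. `dataset_presets()` mirrors six benchmark shapes (e.g. 3 classes × 4
features × 150 patterns) as generator presets.

What passing on planted data shows: the optimizer can find weights
realizing a rate separation that exists. What it does not show: performance
on real data, where no such weight vector may exist, features are
correlated and scales differ wildly. On shapes like the liver or diabetes
benchmarks the original method itself plateaus well below perfect accuracy.

```{r planted}
pd <- make_planted(classes = 3, features = 4, n = 150, seed = 1)
classification_performance(pd$data, pd$w_star)
```

## The experiment protocol

`run_experiment()` reproduces the evaluation protocol end to end: for each
of `repetitions` (default 30) runs, draw a stratified `train_fraction`
(default 0.80) split, train on the training subset, score both subsets, and
record the optimizer's best-so-far error curve. The summary reports mean,
sample standard deviation and a t-distribution confidence interval
$\bar x \pm t_{1-\alpha/2,\,m-1}\, s/\sqrt{m}$ for the training and testing
classification rates.

Design choices made here:

* **Stratified splits.** The protocol's random 80/20 selection is
  stratified per class: a plain split can empty a class in small datasets,
  leaving the AFR of that class — and with it the decision rule — undefined.
  Stratification is the minimal fix and is the documented behaviour.
* **"±" is the sample standard deviation**, printed alongside (not inside)
  the t-based confidence interval, matching summaries that show both a ±
  figure and a CI column.
* **Per-run seeds** are `base_seed + run`, so a report regenerates
  bit-identically from its base seed, and any single run can be reproduced
  in isolation.
* **Frozen AFR.** During training, the AFR is recomputed on the training
  subset for every candidate weight vector and the same subset is scored
  (the objective is fully in-sample). The trained model then freezes the
  training AFR; held-out patterns are classified against it. Recomputing
  prototypes on test data would leak labels.

```{r experiment}
ex <- run_experiment(pd, repetitions = 3, max_cycles = 100, seed = 1)
ex
autoplot(ex)
```

## Problem sizes and runtime

Training cost is dominated by the Euler kernel: one fitness call simulates
every training pattern for `t_window/dt` steps, and a full run makes about
`2 * n_sources * max_cycles` fitness calls. The integration loop is
compiled (Rcpp); at the default `T = 1000` ms a 120-pattern fitness call
costs roughly a millisecond. The examples above and the test suite use
reduced cycle counts (`max_cycles` 100–200) and, in unit tests, shorter
windows (`T = 200` ms), which this package treats as its standard small
problem sizes for demonstration; planted-data recovery is already at
ceiling there. The full-protocol defaults (`max_cycles = 1000`, 30
repetitions) remain the method's reference settings for real datasets.

## Known limitations

* One neuron, one projection: classes must be separable along a single
  current axis after the nonlinearity; multi-neuron extensions are out of
  scope.
* The objective is a step function of the weights (accuracies change in
  jumps), so gradient information does not exist and plateau handling
  depends on the tie-accepting greedy rule and scouts.
* Only the regular-spiking regime is provided; other firing regimes
  (bursting, fast-spiking, ...) would need their own parameter sets and a
  re-examination of the monotone rate-current assumption.
* No feature scaling is applied by default (faithful to the reference
  protocol); heterogeneous feature scales feed directly into the current
  and may require wider weight bounds or preprocessing by the user.
* Time-varying input currents are not modelled: a pattern is a constant
  (step DC) current for the whole window.
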