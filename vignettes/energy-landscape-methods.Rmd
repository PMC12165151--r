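---
title: "Energy-landscape analysis of binarized network dynamics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis of binarized network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elscape)
```

## The model

elscape analyzes multichannel recordings — network-averaged resting-state
fMRI signals, or cluster-reduced transformer hidden-state trajectories —
after binarization to activity patterns $V_t = (\sigma_1(t), \dots,
\sigma_N(t))$ with $\sigma_i \in \{-1, +1\}$ and $N = 9$. The probability of
a pattern is modeled by the pairwise maximum-entropy model (equivalently, an
Ising model): with basal activities $h_i$ and symmetric couplings $J_{ij}$,

$$E(V) = -\sum_i h_i \sigma_i - \tfrac12 \sum_{i,j} J_{ij}\sigma_i\sigma_j,
\qquad P(V) = \frac{e^{-E(V)}}{\sum_{\ell} e^{-E(V_\ell)}}.$$

This is the distribution of maximum entropy among all distributions with
the observed first and second moments, so it is the least-committal model
consistent with mean activities and pairwise co-activations. At $N = 9$ all
$2^9 = 512$ patterns can be enumerated, which the package exploits
throughout: fitting, landscape construction and fit-accuracy evaluation are
all exact, with no Monte-Carlo noise inside the estimation loop.

From a fitted model the *energy landscape* is read off the 9-dimensional
hypercube (patterns adjacent iff they differ at one node): local minima are
patterns strictly below all $N$ neighbors, every pattern is assigned to an
attractor by energy descent, and the hierarchical barrier structure among
minima is summarized by a disconnectivity tree. State dynamics are then
simulated by a Metropolis–Hastings random walk (uniform neighbor proposal,
acceptance $\min(1, e^{E_i - E_j})$), whose stationary law is exactly
$P(V)$. The walk's attractor-label sequence is condensed into per-attractor
dwelling times and pairwise transition frequencies, and each vector is
summarized by a Gini coefficient

$$G = \frac{\sum_{i}\sum_{j} |x_i - x_j|}{2 n^2 \bar x} \in [0, (n-1)/n],$$

the package's polarization index: $G \approx 0$ when the walk treats all
attractors evenly, large $G$ when a few deep attractors dominate.

## Pipeline stages and their parameters

**Binarization.** The brain-like route thresholds each of the nine channels
at the across-node average signal of the same time point (`+1` iff strictly
above). The quoted "whole-recording average as threshold" reading — each
node against its own temporal mean — is one flag away
(`threshold_mode = "per_node_temporal_mean"`); both are deterministic, and
ties give $-1$. The hidden-state route first restricts to an iteration
window (`select_iteration_window()`, half-open, 0-based; defaults keep
iterations $10^4$ to $6\times 10^4$, dropping the prompt-dominated prefix
and the near-fixed-point tail), z-normalizes each node over time, partitions
nodes into nine clusters by k-means on their normalized time courses, and
thresholds each cluster-mean course at its own temporal average. Layers are
processed independently and the first layer is excluded (its states encode
the input tokens, not computation); indices are averaged across the
remaining layers.

**k-means seeding.** Each of the (default 10) restarts is seeded with
k-means++ rather than uniformly random centers. Duplicated channels form
extremely tight clumps in time-course space, and uniformly random centers
miss a clump in most restarts, producing merged/split clusters even on
noiseless data; distance-proportional seeding makes the best-of-restarts
rule reliable. The partition with the lowest within-cluster sum of squares
wins; everything is deterministic given `seed`.

**Fitting.** Plain gradient ascent on the log-likelihood: the update for
$h_i$ is the moment gap $\langle\sigma_i\rangle -
\langle\sigma_i\rangle_m$, for $J_{ij}$ the pairwise-moment gap, both with
learning rate 0.2, model moments recomputed by exact enumeration at every
step, $h = J = 0$ initialization (the independent model). Iteration stops
when the largest absolute moment gap drops below `tol = 1e-6`. The
tolerance is set one order below the commonly quoted $10^{-5}$ because the
moment-to-parameter map can amplify a residual gap by an order of magnitude
when correlations are strong; at $10^{-6}$ the parameter error on exact
moments stays below $10^{-4}$ across random $N = 9$ models with
$|h|, |J| \le 0.5$. Empirical moments are shrunk by $T/(T+1)$ toward zero
before fitting so that boundary moments ($\pm 1$, which require infinite
parameters) remain fittable; the shrinkage is negligible ($<10^{-4}$) at
the sample sizes used and a message is emitted when it is load-bearing.
Non-convergence within `max_iter` is an error carrying the final gap, not a
silent result.

**Fit accuracy.** $r_D = (D_1 - D_2)/D_1$, where $D_k$ is the KL divergence
(nats) of the empirical pattern distribution from the order-$k$ model,
summed over observed patterns ($0\log 0 = 0$). Because the pairwise model
nests the independent one and both are fitted to convergence on the same
moments, $D_2 \le D_1$ and $r_D \in [0, 1]$ up to numerical tolerance. The
degenerate case $D_1 = 0$ is flagged rather than divided through.

**Landscape.** Descent uses the steepest (lowest-energy) strictly smaller
neighbor; ties between equally low neighbors are broken toward the lowest
state index, and exact energy ties between distinct states are broken by
state index everywhere, so results are reproducible under floating-point
ties. Equal-energy neighbors are never descended into. States whose tied
steepest-descent candidates lead to different minima are flagged as saddles
but still assigned deterministically (and counted in basin sizes by
default) — the classical treatment excludes them from classification, but
an unassigned state would leave walk labels undefined. The disconnectivity
tree is built bottom-up with a union-find over states in increasing energy
order, which yields exactly the threshold-lowering construction: the merge
energy of two minima is the smallest threshold at which they stay connected
through states of energy below it, i.e. the minimax path barrier (verified
against exhaustive path search in the tests). Basin *depth* is the barrier
to the first strictly lower minimum (root height for the global minimum),
the standard disconnectivity-graph depth.

**Dynamics.** Walks default to $10^5$ steps with the first 100 discarded,
one chain per subject, temperature 1 (absorbed in the fitted parameters).
The dwelling-time statistic defaults to the mean consecutive run length per
attractor — "how long the pattern stays" read literally — with total
occupancy available via `dwell_stat = "occupancy"`, since the two readings
are not distinguished by common usage. Transition frequency counts switch
events on unordered attractor pairs, excluding self-transitions; the
transition vector fed to the Gini includes zero-count pairs among visited
attractors, so a walk concentrated on one pair is maximally polarized
rather than trivially uniform.

**Statistics.** Group contrasts use two-sample t-tests (pooled variance by
default, Welch by flag), Bonferroni correction over the number of tests
actually performed in a run, and $\eta^2 = t^2/(t^2 + \mathrm{df})$.
Index–behavior association uses Pearson correlation: dwelling-time Gini
against fluency scores, transition-frequency Gini against comprehension
scores, within each group.

## What the synthetic generator emulates

`make_regime_params()` encodes the two qualitative landscape families the
analysis is meant to distinguish. *uniform_shallow* partitions the nine
nodes into three weak ferromagnetic blocks ($J = 0.3$ within blocks): each
block can align either way, giving $2^3 = 8$ minima of similar, shallow
depth. *polarized* replaces the first block by a strongly coupled four-node
block ($J = 0.8$) over the same weak remainder, so two deep attractors
(block up/down) coexist with shallow ones. Gaussian jitter (sd 0.02) on all
couplings and fields breaks the exact block and spin-flip symmetries so
that energies are distinct and tie-breaking is immaterial; draws are
retried (bounded) if a landscape has fewer than two minima, which at these
settings does not occur in practice. Across seeds the polarized depth ratio
(max/min basin depth) exceeds 2 and the uniform ratio stays below 2 — the
separation the regimes were designed for, measured on the exhaustive
landscape, not assumed.

Latent series are drawn i.i.d. from the exact Boltzmann distribution
(`sample_mem_series()`): for moment-matching and recovery experiments this
removes autocorrelation as a confounder. A Glauber single-site chain with
the same stationary law (`sample_glauber_series()`) is provided where
temporal correlation matters. Continuous observations
(`emit_continuous_observations()`) duplicate each latent node into
`nodes_per_cluster` channels with per-channel uniform gain in $[0.5, 1.5]$,
offset in $[-1, 1]$ and Gaussian noise — the gain/offset spread is there to
force the normalization in the preprocessing to do real work. What the
generator does *not* emulate: hemodynamic response functions, scanner
autocorrelation, lesion masking, or any transformer computation. Passing
tests therefore certify the *pipeline* — that the statistical machinery
recovers known structure — not that real recordings satisfy the model's
assumptions.

## Problem sizes and numerical choices

The bundled experiments use $N = 9$ nodes, $T = 10^4$ time points per
synthetic subject, 20 subjects per regime, $10^5$-step walks, and
$10^6$-step walks at $N = 3$ for stationarity checks — sizes at which every
quantity with an exhaustive counterpart is checked against it exactly, and
the full two-regime experiment reruns in minutes on one core. Probabilities
are computed with a max-shift before exponentiation; state indices encode
patterns bitwise (node 1 = least significant bit, bit set iff $+1$), and
this single indexing convention is shared by the state table, basin map and
trajectories. Stationarity of the sampler is asserted within Markov-chain
standard errors estimated by batch means, since i.i.d. binomial standard
errors understate the uncertainty of autocorrelated Metropolis samples.

## A worked example

```{r example, eval = FALSE}
params <- make_regime_params("polarized", seed = 1)
series <- sample_mem_series(params, 1e4, seed = 2)

idx <- subject_indices(series, pipeline_config(n_steps = 1e5, seed = 3))
idx[, c("gini_dwell", "gini_trans", "r_d", "n_minima")]

tab <- exact_distribution(fit_pairwise(empirical_moments(series)))
tree <- build_disconnectivity(tab, find_local_minima(tab))
basin_depths(tree)
autoplot(tree)
```

## Known limitations

* Exact enumeration caps the node count at 16 in principle and 9–10 in
  practice; there is deliberately no pseudo-likelihood or MCMC fitting
  path for large $N$.
* The Gini of transition counts is only defined for two or more visited
  attractors; single-attractor landscapes return 0 with an `undefined`
  flag, and layer averages skip flagged layers.
* Plain gradient ascent slows markedly when empirical moments approach
  $\pm 1$ (nearly frozen channels); such inputs are better handled by
  larger `max_iter` or by questioning the binarization rather than by this
  optimizer.
* The reported group statistics assume independent subjects; per-layer
  indices of one trial are averaged, not treated as independent.
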