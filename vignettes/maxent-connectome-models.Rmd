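---
title: "Maximum-entropy connectome ensembles: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy connectome ensembles: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromaxent)
```

## The modelling framework

A neural connectome is an undirected simple graph over neurons with known
3D positions; an edge records at least one chemical synapse. The package
models such graphs with *canonical* maximum-entropy ensembles: probability
distributions `P(G)` over graphs that maximize the ensemble entropy
`S = -Σ_G P(G) log P(G)` subject to constraints that hold on average. For
the constraint families used here, `P(G)` factorizes over node pairs into
independent Bernoulli edge variables with probabilities `p_ij`, which makes
ensembles cheap to fit, sample (no Markov-chain Monte Carlo) and score
(exact log-likelihoods).

Six ensembles are implemented, named by their constraints:

* **k** — expected degree of every node equals its observed degree
  (the soft configuration model): `p_ij = y_i y_j / (1 + y_i y_j)`, one
  multiplier per node. We parameterize by the propensity `y_i = e^{-θ_i}`
  (θ the Lagrange multiplier), which turns the classic fixed-point update
  into the multiplicative form `y_i ← k_i* y_i / ⟨k_i⟩(y)`.
* **k+L** — degrees plus the expected total wiring length
  `L = Σ_{i<j} A_ij d_ij` (distances in soma-size units):
  `p_ij = y_i y_j e^{-d_ij/d₀} / (1 + y_i y_j e^{-d_ij/d₀})`. The decay
  scale `d₀` is not free: it is calibrated so the ensemble-expected wiring
  length matches the observed one.
* **d** — a nonparametric binned distance dependence: pair distances are
  split into `n_bins = 50` linear bins spanning `[0, max d]` and
  `p_b = (edges in bin b) / (pairs in bin b)`. The identity
  `Σ_b N_pairs,b p_b = E` makes the expected edge count exact by
  construction.
* **c** — a uniform random subnetwork of the contactome: `p = E_syn/E_cont`
  on contact pairs, 0 elsewhere. This is the "physical constraint only"
  baseline.
* **d+c** — distance dependence *conditional on contact*: per-bin
  probability (synaptic edges in bin)/(contact pairs in bin), applied to
  contact pairs only. The conditional definition preserves both the binned
  distance profile and the expected edge count while honouring the hard
  constraint; it was chosen over re-using the unconditional bin
  probabilities, which would violate the edge-count constraint once
  non-contact pairs are zeroed.
* **k+c** — the soft configuration model restricted to the contactome:
  `p_ij = 0` off the contact mask, multipliers solved over contact pairs.

All six preserve the expected total number of edges, which makes their
comparisons (graphlets, efficiencies, likelihoods) interpretable as "what
does each constraint buy at fixed density".

## Numerical choices

**Degree solves.** Multipliers are initialized at
`y_i = k_i*/sqrt(Σ_j k_j*)` (exact for sparse uncorrelated graphs) and
iterated with the multiplicative update; if the residual oscillates, a 0.5
arithmetic damping with the previous iterate is applied. Convergence is
`max_i |⟨k_i⟩ - k_i*| / max(k_i*, 1) ≤ tol` with `tol = 1e-8` and
`max_iter = 10000`; non-convergence is an error carrying the residual.
Nodes with `k_i* = 0` get `p_ij = 0` exactly and are excluded from the
solve.

**Boundary and feasibility.** A node whose target degree equals its number
of allowed partners (partners with positive targets; contact neighbours
under a mask) can only satisfy its constraint in the limit `p → 1` on all
its pairs. Such nodes are pinned at a large multiplier ceiling (`1e12`),
reported via `$boundary`, and excluded from the convergence residual; a
target *exceeding* the allowed-partner count is an infeasibility error.
Components near (but not at) the boundary make the multiplicative update
crawl — its contraction rate degenerates as probabilities approach 0 or 1 —
so every 100 iterations the solver checks progress and, if poor, applies a
damped Newton step on `log y` using the Fisher information
`∂⟨k_i⟩/∂log y_j = p_ij(1-p_ij)` as the (symmetric, PSD) Jacobian. The
Newton step is accepted only when it reduces the residual, so the scheme
can never do worse than the plain iteration.

**Wiring-length calibration.** At fixed converged multipliers, the expected
length `⟨L⟩(d₀)` is monotone increasing in `d₀` (verified numerically in
the test suite), so the calibration is a bracketing search plus geometric
bisection, warm-starting each inner degree solve from the previous probe.
Probes at very small `d₀` can legitimately fail — the kernel
`e^{-d/d₀}` underflows and the constraints become unrepresentable — and
are treated as "below the searchable range" rather than errors. The stop
rule is `|⟨L⟩ - L*|/L* ≤ 1e-4`, i.e. 0.01% of the total edge length.

**Distance bins.** Bins are half-open `[lo, hi)` with the last bin closed.
When a fitted distance model scores a pair beyond its last bin edge
(possible when scoring new pairs), it uses the last bin's probability and
warns. Empty bins score 0.

**Sampling.** Realization `r` of `simulate()` seeds the RNG with
`seed + r`, so a prefix of a longer run is bit-identical and realizations
are independent of how many are requested.

**Contact thresholds.** Contact assignment is strict (`d_min < d_thr`).
The selection rule finds the minimal threshold under which at least the
requested fraction (default 99%) of synaptic pairs lie strictly below, then
rounds *up* to the next integer nanometre; every synaptic pair is required
to have a candidate distance. Synaptic edges still missed at the selected
threshold are force-added during assembly, so the connectome-⊆-contactome
invariant holds exactly on the output.

**Spatial statistics.** The exponential scale `d₀` is estimated by
count-weighted least squares of `log p_b` on bin centers, using only bins
with at least 10 edges (the plotting-rule floor) and, by default, centers
below the finite-size cutoff `d_fs` — the mode of the all-pairs distance
histogram, beyond which the bounded experimental volume suppresses pair
counts and distorts `p(d)`. Histogram-mode ties take the smaller distance.
Soma radii are estimated as the peak of a triangular-kernel density of
center-to-contact distances, evaluated on a grid of resolution
`bandwidth/10`; tied maxima take the smaller location. Directional decay
uses the principal axes of the position cloud ordered by variance.

**Evaluation conventions.** Graphlet counts are *induced* occurrences
(the graphlet-literature convention), computed by per-edge common-neighbour
counting with algebraic corrections and validated against exhaustive
enumeration. Global efficiency averages `1/δ_ij` over all ordered pairs
with `1/δ = 0` for disconnected pairs; diameter and average shortest path
are restricted to the largest connected component, which keeps them finite
on graphs with isolated nodes. Clustering assigns 0 to nodes of degree
below 2. The wiring-length shuffle test permutes the position-to-node
assignment, keeps topology intact, and reports a one-sided
(observed-shorter) permutation p-value with add-one smoothing. Quartiles
(for degree IQRs) use linear interpolation (type 7). Precision–recall AUC
is step-interpolated average precision, the stable summary under the
extreme sparsity of synaptic edges among candidate pairs.

## What the synthetic scenarios emulate

`synthetic_scenario()` plants the data structure the models target:
uniform (optionally anisotropic) positions in a box, a contactome with
exponential distance dependence `min(1, a·e^{-d/d0_c})`, a connectome kept
from contact edges with probability `y_i y_j/(1+y_i y_j)` for log-normal
planted propensities (calibrated by a root solve so the expected kept
fraction is met), heavy-tailed negative-binomial synapse counts whose mean
grows with edge probability, and point clouds built as a dense soma shell
plus sparse neurite rays. Defaults are chosen to resemble a desk-scale
patch of mammalian cortex in soma-size units: a 100-unit box, contact decay
scale 12, synaptic-to-contact edge fraction 0.08, heterogeneity σ = 1
(log-normal), giving broad but not scale-free degrees and a contactome an
order of magnitude denser than the connectome.

The generators deliberately do **not** emulate realistic neuron
morphologies (arbours, boutons, spines), layered or curved tissue geometry,
cropping artefacts at volume boundaries, reconstruction errors, or any
wiring specificity beyond degree propensity (cell types, gene expression).
Passing tests on these scenarios therefore demonstrates correctness of the
estimators and solvers under their stated assumptions — not that the models
capture every property of real connectomes.

## Problem sizes

The test suite and acceptance script run at sizes chosen to exercise every
code path while staying comfortably interactive: solver-vs-oracle
comparisons on all-pairs-checkable graphs (n ≤ 8), graphlet enumeration
cross-checks on 200 random graphs (n ≤ 10), sampling checks at 1000
realizations on 25-node fixtures, parameter recovery and wiring-length
calibration at n = 500, decay-scale recovery at n = 1500, and cloud-based
contactome construction at n = 50 with 80-point clouds.

## Known limitations

* Ensembles are undirected and unweighted; directed, signed or weighted
  constraints (and multi-neuron interactions) are out of scope.
* The `k+L` solver materializes a dense distance matrix, which caps it at a
  few thousand nodes; the streaming pair interface used elsewhere would
  lift this but is not wired into the inner loop.
* Boundary nodes (degree equal to allowed partners) satisfy their
  constraints only in the `p → 1` limit; fits report them rather than
  failing, and their residual contribution is bounded by the multiplier
  ceiling.
* Exact minimum inter-cloud distances use blocked brute force with
  bounding-box pruning — exact, but quadratic per pair in cloud size;
  intended for the point-cloud scales shipped here, not full-resolution
  meshes.
* The exponential decay fit is a weighted regression on log-binned
  probabilities; it inherits the usual sensitivity to bin width at small
  counts, which the edge-count floor mitigates but does not remove.
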