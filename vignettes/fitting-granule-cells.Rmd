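---
title: "Multimodal fitting of AdEx granule-cell models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fitting of AdEx granule-cell models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cerebellar granule cells (GrCs) show a small set of characteristic firing
behaviors: regular repetitive discharge whose rate grows with injected step
current, a first-spike latency that shrinks with current, and theta-band
spiking resonance — enhanced bursting when driven with low-frequency
sinusoidal currents. The adaptive exponential integrate-and-fire (AdEx)
model can reproduce all of these with ten parameters, but the map from
parameters to behavior is nonlinear and many different parameter sets
produce nearly the same behavior. `adexfit` therefore treats fitting as a
*multimodal* optimization problem: rather than returning one "best" model,
it returns a sparse population of distinct, well-separated candidate
parameter sets for an expert to inspect.

## The neuron model

The membrane potential $V$ (mV) and adaptation current $w$ (pA) evolve as

$$C_m \frac{dV}{dt} = -g_L (V - E_L) + g_L \Delta_T
  \exp\!\left(\frac{V - V_T}{\Delta_T}\right) - w + I(t), \qquad
\tau_w \frac{dw}{dt} = a (V - E_L) - w,$$

with the reset rule: when $V > V_{peak}$, a spike is recorded, $V \leftarrow
V_r$ and $w \leftarrow w + b$. Units are pA/pF/nS/mV/ms, which closes
dimensionally (nS·mV = pA, pF·mV/ms = pA); the user-facing interface uses
seconds for time and converts at the boundary. $V$ starts at $E_L$ and $w$
at 0 pA, and there is no refractory period — the reset rule is the only
discontinuity.

Integration is fixed-step forward Euler at `dt = 0.1` ms by default. This
is deliberate: the method's contract is reproducibility (identical inputs
give bit-identical spike trains), and a fixed-step explicit scheme at the
resolution typical of spiking-network simulators achieves that with a
dt-convergence guarantee verified in the test suite (halving `dt` moves
spike times by less than `2*dt`). The exponential term diverges in finite
time during the upward spike stroke, so its argument $(V - V_T)/\Delta_T$
is capped at `exp_clip = 30` before exponentiation; any $V > V_{peak}$
triggers the reset regardless of overshoot, so the cap changes no spike
time at `dt` resolution. If the state still becomes non-finite (possible
only with non-default caps), the run is flagged `diverged` instead of
raising, and scoring assigns a large finite penalty (`1e9`) so the
optimizer keeps a total ordering.

The search box (`default_parameter_bounds()`) constrains each parameter to
a plausible GrC range, e.g. $C_m \in [0.1, 5]$ pF, $g_L \in [0.001, 10]$
nS, $\Delta_T \in [1, 1000]$ mV.

## Features and objective

Three features are extracted per candidate:

* **Mean frequency** (Hz) per step stimulus: spike count divided by the
  stimulation time. Default steps: 10, 16, 22 pA for 1 s.
* **First-spike latency** (s) per step stimulus: time from onset to the
  first spike. A candidate that never spikes gets the full stimulus
  duration as a sentinel — this keeps the score finite and penalizes
  silence proportionally; the choice is documented and configurable.
* **Burst frequency** (Hz) per sinusoidal condition: within each
  stimulation cycle, the inverse of the mean inter-spike interval of the
  in-window spikes; cycles with one or no spike count as 0 Hz. The
  per-condition value is the mean over 10 consecutive cycles. Default
  sinusoids: 6 and 8 pA amplitude on a 12 pA offset for 22.5 s. The
  oscillation frequency grid is configurable and defaults to
  {1, 2, 4, 6, 8, 10, 12} Hz, spanning the theta band where GrC resonance
  is reported (~5–12 Hz in vitro).

The objective is the weighted sum of absolute errors against reference
targets:

$$S = \sum_i |MF^{sim}_i - MF^{ref}_i| \cdot w_{MF}
    + \sum_i |LAT^{sim}_i - LAT^{ref}_i| \cdot w_{LAT}
    + \sum_j |BF^{sim}_j - BF^{ref}_j| \cdot w_{BF} \cdot
      (\mathrm{sd}(BF_j) + 1),$$

with default weights $w_{MF} = w_{BF} = 1$ (errors in Hz) and $w_{LAT} =
1000$ (latency in seconds), so a 1 Hz error and a 1 ms lag weigh equally.
The burst term's $(\mathrm{sd} + 1)$ factor penalizes candidates whose
bursts drift across cycles even when the mean matches. Two readings of
that factor are possible; we take sd as the *population* standard
deviation of the per-cycle burst frequencies within condition $j$, since a
stability penalty only makes sense across cycles. As written, the factor
multiplies the absolute error, so a perfectly matched mean scores 0
regardless of spread — the formula is implemented as stated, not
"improved".

Sinusoidal cycles are windowed by full stimulus period starting at onset
(the first 10 complete cycles). Bursts fall into the positive phase of the
drive naturally; no phase-shifted windowing is applied, but an analysis
onset and a protocol phase offset are exposed for users who want one. ISIs
straddling a window edge are excluded so cycles stay independent.

## Reference targets

Real use feeds in vitro targets via a JSON/CSV schema
(`read_reference()` / `write_reference()`; latencies must be stored in
seconds — a file labeled in ms is rejected). For development and testing,
`generate_reference()` synthesizes targets by running a known ground-truth
parameter set through the protocol suite, optionally followed by
feature-level Gaussian noise (`perturb_reference()`, frequencies clipped
at 0). Noise is applied at the feature level rather than the spike-train
level because the objective consumes features only. The package ships two
plausible GrC-like generator parameter sets (`example_parameters(1:2)`).

A synthetic reference guarantees by construction that its generator scores
exactly 0, which anchors the recovery tests. What it does *not* emulate:
trial-to-trial variability of real recordings, cell-to-cell heterogeneity
(real targets average over cells), electrode artifacts, and any feature of
real GrCs outside the three extracted ones. A passing recovery test shows
the pipeline can find parameter sets reproducing AdEx-generated behavior;
it does not certify biological fidelity of any candidate.

## The optimizer

UEGO manages a population of **species**: a center (candidate solution),
its cached objective value, and an attraction radius. All geometry lives
in the normalized unit box $[0,1]^{10}$ — each parameter affinely rescaled
by its bounds — because raw units would let the slope factor (range 999
mV) dominate every Euclidean distance. The default minimum radius
$r_{min} = 0.7$ and the search-space diameter $\sqrt{10} \approx 3.16$ are
interpreted in that space. Defaults: at most $M = 100$ species, $N = 10^7$
evaluations, $l = 50$ levels.

Per level, radii cool geometrically from the diameter down to $r_{min}$.
Each level creates species (budget $3M$ evaluations), fuses overlapping
ones, trims the population, locally optimizes every species, and fuses
again:

* **Creation**: the budget is split evenly across species; within each
  species' ball, points are sampled uniformly (direction uniform on the
  sphere, length $\propto U^{1/d} R$) and evaluated, and the midpoints of
  all pairs are evaluated. A midpoint *strictly* worse than both endpoints
  signals two separate basins: both endpoints become new species at the
  level radius. Ties create nothing (avoids species explosion on
  plateaus). Any evaluated point strictly better than the parent center
  replaces it. Because midpoint evaluations also consume budget, the
  per-species allotment covers samples *and* midpoints (the largest $m$
  with $m + \binom{m}{2}$ within the allotment) — this keeps the hard
  invariant that total evaluations never exceed $N$.
* **Fusion**: while two centers are closer than the level radius, they
  merge keeping the better center and the *larger* radius (broad regions
  survive). Scan order is creation order; equal fitness keeps the
  earlier-created center. A full-diameter species therefore always exists.
* **Shortening**: above $M$, the shortest-radius species are removed
  first, ties broken by worse fitness.
* **Local search (SASS / Solis–Wets)**: from the center, propose
  `center + radius * sigma * g` with Gaussian `g`, displacement capped at
  the species radius and clipped to the box; accept strict improvements.
  `sigma` starts at its upper bound 1, doubles after 5 consecutive
  successes, halves after 3 consecutive failures, clamped to
  $[10^{-5}, 1]$; the search stops after 32 consecutive failed or
  discarded moves no matter the remaining budget. A proposal whose clipped
  displacement is zero counts as discarded without spending an
  evaluation. The classical Solis–Wets bias vector is not used; moves are
  unbiased Gaussian perturbations.

The per-level local-optimization budget is a linear ramp,
$b_i = \lfloor B \cdot i / \sum_{k=1}^{l} k \rfloor$ with
$B = N - 3M(l-1) - 1$, split evenly among the current species. The exact
schedule is an internal choice of this implementation; the contract it
realizes is that later levels — which refine previously found regions —
receive more evaluations, the first level's lone species still gets a
local search, and the grand total stays at or below $N$. Runs are fully
reproducible from the configured seed, and the per-level ledger records
radius, species count, evaluations and the best score.

## Population analysis

`rank_candidates()` re-extracts features per surviving species and
decomposes each total into the three components (burst split per
stimulation amplitude), asserting consistency with the optimizer's cached
fitness. `pairwise_distances()` compares candidates ("landscapes") by
plain Euclidean distance, in physical units by default — with a
normalized-space option since either convention is defensible.
`classical_mds()` is Torgerson scaling: double-center the squared
distances, eigendecompose, scale the top eigenvectors by root
eigenvalues (negative eigenvalues truncated at zero); it is backed by
`stats::cmdscale` and reproduces any 2-d-realizable configuration to
numerical precision. `parameter_summary()` reports median, quartiles and
5/95 percentiles per parameter using linearly interpolated quantiles
(R type 7) — stated here because box-plot conventions differ.

## Problem sizes used by the tests

The shipped test and acceptance runs are scaled down so the whole suite
runs in minutes on one core, sizes chosen as the smallest that still
exercise every mechanism: toy optimizer runs use $d \le 2$, $M = 10$,
$N \le 5000$, 5–6 levels; the parameter-recovery fit uses the reduced
protocol suite (0.5 s steps; 2.5 s sinusoids at 4/6/8 Hz for both
amplitudes — 2.5 s holds exactly ten 4 Hz cycles), $M = 20$, $l = 10$,
$N = 20{,}000$, `dt` = 0.1 ms. Under these conditions the best recovered
candidate scores far below 5% of the mean score of 100 uniform-random
candidates and reproduces the generator's frequencies within 10% and
latencies within 10 ms. Full-scale runs (22.5 s sinusoids, $N = 10^7$)
use exactly the same code paths.

The closed-form checks deserve a note. In the near-LIF limit
($a = b = 0$, minimal $\Delta_T$) spike counts are compared against the
leaky-integrator period
$T = \tau_m \ln\frac{I - g_L(V_r - E_L)}{I - g_L(V_T - E_L)}$. The
exponential escape from $V_T$ to $V_{peak}$ takes extra time not present
in the closed form (about $\tau_m \ln(m+1)/m$ for a voltage margin of $m$
mV with $\Delta_T = 1$), so the comparison grid uses low firing rates
(2–6 Hz), where that bias stays below one spike per second. The latency
oracle instead uses $\Delta_T = 10^{-3}$ mV, where the escape is
effectively instantaneous.

## Known limitations

* Forward Euler is first-order: spike times carry an O(dt) bias. This is
  shared by common spiking simulators at comparable settings but means
  candidates are fitted to the discretized model, not the ODE limit.
* The latency sentinel (stimulus duration) makes the objective
  discontinuous at the spiking/non-spiking boundary; the optimizer is
  derivative-free, so this is harmless in practice but worth knowing.
* Burst analysis uses the *first* ten cycles; neurons with slow adaptation
  may not have reached steady state. The analysis onset is configurable.
* With very tight evaluation budgets the SASS early-termination rule (32
  consecutive failures) can leave much of the nominal budget unspent —
  this is by design (saved evaluations, as intended), but it means `N` is
  an upper bound, not a prediction of work done.
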