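---
title: "Modeling anesthetic suppression and its cholinergic reversal in a cortical E-I network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling anesthetic suppression and its cholinergic reversal in a cortical E-I network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`anesnet` simulates a cortical circuit of 800 excitatory and 200 inhibitory
single-compartment Hodgkin–Huxley neurons (the 4:1 cortical ratio), randomly
connected with 10% probability, and asks two questions: how do the synaptic
effects of an inhalational anesthetic (desflurane-like: weakened NMDA
transmission, potentiated GABA~A~ transmission) reshape population spiking,
and can increasing cholinergic tone — modeled purely as suppression of the
muscarinic-sensitive slow potassium M-current — reverse those changes while
the anesthetic-induced synaptic changes stay in place?

Each neuron integrates fast sodium, delayed-rectifier potassium, slow
M-type potassium and leak currents:

$$\frac{dV}{dt} = -g_{Na} m_\infty^3 h (V - E_{Na}) - g_{Kd} n^4 (V - E_K)
 - g_{Ks} z (V - E_K) - g_L (V - E_L) + I_{noise} - I_{syn} + I_{DC}$$

with first-order gate kinetics $dX/dt = (X_\infty(V) - X)/\tau_X(V)$ for
$X \in \{h, n, z\}$; sodium activation is instantaneous
($m = m_\infty(V)$). The M-current gate $z$ has a fixed 75-ms time constant,
which makes it a slow, non-inactivating brake on excitability: its maximal
conductance $g_{Ks}$ encodes (inverse) acetylcholine level, from 0 (high
ACh) to 1.5 mS/cm² (low ACh). Raising $g_{Ks}$ also converts the cell from
Type 1 (continuous firing-frequency onset at rheobase) to Type 2
(discontinuous onset) excitability, which `fiCurve()` and `rheobase()`
expose directly.

Synapses are conductance-based double exponentials,

$$I_X = P_X\, B_X(V)\, v\, g \left(e^{-t/\tau_{Xs}} - e^{-t/\tau_{Xf}}\right)(V - E_X),$$

with a shared 0.2-ms rise, decay constants of 3 ms (AMPA), 200 ms (NMDA)
and 5.5 ms (GABA~A~), excitatory reversal at 0 mV and inhibitory at
−75 mV, and the sigmoidal magnesium-block factor $B$ for NMDA (midpoint
−10 mV). Each excitatory edge delivers AMPA and NMDA sharing one
conductance; each presynaptic spike draws an event scale $v \sim U[0.5,1]$
per edge. Edge conductances follow a lognormal distribution
($\mu = -20.0$, $\theta = 9.4$ in log units), so most edges are vanishingly
weak and a small minority are strong enough that a single presynaptic spike
fires a resting target; `fractionSuprathreshold()` locates that threshold by
bisection and reports the tail probability above it.

The anesthetic conditions are the packaged schedule
(`levelParameters()`): receptor scaling factors $P_{NMDA}$, $P_{GABA}$,
$P_{AMPA}$ and $g_{Ks}$ per level. The A-series holds $g_{Ks}$ fixed
across anesthetic levels; the B-series lets it co-vary; the AR/BR reversal
series keep the deepest level's synaptic factors and step $g_{Ks}$ down to
0.40 mS/cm², emulating exogenous cholinergic activation under maintained
anesthesia.

## Parameters that matter, and why these defaults

Printed model constants (reversal potentials, the synaptic time constants,
$I_{DC} = -0.77\ \mu A/cm^2$, the gate kinetics, the condition schedule,
the weight distribution) are used as published. Four quantities are not
printed and had to be fixed by the model's own stated behaviour; they are
all configurable.

* **`g_Na` = 24, `g_Kd` = 3 mS/cm²** come from the pyramidal-cell model
  family this neuron descends from.
* **`g_L` = 0.05 mS/cm²**. The lineage value (0.02) combined with the
  printed bias current puts the resting potential near −98 mV — *below*
  the GABA~A~ reversal, which would make "inhibition" depolarizing and
  (we verified) makes deep-anesthesia parameters *increase* firing. At
  0.05 mS/cm² the cell rests at about −75 mV: GABA~A~ acts as shunting
  inhibition, both excitability types survive across the $g_{Ks}$ range,
  and anesthetic suppression behaves as reported.
* **`noise_amplitude` = 16 µA/cm²** (0.1 Hz, 2 ms per pulse, as
  published). The model requires that a noise pulse alone fires a resting
  cell — these rare seed spikes are what keeps the network's recurrent
  activity alive. A 4 µA/cm² × 2 ms pulse can depolarize a 1 µF/cm²
  membrane by at most 8 mV, which no parameterization of this neuron can
  turn into a spike; 16 µA/cm² is the smallest robust amplitude that fires
  exactly one spike per pulse at every cholinergic level.
* **`wCap` = 0.22 mS/cm²**, the delivered-conductance cap. The untruncated
  lognormal tail ($\theta = 9.4$ log units) produces conductances up to
  $e^{20}$ mS/cm² — unphysical, and stiff beyond what any explicit
  integrator can follow. Because a suprathreshold synapse triggers at most
  one postsynaptic spike per presynaptic spike regardless of its
  magnitude, capping near the single-spike firing threshold
  (≈ 0.14 mS/cm² at these defaults; the cap sits ~1.6× above it) preserves
  the functional effect of
  every edge while bounding the aggregate drive; without it the mean
  synaptic current (~16 µA/cm²) pins the population in depolarization
  block, where anesthesia effects invert.

## Numerical scheme

The network is integrated with the classical fourth-order Runge–Kutta
method (default `dt` = 0.05 ms). Synaptic state is event-driven: two
exponential accumulators per receptor class per neuron, decayed
analytically within each step, which is exactly equivalent to summing the
double-exponential kernels over all past spikes (an equivalence the test
suite checks against direct kernel summation to one part in 10⁹). When a
neuron's total synaptic conductance would make the explicit step stiff
(conductance × dt beyond the RK4 stability margin), its step is subdivided
automatically, with a retry-and-refine fallback; gating variables leaving
[0, 1] by more than round-off, or a non-finite voltage, abort with an
error rather than continuing silently. Spikes are upward 0 mV crossings
with a 2-ms detection lockout. Initial conditions are drawn uniformly
(V ∈ [−72, −32] mV, h, n ∈ [0.2, 0.6], z ∈ [0.2, 0.3]) from the
simulation seed, and the first second is discarded as transient. All
randomness (topology, initial state, noise, event scales, surrogates,
subsampling) is reproducible from integer seeds, with separate streams for
noise and synaptic event scales so that an uncoupled network reproduces
isolated cells exactly.

Measured rates and trend statistics agree across `dt` ∈ {0.05, 0.1, 0.2}
ms; the packaged reduced-scale trend reproduction (below) runs at
`dt` = 0.15 ms.

## Measures

All analyses run on `SpikeRaster` objects and mirror the measurement
protocol used for the reference recordings:

* **Mean rate** and per-neuron rate distributions with Fisher–Pearson
  skewness (`rateStats()`): wake activity is right-skewed; anesthesia
  compresses the distribution.
* **Mean phase coherence** (`meanPhaseCoherence()`): for an ordered pair,
  each comparison spike contributes a unit phasor at its phase within the
  enclosing reference interspike interval; the modulus of the mean phasor
  is 1 for perfect locking and 0 for random phases. The network value
  averages all ordered pairs with at least one contributing spike.
* **Integration** $I(X) = \sum_i H(X_i) - H(X)$ and **complexity**
  $C(X) = H(X) - \sum_i H(X_i \mid X - X_i)$ on 1-ms binned binary
  pattern matrices, with plug-in entropies in bits (base 2; the base only
  rescales fitted costs uniformly). Complexity is computed through the
  identity $H(X_i \mid X - X_i) = H(X) - H(X - X_i)$; a direct
  conditional-entropy route is kept as a cross-check. No bias correction
  is applied, matching the measurement protocol of the reference data;
  the estimator is pluggable.
* **`measureSuite()`** applies the sampling protocol: one random
  60-neuron subsample held fixed per recording, measures computed on 3
  non-overlapping random 6-s windows and averaged. (A figure caption in
  the source describes 5 windows where the methods specify 3; we default
  to 3 and expose the count.)

## Functional connectivity

`inferFunctionalNetwork()` classifies every ordered pair of eligible
neurons (≥ 1 Hz, at most 60, seeded subsample) from its cross-correlogram:
comparison-spike lags within ±20 ms of each reference spike, binned at
1.3 ms (30 full bins; the partial rightmost bin of the 40-ms window is
dropped). The null is 100 surrogates with the comparison train jittered by
±5 ms. An edge is excitatory when its correlogram peak within lags
0–5.2 ms (the first four bins) exceeds the surrogate grand mean by more
than twice the 97th-percentile excursion of the surrogate *global* peak
above that mean; the mirrored criterion classifies inhibitory troughs. We
anchor the band at the surrogate grand mean of the correlogram — the
alternative anchor (the mean of the surrogate extrema themselves)
degenerates for sparse trains, where every surrogate global trough is
zero, and floods the inhibitory class with false positives. Connection
strength is the standardized extremum, (extremum − surrogate mean)/
surrogate SD, using the per-statistic surrogate moments; both per-bin and
per-statistic moments are exposed on the band object. With these
conventions the false-positive rate on independent Poisson pairs is
conservative (0/200 per sign in the packaged calibration test), and a 30%
transmission at 2 ms lag on 60-s trains is detected essentially always.

Functional networks are compared by the cosine similarity of their
pairwise excitatory strength matrices, standardized against similarities
from jittered data (`similarityZscore()`, `crossLevelSimilarity()`).

## Parameter fitting

`fitLevel()` implements the differential-evolution fit of
($P_{NMDA}, P_{GABA}, P_{AMPA}, g_{Ks}$) to target measures under the cost

$$L = \sum_x \left(\frac{x_{exp} - x_{sim}}{x_{exp}}\right)^2, \qquad
x \in \{\text{rate}, \text{MPC}, I(X), C(X)\}.$$

A 30-agent population advances by replacing the 10 worst agents each
generation with offspring $e_i = b_i + DW\,(c_i - d_i)$ (crossover
probability CR = 0.8, DW drawn once per offspring from U[0, 2]; a
coordinate keeps its base value otherwise), stopping after 100 stagnant
generations. The wake level seeds from a 256-point grid scan; deeper
levels seed from their neighbours, and the 6% level anchors at the wake
fit shifted by the reported mean synaptic effects of deep anesthesia (20%
NMDA decrease, 40% GABA increase) ± 5%. Every seeding ends with the
keep-20 / perturb-by-10% / construct-10 refresh — this step is essential,
not cosmetic: without it grid-seeded coordinates are duplicated, the
difference vectors $c - d$ vanish coordinate-wise, and the optimizer can
never leave the grid. In the A-series only $P_{NMDA}$ and $P_{GABA}$ vary
beyond the wake fit; the B-series also frees $g_{Ks}$; $P_{AMPA}$ is only
ever fitted at the wake level. Agents are evaluated on one seeded
simulation each (seed fixed within a generation so ranking is consistent),
and `simulatorCost()` builds such evaluators against a fixed topology.

## What the synthetic generators emulate

`poissonRaster()`, `synchronizedRaster()` and `coupledRaster()` produce
rasters with the statistical structure of cortical multi-unit recordings —
tens of units at 1–10 Hz, controllable synchrony (common-oscillator
phase locking with Gaussian timing jitter), and embedded monosynaptic
couplings (fixed lag, given transmission probability) — so that every
measurement and inference stage is testable without the simulator. They do
not emulate slow rate drift, bursting cell types, electrode artifacts or
burst suppression; passing tests on them validates the *measures*, not the
realism of any particular network state.

## Reduced-scale reproduction and its limits

The published experiment runs 150-s simulations on 10 network
realisations per condition. The packaged acceptance checks rerun the full
1000-neuron network at desk scale — 20 s per level, 3 network
realisations, `dt` = 0.15 ms — and evaluate pooled Pearson correlations of
each measure against ordinal level. At this scale the model reproduces:
firing-rate suppression with anesthetic level in both series, its recovery
as $g_{Ks}$ steps down in the reversal series, declining integration and
complexity with anesthetic level, and declining excitatory functional
strength (the connectivity trend is evaluated on the same 20-s rasters
rather than the 60-s runs the full-scale protocol would use).

Two published quantities do **not** reproduce in this reconstruction, and
the package reports them honestly rather than forcing them:

* **The ~0.2% strong-connection fraction.** With the weight distribution
  as printed and conductances in mS/cm², the bisected single-spike
  threshold sits at the ~2.7% tail, not 0.2%. Reaching 0.2% would require
  a firing threshold near $e^{7}$ mS/cm² — three orders of magnitude above
  any single-synapse conductance this neuron could need — and rescaling
  the weights to force it (we tried) leaves recurrence too weak to produce
  any anesthesia effect at all. The two published calibrations appear
  mutually inconsistent under this reconstruction.
* **The A-series phase-coherence increase.** Here wake is the burstier
  state: with the heavy-tailed weights, the subgraph of non-negligible
  edges has an effective in-degree of only a few synapses per cell — too
  sparse for an inhibition-paced population rhythm — so raising
  $P_{GABA}$ damps population bursts rather than pacing them, and MPC
  drifts slightly *down* with anesthetic level. Rate, integration and
  complexity trends are insensitive to this; the synchrony mechanism is
  the one piece of the published phenomenology this reconstruction does
  not capture, across every noise rate, cap and weight scale we explored.

## A short session

```{r, eval = FALSE}
library(anesnet)

net <- buildNetwork(seed = 1)
wake <- levelParameters("A")[1, ]
deep <- levelParameters("A")[4, ]

rWake <- simulateNetwork(net, wake, duration = 20000, seed = 1)
rDeep <- simulateNetwork(net, deep, duration = 20000, seed = 1)

measureSuite(rWake, seed = 1)
measureSuite(rDeep, seed = 1)

fn <- inferFunctionalNetwork(rWake, seed = 1)
connectionProbability(fn)
```
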