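---
title: "Recruitment networks: from synaptic structure to propagating activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recruitment networks: from synaptic structure to propagating activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`recruitnet` studies how the routing of spiking activity through a recurrent
cortical circuit relates to the circuit's synaptic wiring. Its core objects
are a conductance-based spiking network model, a family of activity-derived
directed graphs built from the model's spike trains, and the graph statistics
— small-world ratios against density-matched nulls, and the decomposition of
directed clustering into fan-in, fan-out, middleman and cycle triangle motifs
— that compare those graphs with the underlying synaptic topology. A parallel
arm applies the same motif statistics to functional networks inferred from
(synthetic) population calcium-imaging recordings.

This vignette documents the model, the estimators, the parameters that
matter, and the design decisions taken where the problem was genuinely open.
Nothing here states an empirical result that the test-suite or
`scripts/acceptance.R` does not itself compute.

## The population model

The network holds 1000 excitatory and 200 inhibitory leaky integrate-and-fire
neurons with conductance-based synapses, wired as a class-dependent
Erdős–Rényi digraph: connection probability depends only on the source and
target classes (E→E 0.2, E→I 0.35, I→E 0.25, I→I 0.3). Synaptic weights are
lognormal (meanlog −0.64, sdlog 0.51; mean 0.60, variance 0.11 in multiples
of the leak conductance), with I→E contacts further scaled ×1.5. The membrane
follows

$$\tau_m \frac{dV}{dt} = (E_{leak}-V) + g_e(E_e-V) + g_i(E_i-V) + g_t(E_t-V),$$

with conductances in leak multiples, $E_e = E_t = 0$ mV, $E_i = -90$ mV,
$E_{leak} = -65$ mV, threshold −48 mV, reset −70 mV, 1 ms absolute
refractoriness, $\tau_m = 20$ ms and synaptic decay constants
$\tau_e = 10$ ms, $\tau_i = 5$ ms. Integration is exponential-Euler — exact
decay of the conductances, forward Euler on $V$ — at $dt = 0.1$ ms, which is
stable and cheap for these time constants; deliveries take effect at the next
integration step (no transmission delay).

A trial is 50 ms of Poisson drive at 15 Hz from a pool of 50 input units
(each contacting excitatory cells with probability 0.1), followed by 100 ms
of freely evolving activity; only that recording window enters the raster.
Every 100 trials (an *epoch*) the input projections are redrawn, emulating a
diversity of stimuli. Sessions default to 5 epochs.

### Two reconstruction constants, and why they exist

Two constants of the synapse model cannot be taken at face value from the
parameter list above, because its face-value reading is dynamically
inconsistent with the regime it is supposed to produce:

* **Kernel normalisation.** If a presynaptic spike of weight $w$ increments
  the target conductance by $w$ directly, the recurrent excitation
  (in-degree ≈ 200, mean weight 0.6, $\tau_e = 10$ ms) is supercritical at
  every activity level: from any initial condition the network races into a
  stable ~900 Hz saturated state, three orders of magnitude away from the
  sparse regime of interest. `recruitnet` therefore reads the weights as
  *time-integrated* conductances of unit-integral exponential kernels: a
  spike adds $\kappa\, w/\tau_{syn}$ to the conductance (`kernel_gain`
  $\kappa$, default 1). Because $\tau_i < \tau_e$, this normalisation also
  doubles the relative strength of inhibition, which is what makes the
  sparse balanced state exist at all. Stored network weights remain the
  lognormal draws themselves, so weight-distribution statistics are
  unaffected.

* **Tonic drive.** The tonic conductance ($E_t = 0$) pulls the isolated-cell
  equilibrium above threshold, so its magnitude sets how strongly the
  balanced network is driven. With $g_t$ equal to the full leak conductance
  the model fires at ~3 Hz with ~35% participation; with $g_t = g_{leak}/2$
  (the package default) it sits at the intended operating point — excitatory
  rates ≈ 1.3–1.6 Hz with a heavy-tailed rate distribution (population sd
  ≈ 3), per-epoch participation ≈ 64–69%, median branching coefficient
  1.00 in 10 ms bins, and ~9–11 excitatory presynaptic spikes in the 25 ms
  preceding each postsynaptic spike. `g_t` is an explicit parameter; the
  sensitivity is roughly linear over $g_t/g_{leak} \in [0.4, 0.7]$ (rate
  ≈ 1.0–2.1 Hz) and both directions degrade either the rate or the
  presynaptic-count statistic, so the default is a genuine compromise and is
  not revisited per analysis.

The third free constant, `input_scale`, multiplies the input-pool projection
weights (the stimulus is otherwise unspecified); at its default of 1 the
50 ms drive ignites activity at the level the recurrent network then
sustains.

In this regime the network is *bistable*: the sparse balanced state coexists
with the saturated one, and the sparse state is maintained by inhibition
tracking the tonic and recurrent drive. Trials start from rest
($V = E_{leak}$, zero conductances); the input phase doubles as warm-up, and
the recording window is statistically stationary (the package's
stationarity profile over 10 ms bins is flat after the first bin).

## Activity maps

All maps live on the excitatory population, with spike times discretised
into 1 ms bins. The tri-state encoding marks each (trial, neuron, bin) as
firing (2), recently active (1; fired within the preceding $T$ ms, default
25), or silent (0); windows never cross trial boundaries.

* **Functional network** — edge $(i,j)$ is the conditional frequency
  $P(s_j = 2 \mid s_i > 0)$ pooled over all trials and bins: how often $j$
  fires in a bin where $i$ was recently active. Simultaneous firing counts
  ($s_i = 2$ satisfies $s_i > 0$).
* **Active subnetwork** — the synaptic subgraph induced by neurons that
  fired at least once, represented on the full excitatory vertex set with
  silent neurons isolated. This representation matters: null models are
  density-matched on the same vertex set as every other family, and the
  activity concentration (a denser active core inside a fixed vertex set) is
  precisely what the statistics are designed to expose. An induced-node-set
  representation would, by construction, be an Erdős–Rényi graph at the same
  density as its nulls and carry no signal.
* **Recruitment network** — the functional network masked by synaptic
  support: non-zero edges join synaptically connected pairs that actually
  fired in lagged sequence, the map of where activity propagated through
  synapses.
* **Voltage-conditioned networks** — reverse correlograms conditioned on
  postsynaptic voltage: for each of 8 equal-occupancy bins of the pooled
  subthreshold membrane-potential distribution (spike-emission bins
  excluded), edge $(i,j)$ is the fraction of $j$'s subthreshold samples in
  that voltage bin among samples taken while $i$ was recently active, masked
  by synaptic connectivity.

## Graph statistics

**Small-world scores.** Local clustering uses the neighbours-of-neighbours
form generalised to weights: the graph is symmetrised as $(W+W^\top)/2$ and
each closed triangle contributes the geometric mean of its three cube-rooted
weights (the arithmetic alternative was the other candidate; the geometric
form is the one whose self-normalisation is exactly scale-free, and the
choice is recorded in the report metadata). Weights are normalised by the
maximum of the *directed* matrix — the symmetrised maximum depends on
whether the largest weight lands on a reciprocal pair, which makes
weight-permuting nulls noisy by several percent. Characteristic path length
inverts weights to costs ($1/w$; absent edges are untraversable), runs
Dijkstra on the symmetrised graph, and averages over reachable ordered
pairs; unreachable pairs (nodes outside the active core) are dropped and
their fraction reported. Both statistics are normalised by their means over
20 Erdős–Rényi nulls matched in node count, edge count and exact weight
multiset; the small-world ratio is the quotient of the two normalised
values.

**Directed motif census.** Seen from a reference node, a closed triangle is
a *fan-in* (two in-neighbours, themselves connected), *fan-out* (two
connected out-neighbours), *middleman* (an in-neighbour linked to an
out-neighbour) or *cycle*. Numerators are matrix-product triangle counts
(weighted form: cube-rooted weights normalised by the maximum); denominators
are the degree-based possible-triangle terms $d_{in}(d_{in}-1)$,
$d_{out}(d_{out}-1)$ and $d_{in}d_{out}-d_\leftrightarrow$. A literal
$O(n^3)$ enumeration (`motif_census_brute`) is the reference implementation
the matrix route is validated against, exhaustively on all 3-node digraphs
and on batches of random 7- and 20-node digraphs.

For activity-derived graphs the census is taken from the perspective of a
reference *postsynaptic* neuron (`perspective = "target"`): the adjacency is
transposed before classification, so "fan-in" names the pattern where two
interconnected partners converge onto the reference in the
influence-reversed map. The two orientations are exact mirrors (fan-in and
fan-out swap; middleman and cycle are invariant), and for
orientation-symmetric graphs such as the Erdős–Rényi synaptic topology the
distinction vanishes. The package fixes the postsynaptic-reference
convention for functional-family censuses because that is the orientation in
which the census expresses presynaptic convergence — the phenomenon the
recruitment analysis is about.

**Clustering propensity.** To compare clustering across very different
densities, a motif's level is expressed as the fractional distance between
density-matched lattice and random references:
$1-\Delta C = 1-(C_{latt}-C_{obs})/(C_{latt}-C_{rand})$, clamped to [0, 1].
The lattice null is a directed ring lattice filled outward from nearest
neighbours to the exact edge count, strongest weights at shortest range.
Graphs are first thresholded to their strongest 20% of non-zero edges, the
density regime where sparse functional maps admit a lattice match.

## Triplet timing

Pure triplets are enumerated exactly: a *fan-in triangle* (a, b, t) has
exactly the edges a→t, b→t, a→b and no others among the three nodes; a
*simple convergence* wedge has exactly a→t and b→t. A *coincident epoch* is
a postsynaptic spike whose centred 50 ms window contains at least one spike
of each presynaptic neuron; rates are normalised per triplet and trial, so
the uniform subsample of triplets used for tractability (10,000 per class by
default) leaves them unbiased. Within an epoch each presynaptic neuron's
timing is its spike nearest the postsynaptic spike, a scalar per epoch;
timing statistics are computed from 1000 sampled epochs.

## The imaging arm

`detect_events` mirrors a two-stage threshold-crossing scheme for
fluorescence traces: cells are retained when the 99th-percentile/mean ratio
of their raw trace exceeds 1.55, and events are excursions of the z-scored
trace above 2σ, extended backwards to the bin after the most recent crossing
of the trace median (the full-trace median; a baseline-segment median was
the alternative, but the generator's traces have no protected baseline
segment).

`infer_functional_weights` reconstructs a directed functional map from
binary event rasters using lagged co-onsets with iterative explaining-away:
beliefs start at the conditional onset frequency
$P(\text{onset}_j \text{ at } f \mid \text{onset}_i \text{ at } f-1)$, the
credit for each onset is divided among its candidate parents in proportion
to current beliefs, beliefs are re-estimated from accumulated credit, and
the procedure repeats to tolerance 10⁻⁶ or 100 sweeps, then averages over 5
random initialisations. The update is validated by planted-structure
recovery — on synthetic recordings the precision of the top-5% inferred
edges exceeds the planted density at least five-fold — not by equivalence to
any external implementation. Conditioning on onsets rather than sustained
event frames is deliberate: a long event is one episode of elevated firing,
and tying influence to its start keeps slow fluorescence dynamics from
smearing causal credit.

## Synthetic data

The calcium generator emulates the *ex vivo* recording setting: ~450 cells
at 20 Hz for 5 minutes, event trains built from sparse population bursts
plus background activity on a planted directed graph (a source's event onset
lifts each target's onset probability by `coupling` one frame later),
convolved with a difference-of-exponentials transient (rise 50 ms, decay
600 ms — generator conventions, not claims about indicator kinetics), scaled
by a lognormal per-cell amplitude over a unit baseline, plus Gaussian noise.
The amplitude distribution (`amp_meanlog = log(0.125)`, `amp_sdlog = 0.6`)
is calibrated once so that ≈ 43% of cells pass the 1.55 retention cutoff;
the planted graph defaults (edge probability 0.01, coupling 0.15) keep the
event cascade subcritical (branching ≈ 0.7) at a realistic event budget.
What the generator does *not* emulate: photon noise, neuropil contamination,
drift, and overlapping cell segmentation — passing tests on it validate the
estimators' contracts, not their robustness to real optical artefacts.

The rate-matched Poisson surrogate replaces every (neuron, trial, 100 ms
bin) spike count with a Poisson draw of the same mean and uniform times,
preserving the inhomogeneous rate profile while destroying synaptic
interactions.

## Numerical choices and degenerate inputs

* Coefficients with zero denominators (isolated or degree-one nodes) are 0;
  graph-level censuses are means over all nodes.
* Fully disconnected graphs raise errors in path-based statistics;
  partially disconnected graphs drop unreachable pairs and report the
  fraction.
* `threshold_and_bootstrap` refuses fewer than 10 surviving edges;
  percentile 100 is a boundary error.
* Constant or non-positive fluorescence traces are dropped with a warning
  (their signal-to-noise ratio is undefined).
* All randomness descends from one master seed through a deterministic
  child-seed hash, so any epoch, trial or null draw is reproducible in
  isolation.

## Problem sizes

The acceptance analyses use the full 1200-neuron model: five structural
iterations, 5 epochs × 100 trials each, 20 nulls per normalisation, 10,000
triplets per motif class, and 100 long trials for the interspike-interval
protocol. Unit tests use a 120-neuron model with identical physiology and
two 40-trial epochs, which preserves every qualitative property at a
fraction of the cost. The irregularity statistic (ISI CV²) treats the 100
repetitions of the stimulation cycle as one continuous session, so intervals
spanning cycle boundaries are included; restricting to within-cycle
intervals selects the high-rate, regular minority of neurons and roughly
halves the statistic.

## Known limitations

* The dynamical regime reproduces the first-order statistics (rates,
  participation, branching, irregularity, presynaptic convergence counts)
  and the undirected higher-order structure (clustering of functional,
  recruitment and active maps relative to nulls), but expresses the
  *directional* higher-order signatures more weakly than the reference
  setting: the coincidence-rate advantage of fan-in triangles over simple
  convergence reaches ~1.2–1.3× rather than ~1.9×, recruitment path
  shortening saturates near 0.8 rather than 0.65, and the inferred-map
  clustering of rate-matched Poisson surrogates collapses only partially.
  These quantities all depend on how strongly individual synapses cause
  postsynaptic spikes; in the implemented balanced regime, spiking is driven
  more by collective fluctuations than by identifiable presynaptic
  ensembles, and no admissible setting of the two reconstruction constants
  removed the discrepancy without destroying the first-order statistics.
* The double-strength contrast (binary motif censuses at doubled weights) is
  implemented and stable, but the expected direction (fan-in down, fan-out
  up as single inputs gain independent efficacy) is not reproduced in this
  regime for the same reason.
* Weighted-census magnitudes depend on the maximum-weight normalisation and
  should be compared across lag intervals or models only as orderings.
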