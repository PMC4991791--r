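# recruitnet

Linking synaptic connectivity to the structure of propagating activity in
recurrent cortical circuits.

Local neocortical populations are sparsely and (to first approximation)
randomly wired, yet the activity that propagates through them is anything
but random. `recruitnet` provides the full toolchain to study this
dissociation in a controlled setting:

* a conductance-based leaky integrate-and-fire network model (1000
  excitatory + 200 inhibitory neurons, class-dependent Erdős–Rényi
  connectivity, lognormal synaptic weights, Poisson input pool) producing
  sparse, irregular, near-critical spiking;
* **activity maps** built from the spike trains — the *functional network*
  (edge *i→j* = P(*j* fires | *i* active within the preceding *T* = 25 ms)),
  the *active subnetwork* (synaptic subgraph of neurons that fired), and the
  *recruitment network* (functional edges with synaptic support: where
  activity actually propagated through synapses);
* **graph statistics** against density- and weight-matched null models:
  small-world ratios (clustering elevation over characteristic-path
  reduction), the decomposition of directed clustering into the four
  triangle motifs (fan-in, fan-out, middleman, cycle), and clustering
  propensity (1 − ΔC, the fractional distance between density-matched
  lattice and random references);
* **triplet timing**: coincident-firing rates and presynaptic timing at
  pure fan-in triangles (a→t, b→t, a→b and nothing else) versus simple
  convergence wedges;
* a **calcium-imaging arm**: event detection from fluorescence traces
  (99th-percentile/mean retention gate, 2σ excursions walked back to the
  median crossing), iterative explaining-away inference of directed
  functional weights from single-frame-lagged event onsets, bootstrap
  false-positive analysis of the resulting motif censuses, and spatial
  statistics — all testable against synthetic recordings with planted
  ground truth.

The central quantity is the directed clustering census. From a reference
node, closed triangles decompose into fan-in (two interconnected partners
converge on the reference), fan-out, middleman and cycle patterns, with
coefficients of the form

    C_i^{fan-in} = (Ŵ^T Ŵ Ŵ)_ii / (d_in (d_in − 1)),   Ŵ = (W / max W)^{1/3}

and analogous degree-based denominators for the other classes. In a random
synaptic topology all four are equal; in recruitment maps of model activity
the fan-in motif dominates — convergent input from interconnected
presynaptic neurons is what drives postsynaptic recruitment.

## Worked example

One epoch (100 trials) of the default model, mapped and scored:

```r
library(recruitnet)

net <- build_synaptic_network(connectivity_params(), seed = 7)
#> <synaptic_network> 1000 excitatory + 200 inhibitory neurons, 332070 edges

raster <- run_session(net, neuron_params(), sim_config(n_epochs = 1, seed = 42))$raster
#> <spike_raster> 46505 spikes, 1200 neurons (1000 excitatory), 100 trials x 100 ms

summarize_dynamics(raster, net = net, include_correlation = FALSE)
#> <dynamics_summary>
#>   excitatory rate     1.356 Hz (population sd 2.791)
#>   branching (median)  1.000
#>   participation       69.0% per epoch, 69.0% overall
#>   presyn spikes/spike 8.61 +/- 2.91
```

The excitatory population fires sparsely (~1.4 Hz) with a heavy-tailed rate
distribution, the branching coefficient sits at criticality (1.00), and each
postsynaptic spike is preceded by ~9 excitatory presynaptic spikes in its
25 ms integration window — collective drive, not single inputs.

```r
func <- functional_network(raster, T = 25)
recr <- recruitment_network(func, net)
#> <wdigraph kind=recruitment> 1000 nodes, 29590 edges, density 0.0296

small_world_scores(recr, n_null = 20, seed = 1)
#> <graph_stat_report> clustering 4.342, path 0.737, small-world 5.893 (n_null = 20)
```

Although the synaptic wiring is Erdős–Rényi (its own ratios are 1.0 by
construction), the recruitment map is strongly small-world: ~4.3× the
clustering of density-matched random graphs at ~0.74× their characteristic
path. Decomposing its clustering by motif (censused from the perspective of
the recruited, postsynaptic reference node):

```r
directed_clustering(recr, binary = FALSE, perspective = "target")$global
#>     fan_in    fan_out  middleman      cycle undirected
#>    0.00150    0.00039    0.00070    0.00054    0.20023
```

The fan-in triangle — two *interconnected* neurons converging on the
reference — is ~4× more prevalent than fan-out, the signature of cooperative
presynaptic recruitment.

The `analysis/` directory holds numbered drivers that run each stage of the
study at full scale and write tables under `results/`.

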