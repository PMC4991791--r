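#!/usr/bin/env Rscript
# Stage 2: map the simulated spiking into the functional, active and
# recruitment networks (at T = 10, 25, 50 ms) and export them.

suppressMessages(library(recruitnet))
dir.create("results", showWarnings = FALSE)

net <- build_synaptic_network(connectivity_params(), seed = 7)
raster <- run_session(net, neuron_params(),
                      sim_config(n_epochs = 5, seed = 11))$raster

for (T in c(10, 25, 50)) {
  func <- functional_network(raster, T = T)
  recr <- recruitment_network(func, net)
  cat(sprintf("T = %2d ms: functional density %.3f, recruitment density %.4f\n",
              T, graph_density(func), graph_density(recr)))
  write_edgelist_csv(func, sprintf("results/functional_T%02d.csv", T))
  write_edgelist_csv(recr, sprintf("results/recruitment_T%02d.csv", T))
  if (T == 25) {
    write_graphml(func, "results/functional_T25.graphml")
    write_graphml(recr, "results/recruitment_T25.graphml")
  }
}

act <- active_subnetwork(net, raster)
cat(sprintf("active subnetwork: %d of %d excitatory neurons fired\n",
            length(attr(act, "active")), net$n_e))
write_edgelist_csv(act, "results/active_subnetwork.csv")
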