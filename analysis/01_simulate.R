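#!/usr/bin/env Rscript
# Stage 1 — simulate the study system.
#
# Generates a synthetic brain with a planted convergence-divergence circuit:
# 20 region-intrinsic hub neurons, each with 8 dedicated upstream partners
# and 7 dedicated downstream partners, plus the full synapse-site table with
# region labels (hubs strictly > 85% in-region) and one skeleton per hub.
# Everything downstream (02..07) reads only the files written here.

suppressMessages(library(circuitome))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- architecture_spec("convergence_divergence", n_hub = 20, n_in = 160,
                          n_out = 140, fan_in = 8, fan_out = 7, seed = seed)
brain <- generate_brain(spec, region = "SMP", skeletons = "hubs")

write_synapse_table(brain$sites, file.path(out, "synapses.csv"))
write_edge_list(brain$graph, file.path(out, "edges.csv"))
write_neuron_metadata(brain$neurons, file.path(out, "neurons.csv"))
utils::write.csv(brain$ground_truth, file.path(out, "ground_truth.csv"),
                 row.names = FALSE)
dir.create(file.path(out, "skeletons"), showWarnings = FALSE)
for (id in names(brain$skeletons)) {
  write_swc(brain$skeletons[[id]],
            file.path(out, "skeletons", paste0(id, ".swc")))
}

message(sprintf(
  "simulated %d neurons, %d synaptic sites, %d connections, %d skeletons",
  nrow(brain$neurons), nrow(brain$sites), nrow(brain$graph$edges),
  length(brain$skeletons)))
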