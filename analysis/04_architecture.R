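#!/usr/bin/env Rscript
# Stage 4 — circuit architecture tests.
#
# Runs the Shannon-entropy three-null battery (labeled-line, mixed, shuffled)
# on the intrinsic population's input connectivity and the triad motif census
# with network significance profiles on both sides of the hub circuit.

suppressMessages(library(circuitome))

graph <- read_edge_list("results/data/edges.csv", threshold = 2L)
hubs <- utils::read.csv("results/intrinsic_ids.csv",
                        stringsAsFactors = FALSE)$id

bat <- architecture_battery(graph, hubs, direction = "input",
                            alpha = 0.01, n_replicates = 100L, seed = 401L)
print(bat)

nsp_in <- motif_nsp(graph, hubs, "input", n_shuffles = 100L,
                    edge_threshold = 2L, seed = 402L)
nsp_out <- motif_nsp(graph, hubs, "output", n_shuffles = 100L,
                     edge_threshold = 2L, seed = 403L)

utils::write.csv(bat$entropies, "results/hub_entropies.csv",
                 row.names = FALSE)
utils::write.csv(
  data.frame(code = names(nsp_in$counts),
             count_input = as.integer(nsp_in$counts),
             z_input = nsp_in$z_scores, nsp_input = nsp_in$nsp,
             count_output = as.integer(nsp_out$counts),
             z_output = nsp_out$z_scores, nsp_output = nsp_out$nsp),
  "results/motif_nsp.csv", row.names = FALSE)

message(sprintf("classified architecture: %s", bat$classified))
message(sprintf("leading input-side motif: %s (NSP %.3f); output-side: %s (NSP %.3f)",
                names(which.max(nsp_in$nsp)), max(nsp_in$nsp),
                names(which.max(nsp_out$nsp)), max(nsp_out$nsp)))
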