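#!/usr/bin/env Rscript
# Stage 5 — multi-layer sensory-input tracing.
#
# Splits the input neurons into three nominal modalities and traces their
# relative connectivity onto the circuit's downstream targets across 0..3
# intermediate layers. In the planted convergence-divergence circuit the
# intrinsic hubs are the only relay, so the strength should concentrate at
# exactly one intermediate layer.

suppressMessages(library(circuitome))

graph <- read_edge_list("results/data/edges.csv", threshold = 2L)
hubs <- utils::read.csv("results/intrinsic_ids.csv",
                        stringsAsFactors = FALSE)$id
gt <- utils::read.csv("results/data/ground_truth.csv",
                      stringsAsFactors = FALSE)

# inputs whose only connection fell below the 2-synapse edge threshold are
# no longer in the graph
srcs <- intersect(gt$id[gt$role == "input"], graph$nodes)
targets <- intersect(gt$id[gt$role == "output"], graph$nodes)
mods <- split(srcs, rep(c("mechanosensory", "olfactory", "visual"),
                        length.out = length(srcs)))

prof <- multilayer_profile(graph, mods, targets = targets, max_layers = 3L)
utils::write.csv(prof$strength, "results/multilayer.csv", row.names = FALSE)

agg <- stats::aggregate(strength ~ layer, prof$strength, sum)
message("total relative strength by intermediate-layer count:")
print(agg)
message(sprintf("peak at %d intermediate layer(s)",
                agg$layer[which.max(agg$strength)]))

mp <- modality_preference(prof, layer = 1, normalize = TRUE)
utils::write.csv(data.frame(id = rownames(mp), mp),
                 "results/modality_preference.csv", row.names = FALSE)
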