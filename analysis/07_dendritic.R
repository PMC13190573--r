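#!/usr/bin/env Rscript
# Stage 7 — subcellular synaptic topology of one hub neuron.
#
# Places two input classes on a hub skeleton with opposite placement biases
# (a proximally biased inhibitory-like class versus a distally biased
# excitatory-like class), assigns sites to skeleton nodes, tests the
# proximal-bias hypothesis with a median-difference permutation test, and
# writes both dendrogram layouts.

suppressMessages(library(circuitome))

paths <- list.files("results/data/skeletons", full.names = TRUE,
                    pattern = "\\.swc$")
sk <- read_swc(paths[[1]])

syn <- place_synapses(sk, list(
  list(label = "inhibitory", count = 150, bias = "proximal", strength = 3),
  list(label = "excitatory", count = 300, bias = "distal", strength = 3)),
  seed = 701L)
syn$x <- sk$nodes$x[match(syn$node_id, sk$nodes$node_id)]
syn$y <- sk$nodes$y[match(syn$node_id, sk$nodes$node_id)]
syn$z <- sk$nodes$z[match(syn$node_id, sk$nodes$node_id)]
syn$polarity <- "post"

ann <- assign_synapses(sk, syn[, c("x", "y", "z", "polarity", "class")])
dd <- class_distance_distributions(ann, reference = "root",
                                   group_by = "class")
utils::write.csv(dd, "results/geodesic_distances.csv", row.names = FALSE)

test <- proximal_bias_test(dd$distance[dd$class == "inhibitory"],
                           dd$distance[dd$class == "excitatory"],
                           n_permutations = 9999L, seed = 702L)
message(sprintf(
  "median inhibitory - excitatory distance: %.0f nm (p = %.4g, %s)",
  test$statistic, test$p_value, test$direction))

lay <- sfdp_layout(sk, iterations = 300L, seed = 703L)
utils::write.csv(data.frame(node_id = rownames(lay$coords), lay$coords),
                 "results/sfdp_layout.csv", row.names = FALSE)
message(sprintf("sfdp: %d accepted steps, energy %.3g -> %.3g",
                length(lay$energy) - 1L, lay$energy[1],
                lay$energy[length(lay$energy)]))

rl <- ranked_layout(sk, rank_by = "cable")
utils::write.csv(rl$coords, "results/ranked_layout.csv", row.names = FALSE)
message(sprintf("ranked layout: %d virtual nodes, %d crossings",
                rl$n_virtual, rl$crossings))
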