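#!/usr/bin/env Rscript
# Stage 3 — brain-wide connectivity atlas of the intrinsic population.
#
# Builds normalised upstream+downstream connectivity vectors for the detected
# intrinsic neurons, embeds them with UMAP on Bray-Curtis distances, clusters
# the embedding with HDBSCAN, and records Ward clusters, k-NN local density,
# and a 2-D KDE of the embedding.

suppressMessages(library(circuitome))

graph <- read_edge_list("results/data/edges.csv", threshold = 2L)
graph <- threshold_graph(graph, 2L)
hubs <- utils::read.csv("results/intrinsic_ids.csv",
                        stringsAsFactors = FALSE)$id

fm <- build_feature_matrix(graph, hubs)
emb <- embed_umap(fm, n_neighbors = 8L, min_dist = 0.1, n_components = 3L,
                  seed = 301L)
hdb <- cluster_embedding(emb$coords, min_cluster_size = 5L, min_samples = 5L)
ward <- ward_cluster(bray_curtis_matrix(fm$features))
dens <- local_density(fm, k = 5L)
kde <- kde_2d(emb$coords[, 1:2])

utils::write.csv(
  data.frame(id = rownames(emb$coords), emb$coords, hdbscan = hdb,
             ward = as.integer(ward), density = dens),
  "results/atlas.csv", row.names = FALSE)

message(sprintf(
  "atlas over %d neurons: %d HDBSCAN clusters (%d noise), Ward cut k = %d",
  length(hubs), attr(hdb, "n_clusters"), sum(hdb == -1L), attr(ward, "k")))
message(sprintf("KDE grid integrates to %.3f",
                sum(kde$z) * diff(kde$x[1:2]) * diff(kde$y[1:2])))
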