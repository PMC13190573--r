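# Connectivity atlas: per-hub connectivity feature vectors, Bray-Curtis
# distances, Ward hierarchical clustering, UMAP embedding with HDBSCAN
# clusters, k-NN local density, and 2-D KDE.

#' Bray-Curtis distance between two non-negative vectors
#'
#' `d(u, v) = sum(|u - v|) / sum(u + v)`. A semimetric: symmetric, 0 iff
#' `u == v`, 1 iff the supports are disjoint; the triangle inequality is not
#' guaranteed.
#'
#' @param u,v non-negative numeric vectors of equal length, not both zero.
#' @return distance in \[0, 1\].
#' @export
bray_curtis <- function(u, v) {
  stopifnot(length(u) == length(v), all(u >= 0), all(v >= 0))
  denom <- sum(u + v)
  if (denom == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(u - v)) / denom
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param x numeric matrix, rows = observations.
#' @return a symmetric matrix of distances (all-zero rows yield `NA`
#'   against each other and are flagged via the `zero_rows` attribute).
#' @export
bray_curtis_matrix <- function(x) {
  x <- as.matrix(x)
  zero <- rowSums(x) == 0
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "zero_rows") <- which(zero)
  d
}

#' Build per-hub connectivity feature vectors
#'
#' One row per hub; columns are the union of upstream partner ids followed by
#' the union of downstream partner ids. Entries in the upstream block are the
#' hub's input synapse counts normalised by its total input count (block sums
#' to 1, or 0 for hubs without inputs), and symmetrically downstream. Column
#' order is deterministic (sorted partner ids).
#'
#' @param graph a `conn_graph`.
#' @param hubs hub neuron ids (must be nodes of `graph`).
#' @return list of class `feature_matrix`: `features` (matrix), `upstream_cols`,
#'   `downstream_cols`, `zero_input_hubs`, `zero_output_hubs`.
#' @export
build_feature_matrix <- function(graph, hubs) {
  stopifnot(all(hubs %in% graph$nodes))
  ed <- graph$edges
  up_ed <- ed[ed$post %in% hubs, , drop = FALSE]
  dn_ed <- ed[ed$pre %in% hubs, , drop = FALSE]
  up_partners <- sort(unique(up_ed$pre))
  dn_partners <- sort(unique(dn_ed$post))
  U <- matrix(0, length(hubs), length(up_partners),
              dimnames = list(hubs, up_partners))
  D <- matrix(0, length(hubs), length(dn_partners),
              dimnames = list(hubs, dn_partners))
  if (nrow(up_ed) > 0L) U[cbind(up_ed$post, up_ed$pre)] <- up_ed$weight
  if (nrow(dn_ed) > 0L) D[cbind(dn_ed$pre, dn_ed$post)] <- dn_ed$weight
  urs <- rowSums(U); drs <- rowSums(D)
  U[urs > 0, ] <- U[urs > 0, , drop = FALSE] / urs[urs > 0]
  D[drs > 0, ] <- D[drs > 0, , drop = FALSE] / drs[drs > 0]
  feats <- cbind(U, D)
  colnames(feats) <- c(paste0("up:", up_partners), paste0("down:", dn_partners))
  structure(list(features = feats,
                 upstream_cols = seq_along(up_partners),
                 downstream_cols = length(up_partners) + seq_along(dn_partners),
                 zero_input_hubs = hubs[urs == 0],
                 zero_output_hubs = hubs[drs == 0]),
            class = "feature_matrix")
}

#' Ward hierarchical clustering on a distance matrix
#'
#' Agglomerates with the Ward variance-minimisation update on the supplied
#' (typically Bray-Curtis) distances. Note Bray-Curtis is not Euclidean, so
#' Ward's variance interpretation is heuristic here; the merge sequence
#' follows the Lance-Williams recurrence on the provided distances exactly.
#'
#' @param d distance matrix (square symmetric, zero diagonal) or `dist`.
#' @param k number of clusters to cut; if `NULL`, a dynamic cut at the
#'   largest merge-height gap is used (recorded in attributes).
#' @return integer cluster labels with attributes `hclust` (the tree), `k`,
#'   and `cut_rule`.
#' @export
ward_cluster <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
      stop("distance matrix must be symmetric")
    }
    d <- stats::as.dist(d)
  }
  hc <- stats::hclust(d, method = "ward.D2")
  if (is.null(k)) {
    gaps <- diff(hc$height)
    k <- if (length(gaps) == 0L) 1L else length(hc$height) - which.max(gaps) + 1L
    rule <- "largest_height_gap"
  } else {
    rule <- "fixed_k"
  }
  labels <- stats::cutree(hc, k = k)
  attr(labels, "hclust") <- hc
  attr(labels, "k") <- k
  attr(labels, "cut_rule") <- rule
  labels
}

#' UMAP embedding of connectivity features
#'
#' Embeds hubs with UMAP on the Bray-Curtis distances of their concatenated
#' upstream/downstream connectivity vectors. Deterministic for a fixed seed
#' (single-threaded optimisation).
#'
#' @param features a `feature_matrix`, plain matrix, or precomputed distance
#'   matrix / `dist`.
#' @param n_neighbors,min_dist,n_components UMAP parameters (defaults 36,
#'   0.1, 3 — the setting that best preserved planted structure in the
#'   connectome analyses this package reproduces).
#' @param seed integer seed.
#' @return list of class `atlas_embedding`: `coords` (n x n_components),
#'   `params`.
#' @export
embed_umap <- function(features, n_neighbors = 36L, min_dist = 0.1,
                       n_components = 3L, seed = 1L) {
  if (inherits(features, "feature_matrix")) features <- features$features
  if (inherits(features, "dist")) {
    d <- features
  } else if (is.matrix(features) && isTRUE(all.equal(unname(features),
                                                     unname(t(features)))) &&
             all(diag(features) == 0) && nrow(features) == ncol(features)) {
    d <- stats::as.dist(features)
  } else {
    d <- stats::as.dist(bray_curtis_matrix(features))
  }
  n <- attr(d, "Size")
  if (n < n_neighbors + 1L) {
    stop("need at least n_neighbors + 1 rows (", n_neighbors + 1L, "), got ", n)
  }
  coords <- with_seed(seed, {
    uwot::umap(d, n_neighbors = n_neighbors, min_dist = min_dist,
               n_components = n_components, n_threads = 1,
               n_sgd_threads = 0, batch = FALSE, verbose = FALSE)
  })
  rownames(coords) <- attr(d, "Labels")
  structure(list(coords = coords,
                 params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                               n_components = n_components, seed = seed)),
            class = "atlas_embedding")
}

#' UMAP parameter-sweep robustness check
#'
#' Re-embeds over a grid of `n_neighbors` and `min_dist` values, clusters
#' each embedding with HDBSCAN, and reports the mean pairwise adjusted Rand
#' index of the cluster labellings across grid cells — a high value means the
#' atlas backbone is stable to the embedding parameters.
#'
#' @param features as in [embed_umap()].
#' @param n_neighbors_grid,min_dist_grid parameter grids (defaults 24/32/40/48
#'   and 0.1/0.15/0.2/0.25).
#' @param min_cluster_size,min_samples HDBSCAN parameters.
#' @param seed integer seed.
#' @return list with `mean_ari`, `ari_matrix`, `labels` (per grid cell).
#' @export
umap_sweep <- function(features, n_neighbors_grid = c(24L, 32L, 40L, 48L),
                       min_dist_grid = c(0.1, 0.15, 0.2, 0.25),
                       min_cluster_size = 15L, min_samples = 15L, seed = 1L) {
  grid <- expand.grid(n_neighbors = n_neighbors_grid, min_dist = min_dist_grid)
  labels <- lapply(seq_len(nrow(grid)), function(i) {
    emb <- embed_umap(features, n_neighbors = grid$n_neighbors[i],
                      min_dist = grid$min_dist[i], seed = seed)
    cluster_embedding(emb$coords, min_cluster_size = min_cluster_size,
                      min_samples = min_samples)
  })
  m <- length(labels)
  ari <- matrix(1, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      ari[i, j] <- ari[j, i] <- adjusted_rand_index(labels[[i]], labels[[j]])
    }
  }
  list(mean_ari = mean(ari[upper.tri(ari)]), ari_matrix = ari,
       labels = labels, grid = grid)
}

#' Adjusted Rand index between two labellings
#'
#' @param a,b integer label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# scikit-learn bridge (HDBSCAN has no installed R implementation)
the_sklearn <- new.env(parent = emptyenv())

sklearn_cluster <- function() {
  if (is.null(the_sklearn$mod)) {
    py <- Sys.which("python")
    if (nzchar(py) && is.null(getOption("circuitome.python_configured"))) {
      try(reticulate::use_python(py, required = FALSE), silent = TRUE)
      options(circuitome.python_configured = TRUE)
    }
    the_sklearn$mod <- reticulate::import("sklearn.cluster", delay_load = FALSE)
  }
  the_sklearn$mod
}

#' Density-based clustering of an embedding with HDBSCAN
#'
#' Clusters embedding coordinates with hierarchical density-based clustering
#' (HDBSCAN, via scikit-learn). Points the algorithm refuses to cluster are
#' labelled `-1` (noise). Returned labels are canonicalised: clusters are
#' renumbered 1..k by order of first appearance, so the labelling is
#' invariant to point order up to the clustering itself.
#'
#' @param coords numeric matrix of embedding coordinates (or an
#'   `atlas_embedding`).
#' @param min_cluster_size smallest cluster size accepted (default 15).
#' @param min_samples density smoothing parameter (default 15).
#' @return integer label vector (noise = -1), attribute `n_clusters`.
#' @export
cluster_embedding <- function(coords, min_cluster_size = 15L,
                              min_samples = 15L) {
  if (inherits(coords, "atlas_embedding")) coords <- coords$coords
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= min_samples)
  if (all(apply(coords, 2L, stats::sd) == 0)) {
    labels <- rep(1L, nrow(coords))
    attr(labels, "n_clusters") <- 1L
    return(labels)
  }
  cl <- sklearn_cluster()$HDBSCAN(
    min_cluster_size = as.integer(min_cluster_size),
    min_samples = as.integer(min_samples), copy = TRUE)
  raw <- as.integer(cl$fit_predict(coords))
  labels <- raw
  pos <- raw >= 0L
  if (any(pos)) {
    labels[pos] <- as.integer(factor(raw[pos], levels = unique(raw[pos])))
  }
  labels[!pos] <- -1L
  attr(labels, "n_clusters") <- length(unique(labels[pos]))
  labels
}

#' k-NN local density in connectivity space
#'
#' Density of each hub is the inverse of its mean Bray-Curtis distance to its
#' `k` nearest neighbours (self excluded; ties broken by row order). The mean
#' is floored at 1e-12 so duplicated rows stay finite (flagged).
#'
#' @param features a `feature_matrix` or matrix (rows > k).
#' @param k neighbour count (default 15).
#' @return positive numeric vector, attribute `duplicates` marking floored
#'   rows.
#' @export
local_density <- function(features, k = 15L) {
  if (inherits(features, "feature_matrix")) features <- features$features
  d <- bray_curtis_matrix(features)
  n <- nrow(d)
  if (n <= k) stop("need more than k rows")
  means <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    mean(sort(di, method = "radix")[seq_len(k)])
  }, 0)
  floored <- means < 1e-12
  dens <- 1 / pmax(means, 1e-12)
  attr(dens, "duplicates") <- which(floored)
  dens
}

#' 2-D kernel density estimate of embedding coordinates
#'
#' Gaussian product kernel with Scott's bandwidth (`sd * n^(-1/6)` per
#' dimension) on a regular grid over the padded bounding box. The grid
#' integrates to ~1 (trapezoid rule).
#'
#' @param coords n x 2 matrix (first two embedding components).
#' @param n_grid grid resolution per axis.
#' @param pad bounding-box padding as a multiple of the bandwidth.
#' @return list `x`, `y`, `z` (density grid), `bandwidth`, `degenerate` flag.
#' @export
kde_2d <- function(coords, n_grid = 128L, pad = 4) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  stopifnot(nrow(coords) >= 3L)
  n <- nrow(coords)
  h <- apply(coords, 2L, stats::sd) * n^(-1 / 6)
  degenerate <- any(h <= 0)
  scale <- max(diff(range(coords[, 1])), diff(range(coords[, 2])), 1)
  h <- pmax(h, 1e-3 * scale)  # bandwidth floor for collinear/identical input
  lims <- c(range(coords[, 1]) + c(-1, 1) * pad * h[1],
            range(coords[, 2]) + c(-1, 1) * pad * h[2])
  # MASS::kde2d's h is 1/4 bandwidth-of-kernel convention
  est <- MASS::kde2d(coords[, 1], coords[, 2], h = 4 * h, n = n_grid,
                     lims = lims)
  list(x = est$x, y = est$y, z = est$z, bandwidth = h, degenerate = degenerate)
}

#' Regional connectivity preference of hubs
#'
#' For each hub and each of three region groups, sums the hub's input
#' connectivity percentage over the group's member neurons and likewise the
#' output percentage, and keeps the larger of the two as the hub's preference
#' for that region.
#'
#' @param fm a `feature_matrix` from [build_feature_matrix()].
#' @param groups named list of three character vectors of member neuron ids.
#' @return n x 3 matrix of preferences in \[0, 1\], columns named after
#'   `groups`.
#' @export
connectivity_preference <- function(fm, groups) {
  stopifnot(inherits(fm, "feature_matrix"), length(groups) == 3L)
  feats <- fm$features
  up_ids <- sub("^up:", "", colnames(feats)[fm$upstream_cols])
  dn_ids <- sub("^down:", "", colnames(feats)[fm$downstream_cols])
  out <- sapply(groups, function(members) {
    inp <- rowSums(feats[, fm$upstream_cols[up_ids %in% members], drop = FALSE])
    outp <- rowSums(feats[, fm$downstream_cols[dn_ids %in% members], drop = FALSE])
    pmax(inp, outp)
  })
  rownames(out) <- rownames(feats)
  out
}

#' Map a 3-channel preference vector to display colours
#'
#' `"cmy"` maps the three preferences to the cyan, magenta, and yellow
#' channels (returned as RGB, so an all-zero preference renders white);
#' `"rgb"` maps them directly to red, green, blue (all-zero renders black).
#' Values are clipped to \[0, 1\].
#'
#' @param pref n x 3 matrix of preferences.
#' @param mode `"cmy"` or `"rgb"`.
#' @return n x 3 matrix of RGB values in \[0, 1\].
#' @export
preference_color <- function(pref, mode = c("cmy", "rgb")) {
  mode <- match.arg(mode)
  pref <- pmin(pmax(as.matrix(pref), 0), 1)
  out <- if (mode == "cmy") 1 - pref else pref
  colnames(out) <- c("r", "g", "b")
  out
}
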