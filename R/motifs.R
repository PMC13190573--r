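# Directed triad motif census and network significance profiles.

#' The 16 directed triad classes
#'
#' Standard triad taxonomy over 3 nodes (M-A-N labelling: counts of mutual,
#' asymmetric, and null dyads plus orientation letters), in the order used by
#' the census. The two single-edge-pair classes carry their circuit aliases:
#' `021D` ("down", one source feeding two targets) is the divergence motif
#' and `021U` ("up", two sources onto one target) is the convergence motif.
#'
#' @return data.frame with columns `code` and `alias`.
#' @export
triad_classes <- function() {
  data.frame(
    code = c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
             "030T", "030C", "201", "120D", "120U", "120C", "210", "300"),
    alias = c("empty", "single_edge", "mutual_dyad", "divergence",
              "convergence", "chain", "in_mutual", "out_mutual",
              "feedforward", "cycle", "double_mutual", "div_mutual",
              "conv_mutual", "chain_mutual", "near_complete", "complete"),
    stringsAsFactors = FALSE)
}

#' Directed triad census of a connectivity graph
#'
#' Counts, for every unordered node triple, the isomorphism class of the
#' induced directed subgraph. Counts over all 16 classes (including the empty
#' and single-edge classes) sum to `choose(n, 3)`.
#'
#' @param graph a `conn_graph` or an igraph object. The graph is assumed to
#'   be edge-thresholded already.
#' @param include_disconnected keep the sparse classes (empty, single-edge,
#'   mutual-dyad) in the returned vector; if `FALSE` they are dropped (their
#'   counts are still computed).
#' @return named integer vector of class counts (names are triad codes).
#' @export
triad_census_graph <- function(graph, include_disconnected = TRUE) {
  g <- if (inherits(graph, "igraph")) graph else as_igraph(graph)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  counts <- igraph::triad_census(g)
  names(counts) <- triad_classes()$code
  if (!include_disconnected) counts <- counts[-(1:3)]
  counts
}

#' Randomised ensembles for the motif null
#'
#' `"endpoint_shuffle"` redraws the graph uniformly among simple directed
#' graphs with the same node and edge counts (all edge endpoints reassigned);
#' `"degree_preserving"` applies double-edge swaps that preserve every node's
#' in- and out-degree (10 x |E| attempted swaps).
#'
#' @param g an igraph object.
#' @param null the randomisation scheme.
#' @return a randomised igraph object.
#' @keywords internal
randomize_graph <- function(g, null = c("endpoint_shuffle", "degree_preserving")) {
  null <- match.arg(null)
  if (null == "endpoint_shuffle") {
    igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g), directed = TRUE)
  } else {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = 10 * igraph::ecount(g)))
  }
}

side_subgraph <- function(graph, hubs, side = c("input", "output"),
                          edge_threshold = NULL) {
  side <- match.arg(side)
  if (!is.null(edge_threshold)) graph <- threshold_graph(graph, edge_threshold)
  ed <- graph$edges
  partners <- if (side == "input") {
    unique(ed$pre[ed$post %in% hubs])
  } else {
    unique(ed$post[ed$pre %in% hubs])
  }
  nodes <- union(hubs, setdiff(partners, hubs))
  keep <- ed$pre %in% nodes & ed$post %in% nodes
  conn_graph(ed[keep, , drop = FALSE], nodes = nodes,
             threshold = graph$threshold_applied)
}

#' Motif census with network significance profile
#'
#' Builds the side-specific hub subgraph (hubs plus their upstream partners
#' for the input side, hubs plus downstream partners for the output side),
#' counts directed triads, and compares each class count against a
#' randomised ensemble: `z_i = (N_real_i - mean(N_rand_i)) / sd(N_rand_i)`.
#' The network significance profile is the z vector scaled to unit Euclidean
#' norm. Classes with zero ensemble variance get `z = 0` and are flagged.
#'
#' @param graph a `conn_graph` (unthresholded or thresholded).
#' @param hubs hub neuron ids.
#' @param side `"input"` or `"output"`.
#' @param n_shuffles ensemble size (>= 2; default 100).
#' @param edge_threshold minimum synapse count per edge used for the census
#'   (dataset-dependent; conventionally 5 for high-z-resolution and 2 for
#'   lower-resolution reconstructions). Default 2.
#' @param null randomisation scheme, see [randomize_graph()]. The default
#'   endpoint shuffle randomises degrees as well as wiring; degree-preserving
#'   swaps are available but cannot, by construction, detect fan-in/fan-out
#'   enrichment (those counts are functions of the degree sequence).
#' @param seed integer seed.
#' @return list of class `motif_census`: `counts`, `z_scores`, `nsp`,
#'   `null_mean`, `null_sd`, `n_shuffles`, `edge_threshold`, `null`,
#'   `zero_sd_classes`.
#' @export
motif_nsp <- function(graph, hubs, side = c("input", "output"),
                      n_shuffles = 100L, edge_threshold = 2L,
                      null = c("endpoint_shuffle", "degree_preserving"),
                      seed = 1L) {
  side <- match.arg(side)
  null <- match.arg(null)
  stopifnot(n_shuffles >= 2L)
  sub <- side_subgraph(graph, hubs, side, edge_threshold)
  g <- igraph::simplify(as_igraph(sub))
  if (igraph::ecount(g) < 2L) {
    stop("subgraph too small to randomise; lower edge_threshold or enlarge the circuit")
  }
  counts <- triad_census_graph(g)
  rand_counts <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      triad_census_graph(randomize_graph(g, null))
    }, numeric(16L))
  })
  mu <- rowMeans(rand_counts)
  sg <- apply(rand_counts, 1L, stats::sd)
  z <- ifelse(sg > 0, (counts - mu) / sg, 0)
  nrm <- sqrt(sum(z^2))
  nsp <- if (nrm > 0) z / nrm else z
  structure(list(counts = counts, z_scores = z, nsp = nsp,
                 null_mean = mu, null_sd = sg,
                 n_shuffles = as.integer(n_shuffles),
                 edge_threshold = as.integer(edge_threshold), null = null,
                 side = side, zero_sd_classes = names(counts)[sg == 0]),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("motif census (%s side, threshold >= %d, %d %s shuffles)\n",
              x$side, x$edge_threshold, x$n_shuffles, x$null))
  tab <- data.frame(code = names(x$counts), count = as.integer(x$counts),
                    z = round(x$z_scores, 2), nsp = round(x$nsp, 3))
  print(tab[tab$count > 0 | abs(tab$z) > 0, ], row.names = FALSE)
  invisible(x)
}
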