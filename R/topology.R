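# Subcellular synaptic topology: synapse-to-skeleton assignment, axon
# initial segment detection, geodesic distance distributions by input class,
# the proximal-bias permutation test, and the two dendrogram layouts.

skeleton_children <- function(skel) {
  nd <- skel$nodes
  pi_ <- match(nd$parent_id, nd$node_id)
  ch <- vector("list", nrow(nd))
  for (i in which(!is.na(pi_))) ch[[pi_[i]]] <- c(ch[[pi_[i]]], i)
  ch
}

edge_lengths <- function(skel) {
  nd <- skel$nodes
  pi_ <- match(nd$parent_id, nd$node_id)
  ifelse(is.na(pi_), 0,
         sqrt((nd$x - nd$x[pi_])^2 + (nd$y - nd$y[pi_])^2 +
              (nd$z - nd$z[pi_])^2))
}

#' Geodesic (cable) distances from a node
#'
#' Distance along the unique tree path, summing Euclidean parent-edge
#' lengths. `distance(from_node) == 0`; the tree metric is symmetric.
#'
#' @param skel a [skeleton()] object.
#' @param from_node node id to measure from.
#' @return named numeric vector of distances, one per node.
#' @export
geodesic_distances <- function(skel, from_node) {
  nd <- skel$nodes
  start <- match(from_node, nd$node_id)
  if (is.na(start)) stop("unknown node id: ", from_node)
  pi_ <- match(nd$parent_id, nd$node_id)
  elen <- edge_lengths(skel)
  ch <- skeleton_children(skel)
  n <- nrow(nd)
  dist <- rep(NA_real_, n)
  dist[start] <- 0
  # traverse the tree as an undirected graph from the start node
  stack <- start
  while (length(stack) > 0L) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- c(ch[[i]], pi_[i])
    for (j in nb) {
      if (!is.na(j) && is.na(dist[j])) {
        w <- if (!is.na(pi_[j]) && pi_[j] == i) elen[j] else elen[i]
        dist[j] <- dist[i] + w
        stack <- c(stack, j)
      }
    }
  }
  stats::setNames(dist, nd$node_id)
}

#' Assign synaptic sites to skeleton nodes
#'
#' Maps each site to the nearest skeleton node by Euclidean distance (ties
#' broken toward the lower node id); the assignment distance is recorded and
#' sites beyond `outlier_radius` are flagged.
#'
#' @param skel a [skeleton()] object.
#' @param sites data.frame with columns `x`, `y`, `z` and optionally
#'   `polarity` (`"pre"`/`"post"`), `partner_id`, `class`.
#' @param outlier_radius flag assignments farther than this (default `Inf`).
#' @return list of class `annotated_skeleton`: `skeleton`, `synapses`
#'   (sites plus `node_id`, `assign_dist`, `outlier`), `ais_node` (`NA`
#'   until [detect_ais()] is run).
#' @export
assign_synapses <- function(skel, sites, outlier_radius = Inf) {
  nd <- skel$nodes
  pts <- as.matrix(nd[, c("x", "y", "z")])
  q <- as.matrix(sites[, c("x", "y", "z")])
  kk <- min(nrow(pts), 8L)
  nn <- RANN::nn2(pts, q, k = kk)
  node_id <- integer(nrow(q))
  dist <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    d0 <- nn$nn.dists[i, 1L]
    tied <- nn$nn.idx[i, nn$nn.dists[i, ] <= d0 + 1e-9]
    node_id[i] <- min(nd$node_id[tied])
    dist[i] <- d0
  }
  syn <- cbind(as.data.frame(sites), node_id = node_id, assign_dist = dist,
               outlier = dist > outlier_radius)
  if (is.null(syn$polarity)) syn$polarity <- "post"
  if (is.null(syn$class)) syn$class <- "all"
  structure(list(skeleton = skel, synapses = syn, ais_node = NA_integer_),
            class = "annotated_skeleton")
}

primary_neurite <- function(skel) {
  d <- geodesic_distances(skel, skel$root)
  deepest <- skel$nodes$node_id[which.max(d)]
  # path from deepest back to root
  nd <- skel$nodes
  path <- integer(0)
  cur <- match(deepest, nd$node_id)
  while (!is.na(cur)) {
    path <- c(nd$node_id[cur], path)
    cur <- match(nd$parent_id[cur], nd$node_id)
  }
  path
}

subtree_nodes <- function(skel, root_idx) {
  ch <- skeleton_children(skel)
  out <- integer(0)
  stack <- root_idx
  while (length(stack) > 0L) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, i)
    stack <- c(stack, ch[[i]])
  }
  out
}

#' Detect the putative axon initial segment
#'
#' Takes the primary neurite as the root-to-deepest path by cable length and
#' walks its branch points outward from the root; returns the first branch
#' point whose off-primary subtree is dominated by pre-synaptic sites
#' (fraction >= `min_pre_fraction`) and carries at least `min_pre_share` of
#' the neuron's pre-synaptic sites — i.e. the branch point where the axonal
#' process leaves the primary process. This is a heuristic operationalisation
#' of the spike-initiation-site convention and is flagged as such.
#'
#' @param annotated an `annotated_skeleton` from [assign_synapses()].
#' @param min_pre_fraction minimum pre-synaptic fraction in the off-primary
#'   subtree (default 0.8).
#' @param min_pre_share minimum share of all pre-synaptic sites the subtree
#'   must hold (default 0.1).
#' @return the `annotated_skeleton` with `ais_node` set (or `NA` when no
#'   branch point qualifies) and a `ais_diagnostics` element.
#' @export
detect_ais <- function(annotated, min_pre_fraction = 0.8,
                       min_pre_share = 0.1) {
  skel <- annotated$skeleton
  syn <- annotated$synapses
  nd <- skel$nodes
  total_pre <- sum(syn$polarity == "pre")
  if (total_pre == 0L) {
    annotated$ais_node <- NA_integer_
    annotated$ais_diagnostics <- list(reason = "no pre-synaptic sites")
    return(annotated)
  }
  prim <- primary_neurite(skel)
  ch <- skeleton_children(skel)
  checked <- list()
  for (node in prim) {
    i <- match(node, nd$node_id)
    off <- setdiff(nd$node_id[ch[[i]]], prim)
    if (length(off) == 0L) next  # not a branch point off the primary neurite
    sub_ids <- nd$node_id[unlist(lapply(match(off, nd$node_id),
                                        function(r) subtree_nodes(skel, r)))]
    s <- syn[syn$node_id %in% sub_ids, , drop = FALSE]
    if (nrow(s) == 0L) next
    frac <- mean(s$polarity == "pre")
    share <- sum(s$polarity == "pre") / total_pre
    checked[[length(checked) + 1L]] <- data.frame(
      node = node, pre_fraction = frac, pre_share = share)
    if (frac >= min_pre_fraction && share >= min_pre_share) {
      annotated$ais_node <- node
      annotated$ais_diagnostics <- list(
        pre_fraction = frac, pre_share = share, heuristic = TRUE,
        candidates = do.call(rbind, checked))
      return(annotated)
    }
  }
  annotated$ais_node <- NA_integer_
  annotated$ais_diagnostics <- list(
    reason = "no qualifying branch point", heuristic = TRUE,
    candidates = if (length(checked)) do.call(rbind, checked) else NULL)
  annotated
}

#' Geodesic distance distributions of synapses by class
#'
#' Distances from a reference node (the detected axon initial segment, the
#' root, or any named node) to every synapse's assigned node, split by
#' grouping columns. Raw distances are always retained; binning is left to
#' the caller.
#'
#' @param annotated an `annotated_skeleton`.
#' @param reference `"ais"`, `"root"`, or a node id.
#' @param group_by columns of the synapse table to group by (default
#'   `c("class", "polarity")`).
#' @param unit distance unit of the skeleton coordinates, recorded in the
#'   output (default `"nm"`; reporting in micrometres or millimetres is a
#'   presentation choice, so nothing is hard-coded).
#' @return data.frame `group` columns + `distance`, with attributes
#'   `reference_node` and `unit`; empty groups are simply absent.
#' @export
class_distance_distributions <- function(annotated, reference = "ais",
                                         group_by = c("class", "polarity"),
                                         unit = "nm") {
  skel <- annotated$skeleton
  ref_node <- if (identical(reference, "ais")) {
    if (is.na(annotated$ais_node)) {
      stop("no AIS detected; run detect_ais() or pass reference = 'root' or a node id")
    }
    annotated$ais_node
  } else if (identical(reference, "root")) {
    skel$root
  } else {
    as.integer(reference)
  }
  d <- geodesic_distances(skel, ref_node)
  syn <- annotated$synapses
  out <- syn[, group_by, drop = FALSE]
  out$distance <- unname(d[as.character(syn$node_id)])
  attr(out, "reference_node") <- ref_node
  attr(out, "unit") <- unit
  out
}

#' Permutation test for proximal synapse-placement bias
#'
#' Statistic: `median(a) - median(b)` of the two geodesic distance samples;
#' a negative value means class `a` sits more proximally. The two-sided
#' p-value comes from permuting class labels over the pooled distances.
#'
#' @param dist_a,dist_b numeric distance vectors (non-empty).
#' @param n_permutations default 10000.
#' @param seed integer seed.
#' @return list of class `proximal_bias_test`: `statistic`, `p_value`,
#'   `direction`, `n_permutations`.
#' @export
proximal_bias_test <- function(dist_a, dist_b, n_permutations = 10000L,
                               seed = 1L) {
  stopifnot(length(dist_a) > 0L, length(dist_b) > 0L)
  obs <- stats::median(dist_a) - stats::median(dist_b)
  pooled <- c(dist_a, dist_b)
  na <- length(dist_a)
  n <- length(pooled)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, na)
      abs(stats::median(pooled[idx]) - stats::median(pooled[-idx])) >= abs(obs) - 1e-12
    }, NA))
  })
  p <- (1 + exceed) / (n_permutations + 1)
  structure(list(statistic = obs, p_value = p,
                 direction = if (obs < 0) "a_proximal" else if (obs > 0)
                   "b_proximal" else "none",
                 n_permutations = as.integer(n_permutations)),
            class = "proximal_bias_test")
}

#' Force-directed (spring-electrical) dendrogram layout
#'
#' Lays out the skeleton graph in 2-D under the spring-electrical model:
#' a repulsive force between every vertex pair inversely proportional to
#' their distance, and an attractive force between neighbours proportional
#' to the squared distance. Positions descend the model's system energy
#' (sum of squared net force magnitudes); a step is accepted only if energy
#' decreases, with the step size halved otherwise, so the recorded energy
#' trace is non-increasing.
#'
#' @param skel a [skeleton()] object (or any igraph-coercible `conn_graph`).
#' @param iterations maximum accepted/attempted iterations (default 300).
#' @param seed integer seed for the initial placement.
#' @param c_rep,c_att repulsion/attraction constants.
#' @param step0 initial step size.
#' @return list of class `sfdp_layout`: `coords` (n x 2, rownames = node
#'   ids), `energy` (trace over accepted steps), `converged`.
#' @export
sfdp_layout <- function(skel, iterations = 300L, seed = 1L,
                        c_rep = 1, c_att = 1, step0 = 0.1) {
  nd <- skel$nodes
  n <- nrow(nd)
  pi_ <- match(nd$parent_id, nd$node_id)
  edges <- cbind(which(!is.na(pi_)), pi_[!is.na(pi_)])
  forces <- function(x) {
    dx <- outer(x[, 1], x[, 1], "-")
    dy <- outer(x[, 2], x[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-9] <- 1e-9
    # repulsion: c_rep / d along the unit vector away from every other vertex
    inv <- c_rep / d^2  # (1/d) * (1/d) for the unit direction
    diag(inv) <- 0
    fx <- rowSums(inv * dx)
    fy <- rowSums(inv * dy)
    # attraction: c_att * d^2 along the unit vector toward each neighbour
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      dd <- d[i, j]
      ux <- (x[j, 1] - x[i, 1]) / dd
      uy <- (x[j, 2] - x[i, 2]) / dd
      f <- c_att * dd^2
      fx[i] <- fx[i] + f * ux; fy[i] <- fy[i] + f * uy
      fx[j] <- fx[j] - f * ux; fy[j] <- fy[j] - f * uy
    }
    cbind(fx, fy)
  }
  energy <- function(f) sum(f^2)
  x <- with_seed(seed, matrix(stats::runif(2 * n, -1, 1), n, 2L))
  f <- forces(x)
  e <- energy(f)
  trace <- e
  step <- step0
  converged <- FALSE
  for (it in seq_len(iterations)) {
    fn <- sqrt(rowSums(f^2))
    dirn <- f / pmax(fn, 1e-12)
    x_new <- x + step * dirn * pmin(fn, 1)  # capped displacement
    f_new <- forces(x_new)
    e_new <- energy(f_new)
    if (e_new < e) {
      x <- x_new; f <- f_new; e <- e_new
      trace <- c(trace, e)
      step <- step * 1.1
    } else {
      step <- step / 2
    }
    if (step < 1e-8) { converged <- TRUE; break }
  }
  rownames(x) <- nd$node_id
  structure(list(coords = x, energy = trace, converged = converged),
            class = "sfdp_layout")
}

#' Ranked (layered) dendrogram layout
#'
#' Assigns each node a vertical rank — its topological depth from the root,
#' or its root geodesic distance quantised by `rank_step` — splits any edge
#' spanning more than one rank with virtual nodes, and orders nodes within
#' ranks by iterated barycenter sweeps to reduce edge crossings.
#'
#' @param skel a [skeleton()] object (whole skeleton or subtree).
#' @param rank_by `"depth"` (topological) or `"cable"` (geodesic, quantised).
#' @param rank_step rank height in cable units when `rank_by = "cable"`.
#' @param sweeps barycenter sweep iterations (default 4).
#' @return list of class `ranked_layout`: `coords` (data.frame `node_id`,
#'   `x`, `rank`, `virtual`), `crossings`, `n_virtual`.
#' @export
ranked_layout <- function(skel, rank_by = c("depth", "cable"),
                          rank_step = NULL, sweeps = 4L) {
  rank_by <- match.arg(rank_by)
  nd <- skel$nodes
  pi_ <- match(nd$parent_id, nd$node_id)
  if (rank_by == "depth") {
    rank <- rep(NA_integer_, nrow(nd))
    rank[is.na(pi_)] <- 0L
    repeat {
      todo <- which(is.na(rank) & !is.na(rank[pi_]))
      if (length(todo) == 0L) break
      rank[todo] <- rank[pi_[todo]] + 1L
    }
  } else {
    d <- geodesic_distances(skel, skel$root)
    if (is.null(rank_step)) rank_step <- max(d) / 10
    rank <- as.integer(round(d / rank_step))
    # a child must sit strictly below its parent for the layering to be valid
    repeat {
      bad <- which(!is.na(pi_) & rank <= rank[pi_])
      if (length(bad) == 0L) break
      rank[bad] <- rank[pi_[bad]] + 1L
    }
  }
  # build layered node table; split multi-rank edges with virtual nodes
  nodes <- data.frame(id = as.character(nd$node_id), rank = rank,
                      virtual = FALSE, stringsAsFactors = FALSE)
  edges <- list()
  n_virtual <- 0L
  vid <- 0L
  for (i in which(!is.na(pi_))) {
    span <- rank[i] - rank[pi_[i]]
    chain <- as.character(nd$node_id[pi_[i]])
    if (span > 1L) {
      for (r in seq(rank[pi_[i]] + 1L, rank[i] - 1L)) {
        vid <- vid + 1L
        v <- paste0("v", vid)
        nodes <- rbind(nodes, data.frame(id = v, rank = r, virtual = TRUE))
        chain <- c(chain, v)
        n_virtual <- n_virtual + 1L
      }
    }
    chain <- c(chain, as.character(nd$node_id[i]))
    for (j in seq_len(length(chain) - 1L)) {
      edges[[length(edges) + 1L]] <- c(chain[j], chain[j + 1L])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(), 0, 2)
  # initial x order: by id within rank; then barycenter sweeps
  ord <- stats::setNames(stats::ave(seq_len(nrow(nodes)), nodes$rank,
                                    FUN = seq_along), nodes$id)
  ranks <- sort(unique(nodes$rank))
  neighbor_mean <- function(id, upper) {
    nb <- c(edges[edges[, 2] == id, 1], edges[edges[, 1] == id, 2])
    nbr <- nodes$rank[match(nb, nodes$id)]
    nb <- nb[if (upper) nbr < nodes$rank[match(id, nodes$id)] else
      nbr > nodes$rank[match(id, nodes$id)]]
    if (length(nb) == 0L) return(NA_real_)
    mean(ord[nb])
  }
  for (s in seq_len(sweeps)) {
    down <- s %% 2L == 1L
    for (r in if (down) ranks else rev(ranks)) {
      ids <- nodes$id[nodes$rank == r]
      bc <- vapply(ids, neighbor_mean, 0, upper = down)
      bc[is.na(bc)] <- ord[ids][is.na(bc)]
      ord[ids] <- rank(bc, ties.method = "first")
    }
  }
  # count crossings between consecutive ranks
  crossings <- 0L
  for (ri in seq_len(length(ranks) - 1L)) {
    sel <- nodes$rank[match(edges[, 1], nodes$id)] == ranks[ri] &
      nodes$rank[match(edges[, 2], nodes$id)] == ranks[ri + 1L]
    ee <- edges[sel, , drop = FALSE]
    if (nrow(ee) < 2L) next
    a <- ord[ee[, 1]]; b <- ord[ee[, 2]]
    for (i in seq_len(nrow(ee) - 1L)) {
      for (j in seq(i + 1L, nrow(ee))) {
        if ((a[i] - a[j]) * (b[i] - b[j]) < 0) crossings <- crossings + 1L
      }
    }
  }
  structure(list(
    coords = data.frame(node_id = nodes$id, x = unname(ord[nodes$id]),
                        rank = nodes$rank, virtual = nodes$virtual,
                        stringsAsFactors = FALSE),
    crossings = crossings, n_virtual = n_virtual),
    class = "ranked_layout")
}
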