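# ---- synapse tables ---------------------------------------------------------

#' Default column mapping for synapse tables
#'
#' Synapse-table exports differ between connectome releases, so the reader is
#' configured with a mapping from the package's canonical field names to the
#' column names present in the file.
#'
#' @param pre_id,post_id,x,y,z,region,side column names in the file. `side`
#'   may be `NULL` if the file carries no hemisphere column.
#' @return named list usable as the `dialect` argument of
#'   [read_synapse_table()].
#' @export
synapse_dialect <- function(pre_id = "pre_id", post_id = "post_id",
                            x = "x", y = "y", z = "z",
                            region = "region", side = NULL) {
  list(pre_id = pre_id, post_id = post_id, x = x, y = y, z = z,
       region = region, side = side)
}

#' Read a synapse table
#'
#' Reads a CSV with one row per synaptic site (pre-synaptic neuron,
#' post-synaptic neuron, 3-D position in nanometres, neuropil label) into the
#' package's canonical layout.
#'
#' @param path path to a CSV file.
#' @param dialect column-name mapping from [synapse_dialect()].
#' @return a `data.frame` of class `synapse_table` with columns
#'   `pre_id`, `post_id`, `x`, `y`, `z`, `region`, `side`.
#' @export
read_synapse_table <- function(path, dialect = synapse_dialect()) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- dialect[!vapply(dialect, is.null, logical(1))]
  missing <- setdiff(unlist(needed), names(raw))
  if (length(missing) > 0L) {
    stop("synapse table is missing mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    pre_id  = as.character(raw[[dialect$pre_id]]),
    post_id = as.character(raw[[dialect$post_id]]),
    x = as.numeric(raw[[dialect$x]]),
    y = as.numeric(raw[[dialect$y]]),
    z = as.numeric(raw[[dialect$z]]),
    region = as.character(raw[[dialect$region]]),
    side = if (is.null(dialect$side)) "unknown" else as.character(raw[[dialect$side]]),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))
  if (length(bad) > 0L) {
    stop("unparseable position in synapse table row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("synapse_table", "data.frame")
  out
}

#' Write a synapse table
#'
#' Emits the canonical CSV layout with a header and deterministic row order
#' (sorted by pre id, post id, then position).
#'
#' @param sites a `synapse_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synapse_table <- function(sites, path) {
  ord <- order(sites$pre_id, sites$post_id, sites$x, sites$y, sites$z)
  out <- as.data.frame(sites)[ord, , drop = FALSE]
  # full-precision coordinates so a write/read cycle is lossless
  for (col in c("x", "y", "z")) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- skeletons (SWC) --------------------------------------------------------

#' Construct a skeleton object
#'
#' A skeleton is a rooted tree of 3-D nodes (SWC-compatible). Validates the
#' tree invariants: exactly one root, parent pointers acyclic, all nodes
#' reachable from the root.
#'
#' @param nodes data.frame with columns `node_id`, `parent_id` (`NA` for the
#'   root), `x`, `y`, `z` (nanometres), `radius`.
#' @param neuron_id identifier of the neuron the skeleton belongs to.
#' @return an object of class `skeleton`.
#' @export
skeleton <- function(nodes, neuron_id = NA_character_) {
  stopifnot(all(c("node_id", "parent_id", "x", "y", "z", "radius") %in% names(nodes)))
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids in skeleton")
  roots <- nodes$node_id[is.na(nodes$parent_id)]
  if (length(roots) == 0L) stop("skeleton has no root (no parent = -1 row)")
  if (length(roots) > 1L) {
    stop("skeleton has multiple roots: ", paste(roots, collapse = ", "))
  }
  orphan <- setdiff(stats::na.omit(nodes$parent_id), nodes$node_id)
  if (length(orphan) > 0L) {
    stop("parent reference(s) to missing node(s): ", paste(orphan, collapse = ", "))
  }
  # reachability from root (also catches cycles: unreachable strongly
  # connected parent loops)
  idx <- match(nodes$parent_id, nodes$node_id)
  n <- nrow(nodes)
  reached <- logical(n)
  reached[is.na(idx)] <- TRUE
  repeat {
    newly <- !reached & reached[idx]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    reached[newly] <- TRUE
  }
  if (!all(reached)) {
    stop("skeleton contains cycle or disconnected node(s): ",
         paste(nodes$node_id[!reached], collapse = ", "))
  }
  structure(list(nodes = nodes, root = roots, neuron_id = neuron_id),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton '%s': %d nodes, root %d, cable length %.1f\n",
              x$neuron_id, nrow(x$nodes), x$root, total_cable_length(x)))
  invisible(x)
}

#' Read an SWC skeleton file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, parent `-1` at the
#' root). Node order in the file is preserved.
#'
#' @param path path to an SWC file.
#' @param neuron_id identifier to attach; defaults to the file name.
#' @return a [skeleton()] object.
#' @export
read_swc <- function(path, neuron_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(neuron_id)) neuron_id <- sub("\\.swc$", "", basename(path))
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("node_id", "type", "x", "y", "z",
                                         "radius", "parent_id"))
  tab$parent_id[tab$parent_id == -1] <- NA_integer_
  skeleton(tab[, c("node_id", "parent_id", "x", "y", "z", "radius")],
           neuron_id = neuron_id)
}

#' Write a skeleton to SWC
#'
#' @param skel a [skeleton()] object.
#' @param path output path.
#' @param type SWC structure-type code written for every node (default 0,
#'   undefined).
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path, type = 0L) {
  nd <- skel$nodes
  parent <- ifelse(is.na(nd$parent_id), -1L, nd$parent_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                     nd$node_id, type, nd$x, nd$y, nd$z, nd$radius, parent),
             con)
  invisible(path)
}

#' Total cable length of a skeleton
#'
#' Sum of Euclidean parent-edge lengths, in the skeleton's coordinate unit.
#'
#' @param skel a [skeleton()] object.
#' @return non-negative scalar.
#' @export
total_cable_length <- function(skel) {
  nd <- skel$nodes
  pi_ <- match(nd$parent_id, nd$node_id)
  has <- !is.na(pi_)
  sum(sqrt((nd$x[has] - nd$x[pi_[has]])^2 +
           (nd$y[has] - nd$y[pi_[has]])^2 +
           (nd$z[has] - nd$z[pi_[has]])^2))
}

# ---- connectivity graphs ----------------------------------------------------

#' Build a thresholded connectivity graph from synapse sites
#'
#' Edge weight is the number of post-synaptic sites between an ordered neuron
#' pair. Connections weaker than `min_synapses` are removed; reported
#' connectome analyses conventionally drop single-synapse connections as
#' spurious, so thresholding is first-class and the applied value is recorded
#' on the object.
#'
#' @param sites a `synapse_table` (or any data.frame with `pre_id`/`post_id`).
#' @param min_synapses integer >= 1; minimum synapse count per retained edge.
#' @return an object of class `conn_graph`: list with `edges`
#'   (data.frame `pre`, `post`, `weight`), `nodes` (character vector) and
#'   `threshold_applied`.
#' @export
build_connectivity <- function(sites, min_synapses = 1L) {
  stopifnot(min_synapses >= 1L)
  if (nrow(sites) == 0L) {
    return(conn_graph(data.frame(pre = character(), post = character(),
                                 weight = integer()),
                      nodes = character(), threshold = min_synapses))
  }
  key <- paste(sites$pre_id, sites$post_id, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  edges <- data.frame(pre = vapply(parts, `[`, "", 1L),
                      post = vapply(parts, `[`, "", 2L),
                      weight = as.integer(tab),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$weight >= min_synapses, , drop = FALSE]
  nodes <- sort(unique(c(sites$pre_id, sites$post_id)))
  conn_graph(edges, nodes = nodes, threshold = as.integer(min_synapses))
}

#' Construct a connectivity graph from an edge list
#'
#' @param edges data.frame with columns `pre`, `post`, `weight`.
#' @param nodes node id vector; defaults to the ids appearing in `edges`.
#' @param threshold the minimum-synapse threshold already applied.
#' @return a `conn_graph` object.
#' @export
conn_graph <- function(edges, nodes = NULL, threshold = 1L) {
  stopifnot(all(c("pre", "post", "weight") %in% names(edges)))
  edges$pre <- as.character(edges$pre)
  edges$post <- as.character(edges$post)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$weight < threshold)) {
    edges <- edges[edges$weight >= threshold, , drop = FALSE]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$pre, edges$post)))
  ord <- order(edges$pre, edges$post)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = as.character(nodes),
                 threshold_applied = as.integer(threshold)),
            class = "conn_graph")
}

#' @export
print.conn_graph <- function(x, ...) {
  cat(sprintf("conn_graph: %d nodes, %d edges (threshold >= %d synapses)\n",
              length(x$nodes), nrow(x$edges), x$threshold_applied))
  invisible(x)
}

#' Re-threshold a connectivity graph
#'
#' @param graph a `conn_graph`.
#' @param min_synapses new minimum edge weight (>= the current threshold to be
#'   meaningful; lowering cannot recover removed edges).
#' @return a new `conn_graph`.
#' @export
threshold_graph <- function(graph, min_synapses) {
  conn_graph(graph$edges[graph$edges$weight >= min_synapses, , drop = FALSE],
             nodes = graph$nodes, threshold = as.integer(min_synapses))
}

#' Convert a connectivity graph to igraph
#'
#' @param graph a `conn_graph`.
#' @return a weighted directed [igraph::graph].
#' @export
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("pre", "post", "weight")],
    directed = TRUE, vertices = data.frame(name = graph$nodes))
  igraph::E(g)$weight <- graph$edges$weight
  g
}

#' Read / write weighted edge lists
#'
#' CSV with header `pre_id,post_id,weight`, rows sorted by pre then post id.
#'
#' @param path file path.
#' @param threshold threshold recorded on the returned graph.
#' @return [read_edge_list()] returns a `conn_graph`.
#' @export
read_edge_list <- function(path, threshold = 1L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pre_id", "post_id", "weight") %in% names(tab)))
  conn_graph(data.frame(pre = tab$pre_id, post = tab$post_id,
                        weight = tab$weight, stringsAsFactors = FALSE),
             threshold = threshold)
}

#' @param graph a `conn_graph` to write.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(graph, path) {
  out <- data.frame(pre_id = graph$edges$pre, post_id = graph$edges$post,
                    weight = graph$edges$weight)
  utils::write.csv(out[order(out$pre_id, out$post_id), ], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write neuron metadata tables
#'
#' CSV with columns `id`, `hemisphere`, `cell_type`, `transmitter`, `n_pre`,
#' `n_post`. Unknown enum values are normalised to `"unknown"`.
#'
#' @param path file path.
#' @return a data.frame of neuron metadata.
#' @export
read_neuron_metadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "n_pre", "n_post") %in% names(tab)))
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) stop("duplicate neuron ids in metadata")
  for (col in c("hemisphere", "cell_type", "transmitter")) {
    if (is.null(tab[[col]])) tab[[col]] <- ""
  }
  hs <- c("left", "right", "unknown")
  tab$hemisphere[!tab$hemisphere %in% hs] <- "unknown"
  tr <- c("acetylcholine", "glutamate", "GABA", "dopamine", "serotonin",
          "octopamine", "unknown")
  tab$transmitter[!tab$transmitter %in% tr] <- "unknown"
  stopifnot(all(tab$n_pre >= 0), all(tab$n_post >= 0))
  tab
}

#' @param meta metadata data.frame to write.
#' @rdname read_neuron_metadata
#' @export
write_neuron_metadata <- function(meta, path) {
  utils::write.csv(meta[order(meta$id), ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default region vocabulary
#'
#' The default region-of-interest is the superior protocerebrum, taken as the
#' union of the SMP, SIP, SLP and CRE neuropils; CRE is included because it is
#' as heavily wired into the superior neuropils as they are into each other.
#'
#' @return character vector of neuropil labels making up the default region.
#' @export
sp_region <- function() c("SMP", "SIP", "SLP", "CRE")
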