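# NBLAST-style morphological similarity: dotprops representation, raw
# pairwise scores, self-normalisation and symmetrisation, ensemble
# identification from connectivity clusters, and cross-dataset ensemble
# matching by the mean - sd threshold.

#' Convert a skeleton to a dotprops representation
#'
#' Points are the skeleton node positions (optionally resampled to a fixed
#' spacing along edges first); the tangent at each point is the principal
#' axis of its `k` nearest points (including itself), unit-normalised.
#' Tangent sign is meaningless downstream (scores use the absolute dot
#' product). Degenerate neighbourhoods (coincident points) fall back to the
#' parent-edge direction.
#'
#' @param skel a [skeleton()] object.
#' @param k neighbour count for tangent estimation (default 5).
#' @param resample_step optional spacing (same unit as coordinates) to
#'   resample points along edges before tangent estimation.
#' @return list of class `dotprops`: `points` (n x 3), `tangents` (n x 3,
#'   unit rows), `k_used`, `neuron_id`.
#' @export
make_dotprops <- function(skel, k = 5L, resample_step = NULL) {
  nd <- skel$nodes
  if (!is.null(resample_step)) {
    pts <- resample_points(skel, resample_step)
    par_dir <- NULL
  } else {
    pts <- as.matrix(nd[, c("x", "y", "z")])
    pi_ <- match(nd$parent_id, nd$node_id)
    par_dir <- pts - pts[ifelse(is.na(pi_), seq_len(nrow(pts)), pi_), , drop = FALSE]
  }
  n <- nrow(pts)
  if (n < k + 1L) stop("need at least k + 1 = ", k + 1L, " points, got ", n)
  nn <- RANN::nn2(pts, pts, k = k)
  tangents <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    nb <- pts[nn$nn.idx[i, ], , drop = FALSE]
    cc <- sweep(nb, 2L, colMeans(nb))
    cv <- crossprod(cc)
    if (sum(abs(cv)) < 1e-12) {
      v <- if (!is.null(par_dir)) par_dir[i, ] else c(1, 0, 0)
      if (sum(abs(v)) < 1e-12) v <- c(1, 0, 0)
    } else {
      v <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
    }
    tangents[i, ] <- v / sqrt(sum(v^2))
  }
  structure(list(points = pts, tangents = tangents, k_used = as.integer(k),
                 neuron_id = skel$neuron_id), class = "dotprops")
}

# point cloud resampled at fixed spacing along each parent edge
resample_points <- function(skel, spacing) {
  nd <- skel$nodes
  pi_ <- match(nd$parent_id, nd$node_id)
  pts <- list(as.matrix(nd[is.na(pi_), c("x", "y", "z"), drop = FALSE]))
  for (i in which(!is.na(pi_))) {
    a <- as.numeric(nd[pi_[i], c("x", "y", "z")])
    b <- as.numeric(nd[i, c("x", "y", "z")])
    len <- sqrt(sum((b - a)^2))
    m <- max(1L, ceiling(len / spacing))
    tt <- seq_len(m) / m
    pts[[length(pts) + 1L]] <- cbind(a[1] + tt * (b[1] - a[1]),
                                     a[2] + tt * (b[2] - a[2]),
                                     a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, pts)
}

#' Default smooth scoring function
#'
#' A synthetic surrogate for a trained log-odds score table:
#' `f(d, a) = a * exp(-d / sigma) - lambda`, maximised at zero distance and
#' parallel tangents. Trained `log2(p_match / p_rand)` tables can be loaded
#' with [read_score_table()] instead.
#'
#' @param sigma distance decay constant, in the coordinate unit (default
#'   2000, i.e. 2 micrometres for nanometre skeletons).
#' @param lambda constant offset penalising unmatched structure.
#' @return a function `f(dist, absdot)` of class `score_function`.
#' @export
score_function_default <- function(sigma = 2000, lambda = 0.1) {
  f <- function(d, a) a * exp(-d / sigma) - lambda
  structure(f, sigma = sigma, lambda = lambda, class = c("score_function",
                                                         "function"))
}

#' Read a tabulated scoring function
#'
#' Plain-text matrix: first row the |dot|-bin upper edges, first column the
#' distance-bin upper edges, body the scores. Lookup is by bin (values above
#' the last edge clamp to the last bin).
#'
#' @param path path to the score-table file (whitespace-separated).
#' @return a function `f(dist, absdot)` of class `score_function`.
#' @export
read_score_table <- function(path) {
  tab <- as.matrix(utils::read.table(path))
  dot_edges <- as.numeric(tab[1, -1])
  dist_edges <- as.numeric(tab[-1, 1])
  values <- unname(tab[-1, -1, drop = FALSE])
  f <- function(d, a) {
    di <- pmin(findInterval(d, dist_edges, left.open = TRUE) + 1L,
               length(dist_edges))
    ai <- pmin(findInterval(a, dot_edges, left.open = TRUE) + 1L,
               length(dot_edges))
    values[cbind(di, ai)]
  }
  structure(f, table = values, dist_edges = dist_edges, dot_edges = dot_edges,
            class = c("score_function", "function"))
}

#' Raw NBLAST score of a query against a target
#'
#' For each query point, finds the nearest target point by Euclidean
#' distance and accumulates `f(d_i, |u_i . v_i|)` over query points.
#' Asymmetric in general.
#'
#' @param query,target `dotprops` objects.
#' @param score_fn a `score_function` (default [score_function_default()]).
#' @return raw score (numeric scalar).
#' @export
nblast_raw <- function(query, target, score_fn = score_function_default()) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"))
  nn <- RANN::nn2(target$points, query$points, k = 1L)
  idx <- nn$nn.idx[, 1L]
  d <- nn$nn.dists[, 1L]
  adot <- abs(rowSums(query$tangents * target$tangents[idx, , drop = FALSE]))
  sum(score_fn(d, pmin(adot, 1)))
}

#' Normalised, symmetrised similarity matrix over a set of neurons
#'
#' Computes raw scores for all ordered pairs, normalises each by the query's
#' self-score (`normalized(a, b) = S(a, b) / S(a, a)`), and symmetrises by
#' averaging `normalized(a, b)` and `normalized(b, a)`. The diagonal is
#' exactly 1. Neurons with non-positive self-score are flagged and their
#' rows/columns set to `NA`.
#'
#' @param dotprops_list named list of `dotprops`.
#' @param score_fn a `score_function`.
#' @return similarity matrix with attribute `flagged` (ids with non-positive
#'   self-score).
#' @export
nblast_matrix <- function(dotprops_list, score_fn = score_function_default()) {
  n <- length(dotprops_list)
  stopifnot(n >= 2L)
  ids <- names(dotprops_list)
  if (is.null(ids)) ids <- vapply(dotprops_list, function(d) d$neuron_id, "")
  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      raw[i, j] <- nblast_raw(dotprops_list[[i]], dotprops_list[[j]], score_fn)
    }
  }
  self <- diag(raw)
  flagged <- ids[self <= 0]
  norm <- raw / self  # row-wise: S(a, b) / S(a, a)
  sym <- (norm + t(norm)) / 2
  diag(sym) <- 1
  if (length(flagged) > 0L) {
    sym[ids %in% flagged, ] <- NA_real_
    sym[, ids %in% flagged] <- NA_real_
  }
  attr(sym, "flagged") <- flagged
  sym
}

#' Identify morphology-backed ensembles among connectivity clusters
#'
#' For each connectivity cluster, compares the intra-cluster pairwise
#' similarities against the similarities between cluster members and all
#' other neurons (self-pairs excluded) with a two-sample t-test; clusters
#' whose intra-cluster similarity is significantly higher are accepted as
#' ensembles. Singleton clusters are skipped and flagged.
#'
#' @param labels named integer vector of cluster labels (names = neuron ids
#'   matching the similarity matrix).
#' @param sim symmetric similarity matrix from [nblast_matrix()].
#' @param alpha significance level (default 0.05).
#' @return data.frame `cluster`, `n`, `mean_intra`, `mean_inter`, `p_value`,
#'   `accepted`, `skipped`.
#' @export
identify_ensembles <- function(labels, sim, alpha = 0.05) {
  ids <- names(labels)
  stopifnot(!is.null(ids), all(ids %in% rownames(sim)))
  sim <- sim[ids, ids]
  out <- lapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    if (length(members) < 2L) {
      return(data.frame(cluster = cl, n = length(members),
                        mean_intra = NA_real_, mean_inter = NA_real_,
                        p_value = NA_real_, accepted = FALSE, skipped = TRUE))
    }
    intra_m <- sim[members, members]
    intra <- intra_m[upper.tri(intra_m)]
    inter <- as.numeric(sim[members, -members])
    if (length(intra) < 2L || length(inter) < 2L) {
      return(data.frame(cluster = cl, n = length(members),
                        mean_intra = mean(intra), mean_inter = mean(inter),
                        p_value = NA_real_, accepted = FALSE, skipped = TRUE))
    }
    p <- if (stats::sd(c(intra, inter)) == 0) 1 else {
      stats::t.test(intra, inter)$p.value
    }
    data.frame(cluster = cl, n = length(members),
               mean_intra = mean(intra), mean_inter = mean(inter),
               p_value = p,
               accepted = p < alpha && mean(intra) > mean(inter),
               skipped = FALSE)
  })
  do.call(rbind, out)
}

#' Match query neurons to reference ensembles across datasets
#'
#' Each reference ensemble's morphological threshold is the mean minus one
#' standard deviation of its intra-ensemble pairwise similarities (sd = 0 is
#' flagged; the threshold is then the mean). A query neuron joins an ensemble
#' when its mean similarity to the ensemble members reaches the threshold.
#'
#' @param ensembles named list: ensemble id -> character vector of reference
#'   member ids (each >= 2 members).
#' @param ref_sim similarity matrix among reference neurons.
#' @param query_sim matrix of query neurons (rows) x reference neurons
#'   (columns) similarities.
#' @return list of `ensemble_match` records: `ensemble`, `members`,
#'   `matched`, `threshold_used`, `sd_zero` flag.
#' @export
match_ensembles <- function(ensembles, ref_sim, query_sim) {
  lapply_named <- function(x, f) stats::setNames(lapply(names(x), f), names(x))
  lapply_named(ensembles, function(id) {
    members <- ensembles[[id]]
    stopifnot(length(members) >= 2L, all(members %in% rownames(ref_sim)))
    sub <- ref_sim[members, members]
    intra <- sub[upper.tri(sub)]
    sd0 <- length(intra) < 2L || stats::sd(intra) == 0
    thr <- mean(intra) - (if (sd0) 0 else stats::sd(intra))
    qmean <- rowMeans(query_sim[, members, drop = FALSE])
    structure(list(ensemble = id, members = members,
                   matched = rownames(query_sim)[qmean >= thr],
                   threshold_used = thr, sd_zero = sd0),
              class = "ensemble_match")
  })
}

#' Mirror a skeleton about an axis-aligned plane
#'
#' Reflects coordinates about the plane `axis = offset`; topology is
#' untouched and the operation is an involution (mirroring twice restores
#' the original).
#'
#' @param skel a [skeleton()] object.
#' @param axis `"x"`, `"y"`, or `"z"`.
#' @param offset plane position along the axis.
#' @return the mirrored [skeleton()].
#' @export
mirror_skeleton <- function(skel, axis = c("x", "y", "z"), offset = 0) {
  axis <- match.arg(axis)
  skel$nodes[[axis]] <- 2 * offset - skel$nodes[[axis]]
  skel
}

#' Downsample a skeleton by an integer factor
#'
#' Keeps every `factor`-th node in file order plus the root and all branch
#' points (so topology is preserved), reconnecting each kept node to its
#' nearest kept ancestor. Used to align node-count distributions between
#' datasets reconstructed at different resolutions.
#'
#' @param skel a [skeleton()] object.
#' @param factor integer >= 1.
#' @return the downsampled [skeleton()].
#' @export
downsample_skeleton <- function(skel, factor) {
  stopifnot(factor >= 1L)
  nd <- skel$nodes
  n <- nrow(nd)
  keep_idx <- seq(1L, n, by = factor)
  pi_ <- match(nd$parent_id, nd$node_id)
  n_children <- tabulate(pi_[!is.na(pi_)], nbins = n)
  branch <- which(n_children >= 2L)
  root <- which(is.na(nd$parent_id))
  keep <- sort(unique(c(keep_idx, branch, root)))
  keep_ids <- nd$node_id[keep]
  new_parent <- vapply(keep, function(i) {
    p <- pi_[i]
    while (!is.na(p) && !(p %in% keep)) p <- pi_[p]
    if (is.na(p)) NA_integer_ else nd$node_id[p]
  }, 0L)
  skeleton(data.frame(node_id = keep_ids, parent_id = new_parent,
                      x = nd$x[keep], y = nd$y[keep], z = nd$z[keep],
                      radius = nd$radius[keep]),
           neuron_id = skel$neuron_id)
}
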