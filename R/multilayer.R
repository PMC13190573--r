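# Relative connectivity through intermediate layers: the aggregate relative
# structural path strength from source populations (e.g. sensory neurons) to
# target hubs, chained through 0..max_layers intermediate relay layers.

#' Relative connectivity through one intermediate layer
#'
#' Normalises the upstream count matrix (sources x intermediates) by rows
#' (each source's output distribution over intermediates) and the downstream
#' count matrix (intermediates x targets) by columns (each target's input
#' distribution over intermediates), then multiplies:
#' `C[s, t] = sum_j u_sj * d_jt`. Entries lie in \[0, 1\]; zero-sum rows or
#' columns stay zero and are flagged. The measure is aggregate relative path
#' strength, not causal influence.
#'
#' @param upstream non-negative matrix, sources x intermediates.
#' @param downstream non-negative matrix, intermediates x targets.
#' @return list of class `relative_connectivity`: `C`, `layer_count = 1`,
#'   `zero_sources`, `zero_targets`.
#' @export
relative_connectivity <- function(upstream, downstream) {
  upstream <- as.matrix(upstream)
  downstream <- as.matrix(downstream)
  if (ncol(upstream) != nrow(downstream)) {
    stop("dimension mismatch: ", ncol(upstream), " intermediates upstream vs ",
         nrow(downstream), " downstream")
  }
  stopifnot(all(upstream >= 0), all(downstream >= 0))
  rs <- rowSums(upstream)
  u <- upstream
  u[rs > 0, ] <- u[rs > 0, , drop = FALSE] / rs[rs > 0]
  cs <- colSums(downstream)
  d <- downstream
  d[, cs > 0] <- sweep(d[, cs > 0, drop = FALSE], 2L, cs[cs > 0], "/")
  structure(list(C = u %*% d, layer_count = 1L,
                 zero_sources = which(rs == 0), zero_targets = which(cs == 0)),
            class = "relative_connectivity")
}

adjacency_block <- function(graph, from, to) {
  ed <- graph$edges
  keep <- ed$pre %in% from & ed$post %in% to
  m <- matrix(0, length(from), length(to), dimnames = list(from, to))
  if (any(keep)) m[cbind(ed$pre[keep], ed$post[keep])] <- ed$weight[keep]
  m
}

row_normalize <- function(m) {
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  m
}

col_normalize <- function(m) {
  cs <- colSums(m)
  m[, cs > 0] <- sweep(m[, cs > 0, drop = FALSE], 2L, cs[cs > 0], "/")
  m
}

#' Multi-layer relative connectivity profile
#'
#' Traces relative connectivity from labelled source populations (e.g.
#' sensory modalities) to targets across 0..`max_layers` intermediate relay
#' layers. Layer `l` chains `l + 1` normalised adjacency blocks: all hops but
#' the last are row-normalised (the presynaptic cell's output distribution),
#' and the final hop into a target is normalised by that target's total
#' input weight over the whole graph, so strengths are additive across
#' disjoint source populations; layer 0 is the normalised direct block.
#' Intermediates exclude sources and targets but may repeat across layers
#' (matrix-product semantics).
#'
#' @param graph a `conn_graph`.
#' @param sources named list: modality -> character vector of source ids, or
#'   a single character vector (treated as one unnamed modality).
#' @param targets character vector of target ids.
#' @param max_layers maximum number of intermediate layers (default 5).
#' @return list of class `multilayer_profile`: `strength` (long data.frame
#'   `target`, `modality`, `layer`, `strength` = summed relative connectivity
#'   from that modality's sources), and `matrices` (per modality, per layer).
#' @export
multilayer_profile <- function(graph, sources, targets, max_layers = 5L) {
  if (max_layers < 0L) stop("max_layers must be >= 0")
  if (!is.list(sources)) sources <- list(all = sources)
  all_sources <- unique(unlist(sources))
  stopifnot(all(all_sources %in% graph$nodes), all(targets %in% graph$nodes))
  inter <- setdiff(graph$nodes, c(all_sources, targets))
  # each target's total input weight across the whole graph: the final-hop
  # denominator, making strengths additive over disjoint source sets
  in_tot <- vapply(targets, function(t) {
    sum(graph$edges$weight[graph$edges$post == t])
  }, 0)
  final_norm <- function(m) {
    m[, in_tot > 0] <- sweep(m[, in_tot > 0, drop = FALSE], 2L,
                             in_tot[in_tot > 0], "/")
    m[, in_tot == 0] <- 0
    m
  }
  out_rows <- list()
  matrices <- list()
  for (mod in names(sources)) {
    src <- sources[[mod]]
    matrices[[mod]] <- vector("list", max_layers + 1L)
    for (l in 0:max_layers) {
      if (l == 0L) {
        C <- final_norm(adjacency_block(graph, src, targets))
      } else {
        C <- row_normalize(adjacency_block(graph, src, inter))
        if (l >= 2L) {
          mid <- row_normalize(adjacency_block(graph, inter, inter))
          for (j in seq_len(l - 1L)) C <- C %*% mid
        }
        C <- C %*% final_norm(adjacency_block(graph, inter, targets))
      }
      matrices[[mod]][[l + 1L]] <- C
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        target = targets, modality = mod, layer = l,
        strength = colSums(C), stringsAsFactors = FALSE)
    }
  }
  structure(list(strength = do.call(rbind, out_rows), matrices = matrices,
                 max_layers = as.integer(max_layers)),
            class = "multilayer_profile")
}

#' Per-target sensory modality preference
#'
#' Collapses a [multilayer_profile()] at a chosen layer into one 3-vector per
#' target (exactly three modality channels required), optionally
#' max-normalised per target for rendering; raw values are preserved.
#'
#' @param profile a `multilayer_profile` with three modalities.
#' @param layer intermediate-layer count to read (disynaptic = 1,
#'   trisynaptic = 2).
#' @param normalize divide each target's vector by its maximum (zero vectors
#'   are left unchanged).
#' @return matrix targets x 3 with attribute `raw` (the unnormalised values).
#' @export
modality_preference <- function(profile, layer = 1L, normalize = FALSE) {
  st <- profile$strength
  mods <- unique(st$modality)
  if (length(mods) != 3L) stop("modality_preference requires exactly 3 modalities")
  st <- st[st$layer == layer, , drop = FALSE]
  targets <- unique(st$target)
  m <- sapply(mods, function(mod) {
    st$strength[st$modality == mod][match(targets, st$target[st$modality == mod])]
  })
  m <- matrix(m, ncol = 3L, dimnames = list(targets, mods))
  raw <- m
  if (normalize) {
    mx <- apply(m, 1L, max)
    m[mx > 0, ] <- m[mx > 0, , drop = FALSE] / mx[mx > 0]
  }
  attr(m, "raw") <- raw
  m
}
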