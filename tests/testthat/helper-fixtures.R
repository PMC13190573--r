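# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write.

# straight chain skeleton along x with unit-length (or custom) edges
chain_skeleton <- function(n, step = 1, id = "chain") {
  skeleton(data.frame(node_id = seq_len(n),
                      parent_id = c(NA_integer_, seq_len(n - 1L)),
                      x = (seq_len(n) - 1) * step, y = 0, z = 0, radius = 1),
           neuron_id = id)
}

# skeleton with an explicit primary neurite (chain 1..n_primary along x) and
# one side branch of n_branch nodes leaving the primary at `branch_at`
branched_skeleton <- function(n_primary = 10L, branch_at = 4L,
                              n_branch = 5L, id = "branched") {
  nodes <- data.frame(node_id = seq_len(n_primary),
                      parent_id = c(NA_integer_, seq_len(n_primary - 1L)),
                      x = (seq_len(n_primary) - 1) * 10, y = 0, z = 0,
                      radius = 1)
  br <- data.frame(node_id = n_primary + seq_len(n_branch),
                   parent_id = c(branch_at,
                                 n_primary + seq_len(n_branch - 1L)),
                   x = (branch_at - 1) * 10,
                   y = seq_len(n_branch) * 5, z = 0, radius = 1)
  skeleton(rbind(nodes, br), neuron_id = id)
}

# random synapse table over a small id pool
random_sites <- function(n, n_neurons = 10L, seed = 1L,
                         regions = c("SMP", "LH", "MB")) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_neurons))
  out <- data.frame(pre_id = sample(ids, n, replace = TRUE),
                    post_id = sample(ids, n, replace = TRUE),
                    x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                    z = runif(n, 0, 1e5),
                    region = sample(regions, n, replace = TRUE),
                    side = "right", stringsAsFactors = FALSE)
  class(out) <- c("synapse_table", "data.frame")
  out
}

# --- independent brute-force triad classifier ------------------------------
# Classifies the induced subgraph on a node triple by canonicalising its
# 6-bit adjacency code over all 6 node permutations, entirely independent of
# igraph's census. The 64 codes are grouped into classes once, and classes
# are named by their dyad census (mutual/asymmetric/null + orientation),
# which reproduces the standard 16-class taxonomy.
triad_oracle_map <- local({
  # arc order within a triple (a,b,c): ab, ba, ac, ca, bc, cb
  arcs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  code_of <- function(adj) {
    sum(vapply(seq_len(6), function(k) adj[arcs[k, 1], arcs[k, 2]], 0) *
          2^(0:5))
  }
  canon <- integer(64)
  for (code in 0:63) {
    bits <- as.integer(intToBits(code))[1:6]
    adj <- matrix(0L, 3, 3)
    for (k in 1:6) adj[arcs[k, 1], arcs[k, 2]] <- bits[k]
    codes <- vapply(seq_len(nrow(perms)), function(p) {
      code_of(adj[perms[p, ], perms[p, ]])
    }, 0)
    canon[code + 1L] <- min(codes)
  }
  # label each canonical code with its M-A-N triad type
  label_of <- function(code) {
    bits <- as.integer(intToBits(code))[1:6]
    adj <- matrix(0L, 3, 3)
    for (k in 1:6) adj[arcs[k, 1], arcs[k, 2]] <- bits[k]
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    dyads <- vapply(1:3, function(i) {
      a <- adj[pairs[i, 1], pairs[i, 2]]; b <- adj[pairs[i, 2], pairs[i, 1]]
      if (a == 1 && b == 1) "m" else if (a == 0 && b == 0) "n" else "a"
    }, "")
    m <- sum(dyads == "m"); a <- sum(dyads == "a"); n <- sum(dyads == "n")
    base <- paste0(m, a, n)
    if (!base %in% c("021", "111", "030", "120")) return(base)
    outdeg <- rowSums(adj); indeg <- colSums(adj)
    if (base == "021") {
      if (max(outdeg) == 2) "021D" else if (max(indeg) == 2) "021U" else "021C"
    } else if (base == "030") {
      if (max(outdeg) == 2) "030T" else "030C"
    } else if (base == "111") {
      # 111D has the asymmetric arc pointing into the mutual dyad (A<->B<-C),
      # 111U has it pointing out of the dyad (A<->B->C)
      mut <- which(adj == 1 & t(adj) == 1, arr.ind = TRUE)
      mutual_nodes <- unique(as.integer(mut))
      other <- setdiff(1:3, mutual_nodes)
      if (any(adj[other, mutual_nodes] == 1)) "111D" else "111U"
    } else {
      non_mut_arcs <- which(adj == 1 & t(adj) == 0, arr.ind = TRUE)
      od <- tabulate(non_mut_arcs[, 1], 3); id <- tabulate(non_mut_arcs[, 2], 3)
      if (max(od) == 2) "120D" else if (max(id) == 2) "120U" else "120C"
    }
  }
  classes <- vapply(canon + 1L, function(i) label_of(canon[i]), "")
  classes
})

# brute-force census: counts per triad code name over all C(n,3) triples
brute_triad_census <- function(adj) {
  n <- nrow(adj)
  out <- integer(16)
  names(out) <- triad_classes()$code
  arcs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  for (a in seq_len(n - 2)) {
    for (b in seq(a + 1, n - 1)) {
      for (cc in seq(b + 1, n)) {
        tri <- adj[c(a, b, cc), c(a, b, cc)]
        code <- sum(vapply(1:6, function(k) tri[arcs[k, 1], arcs[k, 2]], 0) *
                      2^(0:5))
        cls <- triad_oracle_map[code + 1L]
        out[cls] <- out[cls] + 1L
      }
    }
  }
  out
}

conn_graph_from_adj <- function(adj) {
  idx <- which(adj == 1, arr.ind = TRUE)
  ids <- sprintf("v%02d", seq_len(nrow(adj)))
  conn_graph(data.frame(pre = ids[idx[, 1]], post = ids[idx[, 2]],
                        weight = rep(1L, nrow(idx))), nodes = ids)
}

# planted 3-block connectivity features with given contrast
planted_block_features <- function(n_per = 30L, p_per = 10L, contrast = 5,
                                   seed = 1L) {
  set.seed(seed)
  n <- 3L * n_per
  p <- 3L * p_per
  X <- matrix(rgamma(n * p, 1, 1), n, p)
  for (b in 1:3) {
    rows <- (b - 1L) * n_per + seq_len(n_per)
    cols <- (b - 1L) * p_per + seq_len(p_per)
    X[rows, cols] <- X[rows, cols] * contrast
  }
  rownames(X) <- sprintf("h%03d", seq_len(n))
  list(features = X / rowSums(X), truth = rep(1:3, each = n_per))
}

arch_spec_for <- function(kind, seed) {
  switch(kind,
         labeled_line = architecture_spec("labeled_line", n_hub = 100,
                                          n_in = 100, n_out = 100,
                                          seed = seed),
         mixed = architecture_spec("mixed", n_hub = 100, n_in = 100,
                                   n_out = 100, seed = seed),
         convergence_divergence = architecture_spec(
           "convergence_divergence", n_hub = 20, n_in = 160, n_out = 140,
           fan_in = 8, fan_out = 7, seed = seed))
}

hub_ids <- function(arch) arch$ground_truth$id[arch$ground_truth$role == "hub"]
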