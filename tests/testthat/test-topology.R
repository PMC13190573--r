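test_that("synapse assignment is exact nearest-node with the low-id tie rule", {
  sk <- chain_skeleton(5, step = 10)
  sites <- data.frame(x = c(20, 15, 33), y = 0, z = 0, polarity = "post",
                      class = "c")
  ann <- assign_synapses(sk, sites)
  expect_equal(ann$synapses$node_id[1], 3L)     # exactly at node 3
  expect_equal(ann$synapses$assign_dist[1], 0)
  expect_equal(ann$synapses$node_id[2], 2L)     # equidistant 2/3 -> lower id
  expect_equal(ann$synapses$node_id[3], 4L)

  # 1,000 random sites match exhaustive nearest-node search
  sk2 <- generate_skeleton(5, seed = 3)
  set.seed(4)
  q <- cbind(x = runif(1000, min(sk2$nodes$x), max(sk2$nodes$x)),
             y = runif(1000, min(sk2$nodes$y), max(sk2$nodes$y)),
             z = runif(1000, min(sk2$nodes$z), max(sk2$nodes$z)))
  ann2 <- assign_synapses(sk2, as.data.frame(q))
  pts <- as.matrix(sk2$nodes[, c("x", "y", "z")])
  for (i in sample(1000, 50)) {
    d <- sqrt(colSums((t(pts) - q[i, ])^2))
    expect_equal(ann2$synapses$node_id[i],
                 min(sk2$nodes$node_id[d <= min(d) + 1e-9]))
  }
  # outlier flagging
  far <- data.frame(x = 1e9, y = 0, z = 0)
  ann3 <- assign_synapses(sk, far, outlier_radius = 100)
  expect_true(ann3$synapses$outlier)
})

test_that("geodesic distances equal the weighted shortest-path oracle", {
  # chain with unit edges: node 4 is 3 from node 1
  sk <- chain_skeleton(5, step = 1)
  d <- geodesic_distances(sk, 1L)
  expect_equal(unname(d["4"]), 3)
  expect_error(geodesic_distances(sk, 99L), "unknown")

  sk2 <- generate_skeleton(6, seed = 8)
  nd <- sk2$nodes
  pi_ <- match(nd$parent_id, nd$node_id)
  w <- sqrt((nd$x - nd$x[pi_])^2 + (nd$y - nd$y[pi_])^2 +
              (nd$z - nd$z[pi_])^2)[!is.na(pi_)]
  g <- igraph::graph_from_data_frame(
    data.frame(from = nd$node_id[!is.na(pi_)], to = nd$parent_id[!is.na(pi_)]),
    directed = FALSE, vertices = data.frame(name = nd$node_id))
  for (start in sample(nd$node_id, 5)) {
    mine <- geodesic_distances(sk2, start)
    oracle <- igraph::distances(g, v = as.character(start), weights = w)[1, ]
    expect_equal(unname(mine[names(oracle)]), unname(oracle),
                 tolerance = 1e-9)
  }
  # tree-metric symmetry
  a <- nd$node_id[10]; b <- nd$node_id[50]
  expect_equal(unname(geodesic_distances(sk2, a)[as.character(b)]),
               unname(geodesic_distances(sk2, b)[as.character(a)]))
})

test_that("AIS detection finds the axonal branch point", {
  # pre sites confined to the side branch off the primary neurite; the
  # primary path continues past the branch point with post sites
  sk <- branched_skeleton(n_primary = 12, branch_at = 4, n_branch = 6)
  branch_nodes <- 13:18
  pre <- data.frame(x = sk$nodes$x[branch_nodes],
                    y = sk$nodes$y[branch_nodes],
                    z = 0, polarity = "pre", class = "out")
  post <- data.frame(x = sk$nodes$x[6:12], y = 0, z = 0, polarity = "post",
                     class = "in")
  ann <- detect_ais(assign_synapses(sk, rbind(pre, post)))
  expect_equal(ann$ais_node, 4L)
  expect_gte(ann$ais_diagnostics$pre_fraction, 0.8)

  # no pre sites -> none
  ann2 <- detect_ais(assign_synapses(sk, post))
  expect_true(is.na(ann2$ais_node))
  # unbranched chain -> none
  ch <- chain_skeleton(10)
  s <- data.frame(x = 3, y = 0, z = 0, polarity = "pre", class = "c")
  ann3 <- detect_ais(assign_synapses(ch, s))
  expect_true(is.na(ann3$ais_node))
})

test_that("class distance distributions partition the synapse set", {
  sk <- branched_skeleton()
  syn <- data.frame(x = sk$nodes$x[c(1, 5, 14)], y = sk$nodes$y[c(1, 5, 14)],
                    z = 0, polarity = c("pre", "post", "post"),
                    class = c("a", "a", "b"))
  ann <- assign_synapses(sk, syn)
  dd <- class_distance_distributions(ann, reference = "root")
  expect_equal(nrow(dd), 3L)
  expect_equal(attr(dd, "unit"), "nm")
  # all synapses at the reference node give zero distances
  at_root <- data.frame(x = 0, y = 0, z = 0, polarity = "pre", class = "r")
  dd0 <- class_distance_distributions(assign_synapses(sk, at_root),
                                      reference = "root")
  expect_equal(dd0$distance, 0)
  # union of per-group distances equals the all-synapse distances
  dall <- class_distance_distributions(ann, reference = "root",
                                       group_by = "polarity")
  expect_setequal(dall$distance, dd$distance)
  # reference = ais without detection is an explicit error
  expect_error(class_distance_distributions(ann, reference = "ais"),
               "detect_ais")
  # generator-placed synapses recover exactly the planted depth
  sk2 <- generate_skeleton(4, seed = 2)
  pl <- place_synapses(sk2, list(list(label = "x", count = 50,
                                      bias = "uniform", strength = 0)),
                       seed = 3)
  pl$x <- sk2$nodes$x[match(pl$node_id, sk2$nodes$node_id)]
  pl$y <- sk2$nodes$y[match(pl$node_id, sk2$nodes$node_id)]
  pl$z <- sk2$nodes$z[match(pl$node_id, sk2$nodes$node_id)]
  pl$polarity <- "post"
  ann2 <- assign_synapses(sk2, pl)
  expect_equal(ann2$synapses$node_id, pl$node_id)
  d <- geodesic_distances(sk2, sk2$root)
  dd2 <- class_distance_distributions(ann2, reference = "root",
                                      group_by = "class")
  expect_equal(dd2$distance, unname(d[as.character(pl$node_id)]))
})

test_that("proximal-bias permutation test behaves at the extremes", {
  # total separation (continuous values; with exactly tied constants the
  # median statistic is degenerate under permutation): p at the floor
  set.seed(1)
  a <- 1 + runif(30, -1e-3, 1e-3)
  b <- 2 + runif(30, -1e-3, 1e-3)
  r <- proximal_bias_test(a, b, n_permutations = 999, seed = 2)
  expect_equal(r$statistic, -1, tolerance = 1e-2)
  expect_lte(r$p_value, 2 / 1000)
  expect_equal(r$direction, "a_proximal")
  # antisymmetry
  r2 <- proximal_bias_test(rep(2, 30), rep(1, 30), n_permutations = 99,
                           seed = 2)
  expect_equal(r2$statistic, 1)
  expect_error(proximal_bias_test(numeric(0), 1:3))

  # null calibration: rejection rate near alpha for identical distributions
  set.seed(9)
  rej <- vapply(1:60, function(i) {
    a <- rexp(40); b <- rexp(40)
    proximal_bias_test(a, b, n_permutations = 199, seed = i)$p_value < 0.05
  }, NA)
  expect_lte(mean(rej), 0.15)
})

test_that("sfdp layout descends the spring-electrical energy", {
  sk <- generate_skeleton(3, seed = 4)
  lay <- sfdp_layout(sk, iterations = 150, seed = 2)
  expect_true(all(diff(lay$energy) <= 0))
  expect_true(all(is.finite(lay$coords)))
  expect_identical(sfdp_layout(sk, iterations = 50, seed = 7)$coords,
                   sfdp_layout(sk, iterations = 50, seed = 7)$coords)

  # 2-node equilibrium: attractive c_att d^2 balances repulsive c_rep / d,
  # solved independently by 1-D root finding
  two <- chain_skeleton(2, step = 5)
  for (cc in list(c(1, 1), c(8, 1), c(1, 4))) {
    lay2 <- sfdp_layout(two, iterations = 2000, seed = 1,
                        c_rep = cc[1], c_att = cc[2])
    sep <- sqrt(sum((lay2$coords[1, ] - lay2$coords[2, ])^2))
    root <- stats::uniroot(function(d) cc[2] * d^2 - cc[1] / d,
                           c(1e-3, 1e3))$root
    expect_equal(sep, root, tolerance = 1e-2)
  }
  # layout ops never alter the skeleton
  before <- sk$nodes
  invisible(sfdp_layout(sk, iterations = 10, seed = 1))
  invisible(ranked_layout(sk))
  expect_identical(sk$nodes, before)
})

test_that("ranked layout assigns ranks, virtual nodes, and few crossings", {
  ch <- chain_skeleton(6)
  rl <- ranked_layout(ch)
  expect_equal(rl$crossings, 0L)
  expect_equal(rl$n_virtual, 0L)
  expect_true(all(rl$coords$x == 1))  # single column
  expect_equal(sort(rl$coords$rank), 0:5)

  # complete binary tree of depth 3: zero crossings achievable and achieved
  nodes <- data.frame(node_id = 1:15,
                      parent_id = c(NA, rep(1:7, each = 2)),
                      x = 0, y = 0, z = 0, radius = 1)
  nodes$x <- seq_len(15)  # distinct positions
  bt <- skeleton(nodes, "bt")
  expect_equal(ranked_layout(bt)$crossings, 0L)

  # virtual node count = sum over edges of (rank span - 1)
  long <- skeleton(data.frame(node_id = 1:3, parent_id = c(NA, 1L, 2L),
                              x = c(0, 1, 100), y = 0, z = 0, radius = 1),
                   "long")
  rl2 <- ranked_layout(long, rank_by = "cable", rank_step = 1)
  nd_rank <- rl2$coords[!rl2$coords$virtual, ]
  spans <- diff(sort(nd_rank$rank))
  expect_equal(rl2$n_virtual, sum(pmax(spans - 1, 0)))
  expect_gt(rl2$n_virtual, 0L)
})
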