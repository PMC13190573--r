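test_that("dotprops tangents align with local geometry", {
  chain <- chain_skeleton(20, step = 1000)
  dp <- make_dotprops(chain, k = 5)
  expect_equal(nrow(dp$points), 20L)  # point count preserved
  expect_equal(sqrt(rowSums(dp$tangents^2)), rep(1, 20), tolerance = 1e-9)
  # straight chain: all tangents parallel to the axis
  expect_true(all(abs(dp$tangents[, 1]) > 1 - 1e-6))

  # L-shaped path: corner tangent is the principal axis of its k-point
  # neighbourhood (oracle: eigen decomposition done here directly)
  nodes <- data.frame(node_id = 1:11, parent_id = c(NA, 1:10),
                      x = c(0:5, rep(5, 5)), y = c(rep(0, 6), 1:5), z = 0,
                      radius = 1)
  L <- skeleton(nodes, "L")
  dpl <- make_dotprops(L, k = 5)
  corner <- 6  # node at the bend
  pts <- as.matrix(nodes[, c("x", "y", "z")])
  nn <- order(sqrt(rowSums(sweep(pts, 2, pts[corner, ])^2)))[1:5]
  cc <- sweep(pts[nn, ], 2, colMeans(pts[nn, ]))
  v <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(dpl$tangents[corner, ] * v)), 1, tolerance = 1e-9)
  # the corner tangent is genuinely intermediate between the arm axes
  expect_true(abs(dpl$tangents[corner, 1]) > 0.2 &&
                abs(dpl$tangents[corner, 2]) > 0.2)
  expect_error(make_dotprops(chain_skeleton(4), k = 5), "k \\+ 1")
})

test_that("raw scores match hand-computed values and monotonicity", {
  chain <- chain_skeleton(20, step = 1000)
  dp <- make_dotprops(chain, k = 5)
  # self-match with f(0, 1) = 1 - lambda
  sf <- score_function_default(sigma = 2000, lambda = 0.1)
  expect_equal(nblast_raw(dp, dp, sf), 20 * 0.9)

  # 2-point toy with an explicit score table, summed by hand
  tab <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.0 0.5 1.0",
               "1000 1 2",
               "1e9 3 4"), tab)
  f <- read_score_table(tab)
  # bins: d <= 1000 -> row 1; |dot| <= 0.5 -> col 1
  expect_equal(f(500, 0.3), 1)
  expect_equal(f(500, 0.9), 2)
  expect_equal(f(5000, 0.3), 3)
  expect_equal(f(5000, 0.9), 4)
  q <- structure(list(points = rbind(c(0, 0, 0), c(10000, 0, 0)),
                      tangents = rbind(c(1, 0, 0), c(0, 1, 0)),
                      k_used = 1L, neuron_id = "q"), class = "dotprops")
  t_ <- structure(list(points = rbind(c(0, 0, 0), c(10000, 100, 0)),
                       tangents = rbind(c(1, 0, 0), c(0, 1, 0)),
                       k_used = 1L, neuron_id = "t"), class = "dotprops")
  # point 1: d = 0, |dot| = 1 -> 2 ; point 2: d = 100, |dot| = 1 -> 2
  expect_equal(nblast_raw(q, t_, f), 4)

  # translating the target away strictly decreases the score for any score
  # function decreasing in d
  far <- t_
  far$points <- far$points + 50000
  expect_lt(nblast_raw(q, far, sf), nblast_raw(q, t_, sf))
})

test_that("similarity matrix is self-normalised and symmetric", {
  dps <- list(a = make_dotprops(generate_skeleton(3, seed = 1), k = 5),
              b = make_dotprops(generate_skeleton(3, seed = 2), k = 5),
              c = make_dotprops(generate_skeleton(3, seed = 3), k = 5))
  m <- nblast_matrix(dps)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m, t(m))
  # normalised similarity <= 1 for score functions maximised at (0, 1)
  expect_true(all(m <= 1 + 1e-9))
  # duplicated neuron: off-diagonal similarity 1
  dps$d <- dps$a
  m2 <- nblast_matrix(dps)
  expect_equal(m2["a", "d"], 1)
  # self-similarity is the row maximum
  for (i in rownames(m)) expect_equal(max(m[i, ]), m[i, i])
})

test_that("ensemble identification separates planted morphology blocks", {
  # planted similarity: 3 blocks of 6 with high intra, low inter
  set.seed(5)
  n <- 18
  truth <- rep(1:3, each = 6)
  sim <- matrix(runif(n * n, 0, 0.2), n, n)
  for (b in 1:3) {
    idx <- which(truth == b)
    sim[idx, idx] <- runif(36, 0.7, 0.9)
  }
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  ids <- sprintf("n%02d", 1:n)
  dimnames(sim) <- list(ids, ids)
  ens <- identify_ensembles(stats::setNames(truth, ids), sim)
  expect_true(all(ens$accepted))

  # randomly permuted labels are accepted at about the nominal rate
  set.seed(6)
  hits <- replicate(60, {
    perm <- stats::setNames(sample(truth), ids)
    any(identify_ensembles(perm, sim, alpha = 0.05)$accepted)
  })
  expect_lt(mean(hits), 0.5)  # far below the planted case's 100%

  # singleton clusters are skipped with a flag
  lab1 <- stats::setNames(c(1, rep(2, n - 1)), ids)
  ens1 <- identify_ensembles(lab1, sim)
  expect_true(ens1$skipped[ens1$cluster == 1])
})

test_that("ensemble matching applies the mean - sd threshold monotonically", {
  set.seed(7)
  ids <- sprintf("r%02d", 1:6)
  sim <- matrix(runif(36, 0.6, 0.8), 6, 6, dimnames = list(ids, ids))
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  ens <- list(e1 = ids[1:3])
  sub <- sim[ids[1:3], ids[1:3]]
  intra <- sub[upper.tri(sub)]
  thr <- mean(intra) - sd(intra)
  query <- rbind(hit = rep(thr + 0.05, 6), miss = rep(thr - 0.05, 6))
  colnames(query) <- ids
  got <- match_ensembles(ens, sim, query)
  expect_equal(got$e1$threshold_used, thr)
  expect_equal(got$e1$matched, "hit")
  # a query identical to a reference member is matched
  query2 <- rbind(clone = sim[ids[1], ])
  expect_true("clone" %in% match_ensembles(ens, sim, query2)$e1$matched)
  # lowering the threshold never removes a match (monotone): emulate by
  # shifting every query similarity up
  got_hi <- match_ensembles(ens, sim, query + 0.2)
  expect_true(all(got$e1$matched %in% got_hi$e1$matched))
  # sd = 0 pairs flag and use the mean
  sim0 <- sim
  sim0[ids[1], ids[2]] <- sim0[ids[2], ids[1]] <- 0.7
  got0 <- match_ensembles(list(e = ids[1:2]), sim0, query)
  expect_true(got0$e$sd_zero)
  expect_equal(got0$e$threshold_used, 0.7)
})

test_that("mirroring is an involutive isometry preserving topology", {
  sk <- generate_skeleton(4, seed = 9)
  m <- mirror_skeleton(sk, "x", offset = 500)
  mm <- mirror_skeleton(m, "x", offset = 500)
  expect_equal(mm$nodes, sk$nodes)
  expect_equal(m$nodes$parent_id, sk$nodes$parent_id)
  expect_equal(nrow(m$nodes), nrow(sk$nodes))
  # pairwise distances preserved
  p0 <- as.matrix(sk$nodes[1:20, c("x", "y", "z")])
  p1 <- as.matrix(m$nodes[1:20, c("x", "y", "z")])
  expect_equal(as.matrix(dist(p0)), as.matrix(dist(p1)), tolerance = 1e-9)
})

test_that("downsampling preserves root, branch points, and self-similarity", {
  # node spacing well inside the score function's distance decay, as for
  # densely reconstructed skeletons
  sk <- generate_skeleton(6, seed = 12, step = 500)
  n <- nrow(sk$nodes)
  ds <- downsample_skeleton(sk, 2L)
  expect_gte(nrow(ds$nodes), ceiling(n / 2))
  expect_equal(ds$root, sk$root)
  # branch points survive
  pi_ <- match(sk$nodes$parent_id, sk$nodes$node_id)
  nch <- tabulate(pi_[!is.na(pi_)], nbins = n)
  expect_true(all(sk$nodes$node_id[nch >= 2] %in% ds$nodes$node_id))
  # normalised self-similarity of skeleton to its downsampled self stays
  # high at factor 2 (heuristic bound on smooth synthetic skeletons)
  dp <- make_dotprops(sk, k = 5)
  dpd <- make_dotprops(ds, k = 5)
  sf <- score_function_default()
  norm_sim <- nblast_raw(dp, dpd, sf) / nblast_raw(dp, dp, sf)
  expect_gte(norm_sim, 0.8)
})
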