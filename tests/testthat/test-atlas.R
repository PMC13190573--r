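test_that("Bray-Curtis matches the printed formula and semimetric properties", {
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)  # (1 + 0) / (3 + 2)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(3)
  for (i in 1:30) {
    u <- rexp(8); v <- rexp(8)
    expect_equal(bray_curtis(u, v), bray_curtis(v, u))
    expect_equal(bray_curtis(u, u), 0)
    expect_gte(bray_curtis(u, v), 0)
    expect_lte(bray_curtis(u, v), 1)
  }
  # the matrix route agrees with the scalar definition
  X <- matrix(rexp(40), 8, 5)
  D <- bray_curtis_matrix(X)
  for (i in 1:7) expect_equal(D[i, i + 1], bray_curtis(X[i, ], X[i + 1, ]))
})

test_that("feature matrix blocks are normalised per hub", {
  ed <- data.frame(pre = c("a", "b", "h1", "h1", "x"),
                   post = c("h1", "h1", "t1", "t2", "y"),
                   weight = c(3, 1, 2, 2, 5))
  g <- conn_graph(ed)
  fm <- build_feature_matrix(g, c("h1", "x"))
  expect_equal(unname(fm$features["h1", c("up:a", "up:b")]), c(0.75, 0.25))
  expect_equal(sum(fm$features["h1", fm$downstream_cols]), 1)
  # 'x' has no inputs: zero upstream row, flagged
  expect_equal(sum(fm$features["x", fm$upstream_cols]), 0)
  expect_true("x" %in% fm$zero_input_hubs)
  # block row sums are 0 or 1 on random graphs
  arch <- generate_architecture(arch_spec_for("convergence_divergence", 12))
  fm2 <- build_feature_matrix(arch$graph, hub_ids(arch))
  ru <- rowSums(fm2$features[, fm2$upstream_cols])
  rd <- rowSums(fm2$features[, fm2$downstream_cols])
  expect_true(all(abs(ru) < 1e-12 | abs(ru - 1) < 1e-12))
  expect_true(all(abs(rd) < 1e-12 | abs(rd - 1) < 1e-12))
})

test_that("Ward clustering follows the Lance-Williams recurrence", {
  # manual agglomeration on a 4-point distance matrix
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- c(1, 5, 6, 5.2, 6.1, 1.1)
  d <- d + t(d)
  hc <- attr(ward_cluster(d, k = 2), "hclust")
  # first two merges join the two tight pairs at their pairwise distances
  expect_equal(sort(hc$height[1:2]), c(1, 1.1))
  # final merge height from the recurrence:
  # d(u,v)^2 = ((|v|+|s|) d(v,s)^2 + (|v|+|t|) d(v,t)^2 - |v| d(s,t)^2) / T
  h12 <- sqrt((3 * 5^2 + 3 * 6^2 - 2 * 1^2) / 4)       # {1,2} vs 3
  h12_4 <- NULL
  # merge {3,4} after {1,2}: d({1,2},{3,4})
  d_12_3 <- sqrt((2 * 25 + 2 * 27.04 - 1) / 3)
  d_12_4 <- sqrt((2 * 36 + 2 * 37.21 - 1) / 3)
  final <- sqrt((3 * d_12_3^2 + 3 * d_12_4^2 - 2 * 1.1^2) / 4)
  expect_equal(hc$height[3], final, tolerance = 1e-10)
  # merge heights are non-decreasing
  expect_true(all(diff(hc$height) >= -1e-12))
  # k = n gives singletons
  expect_equal(length(unique(ward_cluster(d, k = 4))), 4L)
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Ward on Bray-Curtis recovers planted connectivity blocks", {
  pb <- planted_block_features(n_per = 20, contrast = 5, seed = 2)
  lab <- ward_cluster(bray_curtis_matrix(pb$features), k = 3)
  expect_equal(adjusted_rand_index(lab, pb$truth), 1)
})

test_that("UMAP embedding is seeded-deterministic and separates blocks", {
  pb <- planted_block_features(n_per = 20, contrast = 5, seed = 5)
  e1 <- embed_umap(pb$features, n_neighbors = 10, seed = 42)
  e2 <- embed_umap(pb$features, n_neighbors = 10, seed = 42)
  expect_identical(e1$coords, e2$coords)
  expect_true(all(is.finite(e1$coords)))
  expect_equal(nrow(e1$coords), 60L)
  # between-block centroid distances exceed mean within-block distance
  cen <- sapply(1:3, function(b) colMeans(e1$coords[pb$truth == b, ]))
  between <- min(dist(t(cen)))
  within <- mean(sapply(1:3, function(b) {
    mean(dist(e1$coords[pb$truth == b, ]))
  }))
  expect_gt(between, within)
  expect_error(embed_umap(pb$features[1:5, ], n_neighbors = 10), "n_neighbors")
})

test_that("HDBSCAN clusters dense blobs and refuses sparse bridges", {
  set.seed(8)
  blob1 <- matrix(rnorm(80, 0, 0.05), ncol = 2)
  blob2 <- matrix(rnorm(80, 5, 0.05), ncol = 2)
  bridge <- cbind(seq(2.2, 2.8, length.out = 3), seq(2.2, 2.8, length.out = 3))
  pts <- rbind(blob1, blob2, bridge)
  lab <- cluster_embedding(pts, min_cluster_size = 10, min_samples = 10)
  expect_equal(attr(lab, "n_clusters"), 2L)
  # the two blobs are recovered exactly; sparse bridge points are never a
  # cluster of their own and at least some are refused as noise
  expect_equal(adjusted_rand_index(lab[1:80], rep(1:2, each = 40)), 1)
  expect_true(any(lab[81:83] == -1L))
  # labels invariant to point order after canonical relabelling (clean
  # two-blob case; borderline points are legitimately order-sensitive)
  clean <- rbind(blob1, blob2)
  lab_c <- cluster_embedding(clean, 10, 10)
  perm <- sample(nrow(clean))
  lab_p <- cluster_embedding(clean[perm, ], 10, 10)
  expect_equal(adjusted_rand_index(lab_p, lab_c[perm]), 1)
  # all points identical: a single cluster
  same <- matrix(1, 20, 2)
  expect_equal(attr(cluster_embedding(same, 5, 5), "n_clusters"), 1L)
})

test_that("local density separates planted clusters from outliers", {
  set.seed(9)
  clustered <- matrix(rep(c(5, 5, 5, 1, 1), each = 30), 30, 5) +
    matrix(runif(150, 0, 0.05), 30, 5)
  outliers <- matrix(rexp(50, 0.2), 10, 5)
  X <- rbind(clustered, outliers)
  dens <- local_density(X, k = 5)
  expect_true(all(is.finite(dens) & dens > 0))
  expect_gt(min(dens[1:30]), max(dens[31:40]))
  # duplicated rows floor at the epsilon and get flagged
  dup <- matrix(1, 7, 3)
  dd <- local_density(rbind(dup, matrix(runif(30), 10, 3)), k = 5)
  expect_true(all(1:7 %in% attr(dd, "duplicates")))
  expect_true(all(is.finite(dd)))
  expect_error(local_density(dup, k = 15), "more than k")
})

test_that("2-D KDE integrates to one and respects symmetry", {
  set.seed(10)
  blob <- cbind(rnorm(200, 2, 0.3), rnorm(200, -1, 0.3))
  est <- kde_2d(blob)
  # trapezoid quadrature oracle
  dx <- diff(est$x[1:2]); dy <- diff(est$y[1:2])
  integral <- sum(est$z) * dx * dy
  expect_lt(abs(integral - 1), 0.02)
  # argmax within the blob's bounding box
  am <- which(est$z == max(est$z), arr.ind = TRUE)[1, ]
  expect_true(est$x[am[1]] > min(blob[, 1]) && est$x[am[1]] < max(blob[, 1]))
  expect_true(est$y[am[2]] > min(blob[, 2]) && est$y[am[2]] < max(blob[, 2]))
  # mirror-symmetric two-blob input gives a symmetric grid
  half <- cbind(rnorm(300, -3, 0.2), rnorm(300, 0, 0.2))
  two <- rbind(half, cbind(-half[, 1], half[, 2]))  # exact reflection
  est2 <- kde_2d(two, n_grid = 64)
  expect_equal(est2$z, est2$z[rev(seq_along(est2$x)), ], tolerance = 1e-6)
  # degenerate input flagged, not an error
  est3 <- kde_2d(matrix(1, 5, 2))
  expect_true(est3$degenerate)
})

test_that("regional preference uses the max of input and output percentage", {
  ed <- data.frame(pre = c("lh1", "h1", "mb1", "h2"),
                   post = c("h1", "mb1", "h2", "lh1"),
                   weight = c(3, 6, 5, 5))
  g <- conn_graph(ed)
  fm <- build_feature_matrix(g, c("h1", "h2"))
  pref <- connectivity_preference(fm, list(LH = "lh1", MB = "mb1",
                                           FB = "fb_none"))
  # h1: input 100% from lh1, output 100% to mb1 -> LH 1 (max(1, 0)), MB 1
  expect_equal(unname(pref["h1", ]), c(1, 1, 0))
  col <- preference_color(matrix(c(1, 0, 0), 1), mode = "cmy")
  expect_equal(unname(col[1, ]), c(0, 1, 1))  # pure cyan
  expect_equal(unname(preference_color(matrix(0, 1, 3), "cmy")[1, ]),
               c(1, 1, 1))  # white origin in CMY
  expect_equal(unname(preference_color(matrix(0, 1, 3), "rgb")[1, ]),
               c(0, 0, 0))  # black origin in RGB
  expect_equal(unname(preference_color(matrix(c(0.3, 0.6, 2), 1), "rgb")[1, ]),
               c(0.3, 0.6, 1))  # clipped
})
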