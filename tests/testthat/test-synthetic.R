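test_that("planted architectures have the prescribed degree structure", {
  # labeled line: every hub has exactly one upstream and one downstream
  # partner, disjoint across hubs
  arch <- generate_architecture(architecture_spec("labeled_line", n_hub = 5,
                                                  n_in = 8, n_out = 6,
                                                  seed = 2))
  ed <- arch$graph$edges
  hubs <- hub_ids(arch)
  for (h in hubs) {
    expect_equal(sum(ed$post == h), 1L)
    expect_equal(sum(ed$pre == h), 1L)
  }
  ups <- ed$pre[ed$post %in% hubs]
  expect_equal(anyDuplicated(ups), 0L)

  # mixed: every input connects to every hub
  arch <- generate_architecture(architecture_spec("mixed", n_hub = 3,
                                                  n_in = 4, n_out = 2,
                                                  seed = 2))
  ed <- arch$graph$edges
  expect_equal(sum(ed$post %in% hub_ids(arch)), 12L)

  # convergence-divergence: hub in-degree has mean fan_in exactly
  arch <- generate_architecture(architecture_spec("convergence_divergence",
                                                  n_hub = 10, n_in = 80,
                                                  n_out = 70, fan_in = 8,
                                                  fan_out = 7, seed = 2))
  ed <- arch$graph$edges
  indeg <- vapply(hub_ids(arch), function(h) sum(ed$post == h), 0L)
  outdeg <- vapply(hub_ids(arch), function(h) sum(ed$pre == h), 0L)
  expect_equal(mean(indeg), 8)
  expect_equal(mean(outdeg), 7)
  # dedicated partners: within-hub sets drawn without replacement
  for (h in hub_ids(arch)) {
    expect_equal(anyDuplicated(ed$pre[ed$post == h]), 0L)
  }

  # infeasible specs error out
  expect_error(architecture_spec("labeled_line", n_hub = 5, n_in = 3,
                                 n_out = 5), "n_in")
  expect_error(architecture_spec("convergence_divergence", n_hub = 2,
                                 n_in = 3, n_out = 3, fan_in = 5,
                                 fan_out = 1), "fan_in")
})

test_that("generators are deterministic per seed", {
  s <- architecture_spec("convergence_divergence", n_hub = 5, n_in = 20,
                         n_out = 20, fan_in = 4, fan_out = 4, seed = 11)
  expect_identical(generate_architecture(s)$graph$edges,
                   generate_architecture(s)$graph$edges)
  expect_identical(generate_fragment_population(50, 50, seed = 3),
                   generate_fragment_population(50, 50, seed = 3))
  expect_identical(generate_skeleton(4, seed = 8)$nodes,
                   generate_skeleton(4, seed = 8)$nodes)
  sk <- generate_skeleton(3, seed = 1)
  cls <- list(list(label = "a", count = 50, bias = "proximal", strength = 2))
  expect_identical(place_synapses(sk, cls, seed = 5),
                   place_synapses(sk, cls, seed = 5))
})

test_that("fragment populations are bimodal with a valley between the modes", {
  pop <- generate_fragment_population(2000, 2000,
                                      complete_law = lognormal_law(300 * exp(0.25), 0.5),
                                      fragment_law = lognormal_law(8 * exp(0.25), 0.5),
                                      seed = 4)
  counts <- c(pop$n_pre, pop$n_post)
  z <- log10(counts + 1)
  den <- stats::density(z, bw = stats::sd(z) * length(z)^(-1 / 5))
  # density grid-search oracle: the pooled density valley lies strictly
  # between the two modes (8 and 300)
  between <- den$x > log10(8) & den$x < log10(300)
  valley_x <- den$x[between][which.min(den$y[between])]
  expect_gt(valley_x, log10(8) + 0.1)
  expect_lt(valley_x, log10(300) - 0.1)

  # no fragments -> unimodal; the estimator reports no threshold
  uni <- generate_fragment_population(500, 0, seed = 4)
  th <- estimate_completeness_threshold(c(uni$n_pre, uni$n_post), "valley")
  expect_false(th$found)

  # overlapping modes flag a warning in the output
  ov <- generate_fragment_population(100, 100,
                                     complete_law = lognormal_law(20, 0.5),
                                     fragment_law = lognormal_law(10, 0.5),
                                     seed = 4)
  expect_true(attr(ov, "mode_overlap_warning"))
})

test_that("intrinsic populations respect the 85% boundary exactly", {
  pp <- generate_intrinsic_population(20, 20, region = "SMP", seed = 6)
  gt <- pp$ground_truth
  expect_true(all(gt$combined_frac[gt$intrinsic] > 0.85))
  expect_true(all(gt$pre_frac[gt$intrinsic] > 0.85))
  expect_true(all(gt$combined_frac[!gt$intrinsic] <= 0.85))

  # recount oracle: fractions recomputed from the emitted sites match the
  # recorded ground truth
  fr <- compute_region_fractions(pp$sites, "SMP", neuron_ids = gt$id)
  i <- match(fr$neuron_id, gt$id)
  expect_equal(fr$combined_frac, gt$combined_frac[i], tolerance = 1e-12)
  expect_equal(fr$pre_frac, gt$pre_frac[i], tolerance = 1e-12)

  # n_extrinsic = 0 -> all fractions above the boundary
  only <- generate_intrinsic_population(10, 0, seed = 6)
  expect_true(all(only$ground_truth$combined_frac > 0.85))

  # laws with mass at/over the boundary are rejected
  expect_error(generate_intrinsic_population(
    5, 5, intrinsic_frac_law = uniform_law(0.85, 0.99)), "0.85")
  expect_error(generate_intrinsic_population(
    5, 5, extrinsic_frac_law = uniform_law(0.1, 0.86)), "0.85")
})

test_that("skeleton generator yields binary trees with b + 1 leaves", {
  chain <- generate_skeleton(0, seed = 2)
  expect_equal(sum(!(chain$nodes$node_id %in% chain$nodes$parent_id)), 1L)
  expect_gt(total_cable_length(chain), 0)

  sk <- generate_skeleton(7, seed = 2)
  leaves <- sum(!(sk$nodes$node_id %in% sk$nodes$parent_id))
  expect_equal(leaves, 8L)
})

test_that("synapse placement matches cable proportions and bias direction", {
  sk <- generate_skeleton(5, seed = 13)
  # uniform: node-choice frequencies track cable-length shares
  syn <- place_synapses(sk, list(list(label = "u", count = 10000,
                                      bias = "uniform", strength = 0)),
                        seed = 3)
  nd <- sk$nodes
  pi_ <- match(nd$parent_id, nd$node_id)
  elen <- ifelse(is.na(pi_), 0,
                 sqrt((nd$x - nd$x[pi_])^2 + (nd$y - nd$y[pi_])^2 +
                        (nd$z - nd$z[pi_])^2))
  w <- elen / 2
  for (i in which(!is.na(pi_))) w[pi_[i]] <- w[pi_[i]] + elen[i] / 2
  p_true <- w / sum(w)
  freq <- tabulate(match(syn$node_id, nd$node_id), nbins = nrow(nd)) / 10000
  # binomial error bound at n = 10,000 (4 sigma, elementwise)
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_true(all(abs(freq - p_true) <= 4 * se + 1e-9))

  # proximal class lands closer to the root than distal, across seeds
  d <- geodesic_distances(sk, sk$root)
  hits <- vapply(1:20, function(s) {
    syn <- place_synapses(sk, list(
      list(label = "p", count = 500, bias = "proximal", strength = 3),
      list(label = "d", count = 500, bias = "distal", strength = 3)),
      seed = s)
    median(d[as.character(syn$node_id[syn$class == "p"])]) <
      median(d[as.character(syn$node_id[syn$class == "d"])])
  }, NA)
  expect_gte(sum(hits), 20L)

  # bias strength 0 is the uniform case
  a <- place_synapses(sk, list(list(label = "x", count = 100,
                                    bias = "proximal", strength = 0)),
                      seed = 9)
  b <- place_synapses(sk, list(list(label = "x", count = 100,
                                    bias = "uniform", strength = 0)),
                      seed = 9)
  expect_identical(a$node_id, b$node_id)
  expect_error(place_synapses(sk, list(list(label = "x", count = 10,
                                            bias = "sideways",
                                            strength = 1)), seed = 1))
})

test_that("generated brains carry complete, consistent ground truth", {
  spec <- architecture_spec("convergence_divergence", n_hub = 6, n_in = 48,
                            n_out = 42, fan_in = 8, fan_out = 7, seed = 3)
  brain <- generate_brain(spec, skeletons = "hubs", n_branchpoints = 3L)
  expect_setequal(brain$ground_truth$id, brain$neurons$id)
  hubs <- brain$ground_truth$id[brain$ground_truth$role == "hub"]
  expect_named(brain$skeletons, hubs, ignore.order = TRUE)
  # every hub is strictly intrinsic in the emitted sites, per polarity
  fr <- compute_region_fractions(brain$sites, brain$region,
                                 neuron_ids = brain$neurons$id)
  sel <- select_intrinsic(fr, rule = "both_polarity")
  expect_setequal(sel, hubs)
  # and no non-hub neuron passes even the combined rule
  selc <- select_intrinsic(fr, rule = "combined")
  expect_setequal(selc, hubs)
})
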