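# Synthetic connectomes with planted ground truth. Every generator is
# deterministic per seed and records enough truth to score the downstream
# stage that consumes it.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Log-normal synapse-count law
#'
#' Weight and count laws are parameterised log-normals. The default edge
#' weight law (median 5, sigma_log 1) is chosen so that conventional edge
#' thresholds (>= 2, >= 5 synapses) remove a realistic minority of edges.
#'
#' @param median median of the law.
#' @param sdlog standard deviation on the natural-log scale.
#' @return a law specification list.
#' @export
lognormal_law <- function(median = 5, sdlog = 1) {
  list(dist = "lognormal", meanlog = log(median), sdlog = sdlog)
}

law_mode <- function(law) exp(law$meanlog - law$sdlog^2)

draw_counts <- function(n, law) {
  pmax(1L, as.integer(round(stats::rlnorm(n, law$meanlog, law$sdlog))))
}

#' Architecture specification for synthetic circuits
#'
#' Describes one of three planted wiring architectures between input neurons,
#' hub (region-intrinsic) neurons, and output neurons: `labeled_line`
#' (dedicated one-to-one channels), `mixed` (all-to-all), or
#' `convergence_divergence` (many-to-one fan-in, one-to-many fan-out through
#' the hub bottleneck).
#'
#' @param kind one of `"labeled_line"`, `"mixed"`, `"convergence_divergence"`.
#' @param n_hub,n_in,n_out neuron counts per role.
#' @param fan_in,fan_out inputs/outputs per hub (convergence-divergence only).
#' @param weight_law synapse-count law for edge weights, see [lognormal_law()].
#' @param seed integer seed.
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(kind = c("labeled_line", "mixed",
                                       "convergence_divergence"),
                              n_hub, n_in, n_out,
                              fan_in = NULL, fan_out = NULL,
                              weight_law = lognormal_law(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_hub >= 1, n_in >= 1, n_out >= 1)
  if (kind == "labeled_line" && (n_in < n_hub || n_out < n_hub)) {
    stop("labeled_line requires n_in >= n_hub and n_out >= n_hub")
  }
  if (kind == "convergence_divergence") {
    if (is.null(fan_in) || is.null(fan_out)) {
      stop("convergence_divergence requires fan_in and fan_out")
    }
    stopifnot(fan_in >= 1, fan_out >= 1)
    if (fan_in > n_in) stop("fan_in exceeds n_in")
    if (fan_out > n_out) stop("fan_out exceeds n_out")
  }
  structure(list(kind = kind, n_hub = as.integer(n_hub),
                 n_in = as.integer(n_in), n_out = as.integer(n_out),
                 fan_in = fan_in, fan_out = fan_out,
                 weight_law = weight_law, seed = as.integer(seed)),
            class = "architecture_spec")
}

pad_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

# dedicated partner assignment: shuffled pool consumed in blocks, cycling
# (round-robin overflow) when the pool is exhausted, so partner sets within a
# hub are drawn without replacement and across hubs are disjoint while the
# pool lasts
assign_partners <- function(pool, n_hub, fan) {
  shuffled <- sample(pool)
  out <- vector("list", n_hub)
  pos <- 0L
  for (h in seq_len(n_hub)) {
    idx <- ((pos + seq_len(fan) - 1L) %% length(shuffled)) + 1L
    out[[h]] <- shuffled[idx]
    pos <- pos + fan
  }
  out
}

#' Generate a planted wiring architecture
#'
#' @param spec an [architecture_spec()].
#' @return list with `graph` (a `conn_graph`), and `ground_truth`
#'   (data.frame `id`, `role` in hub/input/output, `architecture`).
#' @export
generate_architecture <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  with_seed(spec$seed, {
    hubs <- pad_ids("hub", spec$n_hub)
    ins <- pad_ids("in", spec$n_in)
    outs <- pad_ids("out", spec$n_out)
    edges <- switch(spec$kind,
      labeled_line = {
        up <- sample(ins, spec$n_hub)
        dn <- sample(outs, spec$n_hub)
        rbind(data.frame(pre = up, post = hubs),
              data.frame(pre = hubs, post = dn))
      },
      mixed = {
        rbind(expand.grid(pre = ins, post = hubs, stringsAsFactors = FALSE),
              expand.grid(pre = hubs, post = outs, stringsAsFactors = FALSE))
      },
      convergence_divergence = {
        up <- assign_partners(ins, spec$n_hub, spec$fan_in)
        dn <- assign_partners(outs, spec$n_hub, spec$fan_out)
        rbind(
          data.frame(pre = unlist(up), post = rep(hubs, each = spec$fan_in)),
          data.frame(pre = rep(hubs, each = spec$fan_out), post = unlist(dn)))
      })
    edges$weight <- draw_counts(nrow(edges), spec$weight_law)
    gt <- data.frame(
      id = c(hubs, ins, outs),
      role = rep(c("hub", "input", "output"),
                 c(spec$n_hub, spec$n_in, spec$n_out)),
      architecture = spec$kind, stringsAsFactors = FALSE)
    list(graph = conn_graph(edges, nodes = gt$id, threshold = 1L),
         ground_truth = gt, spec = spec)
  })
}

#' Generate a bimodal fragment/complete neuron population
#'
#' Real reconstructions mix partially-traced short fragments with well-traced
#' neurons, giving bimodal pooled synapse-count distributions; this generator
#' emulates that by drawing per-neuron pre- and post-synaptic site counts from
#' two log-normal laws with separated modes.
#'
#' @param n_complete,n_fragment population sizes.
#' @param complete_law,fragment_law count laws, see [lognormal_law()]. Default
#'   modes near 300 (well-traced) and 8 (fragment).
#' @param seed integer seed.
#' @param min_mode_ratio required separation factor between the two modes;
#'   below it the output carries `mode_overlap_warning = TRUE`.
#' @return data.frame `id`, `n_pre`, `n_post`, `completeness`
#'   (`"complete"`/`"fragment"`), with attribute `mode_overlap_warning`.
#' @export
generate_fragment_population <- function(n_complete, n_fragment,
                                         complete_law = lognormal_law(350, 0.5),
                                         fragment_law = lognormal_law(10, 0.5),
                                         seed = 1L, min_mode_ratio = 4) {
  warn <- FALSE
  if (n_fragment > 0L && n_complete > 0L) {
    ratio <- law_mode(complete_law) / law_mode(fragment_law)
    if (ratio < min_mode_ratio) warn <- TRUE
  }
  out <- with_seed(seed, {
    data.frame(
      id = pad_ids("frag", n_complete + n_fragment),
      n_pre = c(draw_counts(n_complete, complete_law),
                draw_counts(n_fragment, fragment_law)),
      n_post = c(draw_counts(n_complete, complete_law),
                 draw_counts(n_fragment, fragment_law)),
      completeness = rep(c("complete", "fragment"), c(n_complete, n_fragment)),
      stringsAsFactors = FALSE)
  })
  attr(out, "mode_overlap_warning") <- warn
  out
}

#' Uniform fraction law on an interval
#'
#' @param min,max support bounds.
#' @return a fraction-law list.
#' @export
uniform_law <- function(min, max) list(dist = "uniform", min = min, max = max)

#' Generate a region-intrinsic neuron population with synapse sites
#'
#' Intrinsic neurons place strictly more than 85% of their synaptic sites
#' inside the focal region; extrinsic neurons at most 85%. In-region site
#' counts are rounded up (intrinsic) or down (extrinsic) so the realised
#' per-neuron fractions respect the boundary exactly.
#'
#' @param n_intrinsic,n_extrinsic population sizes.
#' @param region region label for in-region sites.
#' @param intrinsic_frac_law fraction law supported on (0.85, 1].
#' @param extrinsic_frac_law fraction law supported on \[0, 0.85\].
#' @param sites_law per-polarity site-count law.
#' @param other_regions labels used for out-of-region sites.
#' @param seed integer seed.
#' @return list with `sites` (a `synapse_table`) and `ground_truth`
#'   (data.frame `id`, `intrinsic`, `pre_frac`, `post_frac`, `combined_frac`).
#' @export
generate_intrinsic_population <- function(n_intrinsic, n_extrinsic,
                                          region = "SMP",
                                          intrinsic_frac_law = uniform_law(0.88, 0.99),
                                          extrinsic_frac_law = uniform_law(0.05, 0.75),
                                          sites_law = lognormal_law(150, 0.4),
                                          other_regions = c("LH", "MB", "FB", "AVLP"),
                                          seed = 1L) {
  if (intrinsic_frac_law$min <= 0.85 || intrinsic_frac_law$max > 1) {
    stop("intrinsic_frac_law must be supported on (0.85, 1]")
  }
  if (extrinsic_frac_law$max > 0.85 || extrinsic_frac_law$min < 0) {
    stop("extrinsic_frac_law must be supported on [0, 0.85]")
  }
  with_seed(seed, {
    n <- n_intrinsic + n_extrinsic
    ids <- pad_ids("neu", n)
    intrinsic <- rep(c(TRUE, FALSE), c(n_intrinsic, n_extrinsic))
    frac <- ifelse(intrinsic,
                   stats::runif(n, intrinsic_frac_law$min, intrinsic_frac_law$max),
                   stats::runif(n, extrinsic_frac_law$min, extrinsic_frac_law$max))
    rows <- vector("list", n)
    gt <- data.frame(id = ids, intrinsic = intrinsic,
                     pre_frac = NA_real_, post_frac = NA_real_,
                     combined_frac = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      n_pre <- draw_counts(1L, sites_law)
      n_post <- draw_counts(1L, sites_law)
      k_pre <- if (intrinsic[i]) ceiling(frac[i] * n_pre) else floor(frac[i] * n_pre)
      k_post <- if (intrinsic[i]) ceiling(frac[i] * n_post) else floor(frac[i] * n_post)
      reg_pre <- c(rep(region, k_pre),
                   sample(other_regions, n_pre - k_pre, replace = TRUE))
      reg_post <- c(rep(region, k_post),
                    sample(other_regions, n_post - k_post, replace = TRUE))
      rows[[i]] <- data.frame(
        pre_id = c(rep(ids[i], n_pre), sprintf("bg%05d", sample.int(99999L, n_post))),
        post_id = c(sprintf("bg%05d", sample.int(99999L, n_pre)), rep(ids[i], n_post)),
        x = stats::runif(n_pre + n_post, 0, 3e5),
        y = stats::runif(n_pre + n_post, 0, 3e5),
        z = stats::runif(n_pre + n_post, 0, 3e5),
        region = c(reg_pre, reg_post),
        side = "right", stringsAsFactors = FALSE)
      gt$pre_frac[i] <- k_pre / n_pre
      gt$post_frac[i] <- k_post / n_post
      gt$combined_frac[i] <- (k_pre + k_post) / (n_pre + n_post)
    }
    sites <- do.call(rbind, rows)
    class(sites) <- c("synapse_table", "data.frame")
    list(sites = sites, ground_truth = gt)
  })
}

#' Generate a random binary-tree skeleton
#'
#' Grows a rooted binary tree: an initial segment from the root, then
#' `n_branchpoints` branch events, each converting one tip into a branch
#' point with two child segments, so a tree with `b` branch points has
#' exactly `b + 1` leaves.
#'
#' @param n_branchpoints number of branch events (>= 0).
#' @param segment_length_law uniform law for segment cable length (nm).
#' @param step node spacing along segments (nm).
#' @param smoothness direction persistence in (0, 1); higher values give
#'   locally smoother neurites (default 0.9, matching the local smoothness
#'   of traced processes at micrometre scale).
#' @param seed integer seed.
#' @param neuron_id identifier for the generated skeleton.
#' @return a [skeleton()] object.
#' @export
generate_skeleton <- function(n_branchpoints,
                              segment_length_law = uniform_law(8000, 20000),
                              step = 1000, smoothness = 0.9, seed = 1L,
                              neuron_id = "synthetic") {
  stopifnot(n_branchpoints >= 0, smoothness > 0, smoothness < 1)
  with_seed(seed, {
    rand_dir <- function(prev = NULL) {
      v <- stats::rnorm(3)
      if (!is.null(prev)) {
        v <- smoothness * prev + (1 - smoothness) * v / sqrt(sum(v^2))
      }
      v / sqrt(sum(v^2))
    }
    nodes <- data.frame(node_id = 1L, parent_id = NA_integer_,
                        x = 0, y = 0, z = 0, radius = 200)
    next_id <- 2L
    grow_segment <- function(from_id, dir0) {
      len <- stats::runif(1, segment_length_law$min, segment_length_law$max)
      m <- max(2L, as.integer(round(len / step)))
      dir <- dir0
      parent <- from_id
      pos <- as.numeric(nodes[match(from_id, nodes$node_id), c("x", "y", "z")])
      for (j in seq_len(m)) {
        dir <- rand_dir(dir)
        pos <- pos + step * dir
        nodes <<- rbind(nodes, data.frame(
          node_id = next_id, parent_id = parent,
          x = pos[1], y = pos[2], z = pos[3], radius = 100))
        parent <- next_id
        next_id <<- next_id + 1L
      }
      parent  # tip id
    }
    tips <- grow_segment(1L, rand_dir())
    for (b in seq_len(n_branchpoints)) {
      at <- tips[sample.int(length(tips), 1L)]
      tips <- setdiff(tips, at)
      tips <- c(tips, grow_segment(at, rand_dir()), grow_segment(at, rand_dir()))
    }
    skeleton(nodes, neuron_id = neuron_id)
  })
}

#' Place synapses on a skeleton with class-specific distance bias
#'
#' Each class places `count` synapses on skeleton nodes with probability
#' proportional to the node's incident cable length times
#' `exp(-bias_strength * d)` (proximal), `exp(+bias_strength * d)` (distal)
#' or 1 (uniform), where `d` is the node's geodesic distance from the root
#' normalised to \[0, 1\]. Bias strength 0 is exactly the uniform case.
#'
#' @param skel a [skeleton()] object.
#' @param classes list of lists with fields `label`, `count`,
#'   `bias` (`"proximal"`, `"distal"`, `"uniform"`), `strength`.
#' @param seed integer seed.
#' @return data.frame `node_id`, `class`, `bias`, `strength`.
#' @export
place_synapses <- function(skel, classes, seed = 1L) {
  nd <- skel$nodes
  pi_ <- match(nd$parent_id, nd$node_id)
  elen <- ifelse(is.na(pi_), 0,
                 sqrt((nd$x - nd$x[pi_])^2 + (nd$y - nd$y[pi_])^2 +
                      (nd$z - nd$z[pi_])^2))
  # half of each edge's cable accrues to both endpoints
  base_w <- elen / 2
  for (i in which(!is.na(pi_))) base_w[pi_[i]] <- base_w[pi_[i]] + elen[i] / 2
  d <- geodesic_distances(skel, skel$root)
  d_norm <- if (max(d) > 0) d / max(d) else d
  with_seed(seed, {
    out <- lapply(classes, function(cl) {
      stopifnot(cl$count >= 1)
      bias <- match.arg(cl$bias, c("proximal", "distal", "uniform"))
      s <- if (bias == "uniform") 0 else cl$strength
      sign <- switch(bias, proximal = -1, distal = 1, uniform = 0)
      w <- base_w * exp(sign * s * d_norm)
      if (sum(w) <= 0) w <- rep(1, length(w))
      picked <- sample(nd$node_id, cl$count, replace = TRUE, prob = w)
      data.frame(node_id = picked, class = cl$label, bias = bias,
                 strength = s, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate a complete synthetic brain
#'
#' Assembles a full testbed: a planted architecture, synapse sites realising
#' its edges with region labels such that every hub is strictly region
#' intrinsic (> 85% of sites in-region) and every non-hub neuron is not
#' (extra out-of-region background sites dilute them to <= 80%), transmitter
#' labels drawn per role, and optional skeletons for hub neurons.
#'
#' @param spec an [architecture_spec()].
#' @param region region label for in-region synapses.
#' @param intrinsic_frac_law hub in-region fraction law on (0.85, 1].
#' @param other_regions labels for out-of-region sites.
#' @param skeletons `"none"` or `"hubs"`; skeletons are costly, generate only
#'   when the morphology/topology stages will run.
#' @param n_branchpoints branch points per generated skeleton.
#' @return list with `graph`, `sites`, `neurons` (metadata), `skeletons`
#'   (named list), `ground_truth`.
#' @export
generate_brain <- function(spec, region = "SMP",
                           intrinsic_frac_law = uniform_law(0.88, 0.99),
                           other_regions = c("LH", "MB", "FB", "AVLP"),
                           skeletons = c("none", "hubs"),
                           n_branchpoints = 7L) {
  skeletons <- match.arg(skeletons)
  arch <- generate_architecture(spec)
  gt <- arch$ground_truth
  with_seed(spec$seed + 1000003L, {
    ed <- arch$graph$edges
    # expand edges to one row per synaptic site
    n_sites <- sum(ed$weight)
    sites <- data.frame(
      pre_id = rep(ed$pre, ed$weight), post_id = rep(ed$post, ed$weight),
      x = stats::runif(n_sites, 0, 3e5), y = stats::runif(n_sites, 0, 3e5),
      z = stats::runif(n_sites, 0, 3e5),
      region = NA_character_, side = "right", stringsAsFactors = FALSE)
    hubs <- gt$id[gt$role == "hub"]
    # per-hub intrinsic fraction; a site incident to a hub is in-region unless
    # rationed out, with the in-region count rounded up so fractions stay
    # strictly above the boundary
    hub_frac <- stats::setNames(
      stats::runif(length(hubs), intrinsic_frac_law$min, intrinsic_frac_law$max),
      hubs)
    touches_hub <- sites$pre_id %in% hubs | sites$post_id %in% hubs
    sites$region[!touches_hub] <- sample(other_regions, sum(!touches_hub),
                                         replace = TRUE)
    for (h in hubs) {
      # allocate in-region sites per polarity so both the pre- and the
      # post-fraction clear the boundary (hubs never synapse onto hubs in
      # the planted architectures, so allocations cannot collide)
      for (idx in list(which(sites$pre_id == h), which(sites$post_id == h))) {
        if (length(idx) == 0L) next
        k <- ceiling(hub_frac[[h]] * length(idx))
        inreg <- if (k >= length(idx)) idx else sample(idx, k)
        sites$region[inreg] <- region
        outreg <- setdiff(idx, inreg)
        sites$region[outreg] <- sample(other_regions, length(outreg),
                                       replace = TRUE)
      }
    }
    # dilute non-hub neurons below the boundary with background sites
    extra <- list()
    for (v in gt$id[gt$role != "hub"]) {
      tot <- sum(sites$pre_id == v) + sum(sites$post_id == v)
      inreg <- sum(sites$pre_id == v & sites$region == region) +
        sum(sites$post_id == v & sites$region == region)
      if (tot == 0) next
      need <- max(0L, ceiling(inreg / 0.80 - tot))
      if (need > 0L) {
        extra[[v]] <- data.frame(
          pre_id = v, post_id = sprintf("bg%05d", sample.int(99999L, need)),
          x = stats::runif(need, 0, 3e5), y = stats::runif(need, 0, 3e5),
          z = stats::runif(need, 0, 3e5),
          region = sample(other_regions, need, replace = TRUE),
          side = "right", stringsAsFactors = FALSE)
      }
    }
    sites <- rbind(sites, do.call(rbind, extra))
    class(sites) <- c("synapse_table", "data.frame")

    transmitter_pool <- list(
      hub = c(GABA = 0.28, glutamate = 0.27, dopamine = 0.2,
              acetylcholine = 0.15, serotonin = 0.06, octopamine = 0.04),
      input = c(acetylcholine = 0.6, glutamate = 0.2, GABA = 0.2),
      output = c(acetylcholine = 0.5, GABA = 0.3, glutamate = 0.2))
    gt$transmitter <- vapply(gt$role, function(r) {
      p <- transmitter_pool[[r]]
      sample(names(p), 1L, prob = p)
    }, "")
    neurons <- data.frame(
      id = gt$id, hemisphere = "right",
      cell_type = paste0("type_", sub("[0-9]+$", "", gt$id)),
      transmitter = gt$transmitter,
      n_pre = vapply(gt$id, function(v) sum(sites$pre_id == v), 0L),
      n_post = vapply(gt$id, function(v) sum(sites$post_id == v), 0L),
      stringsAsFactors = FALSE)

    skels <- list()
    if (skeletons == "hubs") {
      skels <- lapply(seq_along(hubs), function(i) {
        generate_skeleton(n_branchpoints, seed = spec$seed * 131L + i,
                          neuron_id = hubs[i])
      })
      names(skels) <- hubs
    }
    gt$intrinsic_frac <- NA_real_
    gt$intrinsic_frac[match(hubs, gt$id)] <- unname(hub_frac)
    list(graph = arch$graph, sites = sites, neurons = neurons,
         skeletons = skels, ground_truth = gt, region = region, spec = spec)
  })
}
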