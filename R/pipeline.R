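# Config-driven orchestration of the full analysis: synthesize/ingest ->
# detect intrinsic neurons -> connectivity atlas -> architecture tests ->
# multilayer tracing -> morphology -> dendritic topology. Each stage writes
# machine-readable reports stamped with the config hash and seed.

#' Build a pipeline run configuration
#'
#' @param out_dir output directory for stage reports.
#' @param seed global seed; per-stage seeds derive from it by a fixed counter
#'   scheme (`seed + 101 * stage_index`), so stages are independently
#'   reproducible.
#' @param synthetic an [architecture_spec()] describing the synthetic brain
#'   to generate (dataset ingestion alternatively via `sites_path` +
#'   `metadata_path`).
#' @param sites_path,metadata_path optional CSV inputs instead of synthesis.
#' @param region region label(s) defining the focal neuropil.
#' @param edge_threshold minimum synapses per connection (default 2).
#' @param intrinsic_rule,intrinsic_threshold see [select_intrinsic()].
#' @param atlas_params list: `n_neighbors`, `min_dist`, `n_components`,
#'   `min_cluster_size`, `min_samples`, `k_density`.
#' @param n_shuffles replicates for entropy/motif nulls.
#' @param skeletons whether the synthetic brain carries hub skeletons
#'   (enables the morphology and dendritic stages).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       synthetic = architecture_spec("convergence_divergence",
                                                     n_hub = 20, n_in = 160,
                                                     n_out = 140, fan_in = 8,
                                                     fan_out = 7, seed = seed),
                       sites_path = NULL, metadata_path = NULL,
                       region = "SMP", edge_threshold = 2L,
                       intrinsic_rule = "both_polarity",
                       intrinsic_threshold = 0.85,
                       atlas_params = list(n_neighbors = 15L, min_dist = 0.1,
                                           n_components = 3L,
                                           min_cluster_size = 10L,
                                           min_samples = 10L, k_density = 10L),
                       n_shuffles = 100L, skeletons = "hubs") {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              synthetic = synthetic, sites_path = sites_path,
              metadata_path = metadata_path, region = region,
              edge_threshold = as.integer(edge_threshold),
              intrinsic_rule = intrinsic_rule,
              intrinsic_threshold = intrinsic_threshold,
              atlas_params = atlas_params, n_shuffles = as.integer(n_shuffles),
              skeletons = skeletons)
  if (!intrinsic_rule %in% c("both_polarity", "combined")) {
    stop("invalid intrinsic_rule: ", intrinsic_rule)
  }
  if (!is.character(region) || any(!nzchar(region))) {
    stop("invalid region name")
  }
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  # small stable fingerprint without extra dependencies
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

stage_seed <- function(cfg, index) cfg$seed + 101L * index

write_report <- function(cfg, stage, payload) {
  payload$meta <- list(stage = stage, config_hash = config_hash(cfg),
                       seed = cfg$seed,
                       package_version = as.character(utils::packageVersion("circuitome")))
  jsonlite::write_json(payload, file.path(cfg$out_dir,
                                          paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing a JSON report (plus CSVs where a
#' stage has tabular output) per stage into `cfg$out_dir`. On stage failure,
#' completed outputs are left intact and a `FAILED` manifest names the stage.
#'
#' @param cfg a [run_config()].
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  # out_dir is implied by the file's location and would differ between
  # otherwise identical runs
  jsonlite::write_json(cfg[setdiff(names(cfg), c("synthetic", "out_dir"))],
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, force = TRUE, pretty = TRUE)
  results <- list()
  current_stage <- NA_character_
  run_stage <- function(name, fun) {
    current_stage <<- name
    results[[name]] <<- fun()
  }
  tryCatch({
    # 1. data
    run_stage("data", function() {
      if (!is.null(cfg$sites_path)) {
        sites <- read_synapse_table(cfg$sites_path)
        neurons <- read_neuron_metadata(cfg$metadata_path)
        brain <- list(sites = sites, neurons = neurons,
                      graph = build_connectivity(sites, cfg$edge_threshold),
                      skeletons = list(), ground_truth = NULL)
      } else {
        brain <- generate_brain(cfg$synthetic, region = cfg$region,
                                skeletons = cfg$skeletons)
      }
      write_edge_list(brain$graph, file.path(cfg$out_dir, "edges.csv"))
      write_neuron_metadata(brain$neurons,
                            file.path(cfg$out_dir, "neurons.csv"))
      write_report(cfg, "data",
                   list(n_neurons = nrow(brain$neurons),
                        n_sites = nrow(brain$sites),
                        n_edges = nrow(brain$graph$edges)))
      brain
    })
    brain <- results$data

    # 2. intrinsic detection
    run_stage("intrinsic", function() {
      fr <- compute_region_fractions(brain$sites, cfg$region,
                                     neuron_ids = brain$neurons$id)
      sel <- select_intrinsic(fr, rule = cfg$intrinsic_rule,
                              threshold = cfg$intrinsic_threshold)
      curve <- tryCatch(fit_fraction_curve(fr), error = function(e) NULL)
      utils::write.csv(data.frame(id = sort(sel)),
                       file.path(cfg$out_dir, "intrinsic_ids.csv"),
                       row.names = FALSE, quote = FALSE)
      write_report(cfg, "intrinsic", list(
        n_selected = length(sel), rule = cfg$intrinsic_rule,
        threshold = cfg$intrinsic_threshold,
        curve = if (!is.null(curve)) {
          list(a = curve$coefficients[["a"]], b = curve$coefficients[["b"]],
               c = curve$coefficients[["c"]], r_squared = curve$r_squared)
        }))
      list(fractions = fr, selected = sel, curve = curve)
    })
    hubs <- results$intrinsic$selected
    graph <- threshold_graph(brain$graph, cfg$edge_threshold)

    # 3. connectivity atlas
    run_stage("atlas", function() {
      ap <- cfg$atlas_params
      fm <- build_feature_matrix(graph, hubs)
      emb <- embed_umap(fm, n_neighbors = ap$n_neighbors,
                        min_dist = ap$min_dist,
                        n_components = ap$n_components,
                        seed = stage_seed(cfg, 3L))
      labels <- cluster_embedding(emb$coords,
                                  min_cluster_size = ap$min_cluster_size,
                                  min_samples = ap$min_samples)
      dens <- local_density(fm, k = ap$k_density)
      ward <- ward_cluster(bray_curtis_matrix(fm$features))
      utils::write.csv(
        data.frame(id = rownames(emb$coords), emb$coords,
                   hdbscan = labels, ward = as.integer(ward),
                   density = dens),
        file.path(cfg$out_dir, "atlas.csv"), row.names = FALSE)
      write_report(cfg, "atlas", list(
        params = ap, n_hubs = length(hubs),
        n_clusters = attr(labels, "n_clusters"),
        n_noise = sum(labels == -1L),
        ward_k = attr(ward, "k")))
      list(features = fm, embedding = emb, hdbscan = labels, ward = ward,
           density = dens)
    })

    # 4. architecture tests
    run_stage("architecture", function() {
      bat <- architecture_battery(graph, hubs, direction = "input",
                                  n_replicates = cfg$n_shuffles,
                                  seed = stage_seed(cfg, 4L))
      nsp_in <- motif_nsp(graph, hubs, side = "input",
                          n_shuffles = cfg$n_shuffles,
                          edge_threshold = cfg$edge_threshold,
                          seed = stage_seed(cfg, 4L))
      nsp_out <- motif_nsp(graph, hubs, side = "output",
                           n_shuffles = cfg$n_shuffles,
                           edge_threshold = cfg$edge_threshold,
                           seed = stage_seed(cfg, 4L) + 1L)
      utils::write.csv(bat$entropies,
                       file.path(cfg$out_dir, "hub_entropies.csv"),
                       row.names = FALSE)
      write_report(cfg, "architecture", list(
        classified = bat$classified,
        rejected = as.list(bat$rejected),
        p_labeled_line = bat$labeled_line$p_value,
        p_mixed = bat$mixed$p_value,
        shuffled_z = bat$shuffled$statistic,
        nsp_input = as.list(stats::setNames(nsp_in$nsp, names(nsp_in$counts))),
        nsp_output = as.list(stats::setNames(nsp_out$nsp, names(nsp_out$counts)))))
      list(battery = bat, nsp_input = nsp_in, nsp_output = nsp_out)
    })

    # 5. multilayer tracing
    run_stage("multilayer", function() {
      gt <- brain$ground_truth
      if (is.null(gt)) return(NULL)
      srcs <- gt$id[gt$role == "input"]
      thirds <- split(srcs, rep(1:3, length.out = length(srcs)))
      names(thirds) <- c("olfactory", "mechanosensory", "visual")
      prof <- multilayer_profile(graph, thirds, targets = hubs,
                                 max_layers = 3L)
      utils::write.csv(prof$strength,
                       file.path(cfg$out_dir, "multilayer.csv"),
                       row.names = FALSE)
      write_report(cfg, "multilayer", list(
        max_layers = prof$max_layers,
        peak_layer = with(stats::aggregate(strength ~ layer,
                                           prof$strength, sum),
                          layer[which.max(strength)])))
      prof
    })

    # 6 + 7. morphology and dendritic topology (need skeletons)
    if (length(brain$skeletons) >= 2L) {
      run_stage("morphology", function() {
        dps <- lapply(brain$skeletons, make_dotprops)
        sim <- nblast_matrix(dps)
        labels <- results$atlas$ward[match(names(dps),
                                           rownames(results$atlas$features$features))]
        names(labels) <- names(dps)
        ens <- identify_ensembles(labels, sim)
        utils::write.csv(ens, file.path(cfg$out_dir, "ensembles.csv"),
                         row.names = FALSE)
        write_report(cfg, "morphology", list(
          n_neurons = length(dps), n_accepted = sum(ens$accepted)))
        list(similarity = sim, ensembles = ens)
      })
      run_stage("dendritic", function() {
        skel <- brain$skeletons[[1L]]
        syn <- place_synapses(skel, list(
          list(label = "inhibitory", count = 150, bias = "proximal",
               strength = 3),
          list(label = "excitatory", count = 300, bias = "distal",
               strength = 3)), seed = stage_seed(cfg, 7L))
        syn$x <- skel$nodes$x[match(syn$node_id, skel$nodes$node_id)]
        syn$y <- skel$nodes$y[match(syn$node_id, skel$nodes$node_id)]
        syn$z <- skel$nodes$z[match(syn$node_id, skel$nodes$node_id)]
        syn$polarity <- "post"
        ann <- assign_synapses(skel, syn)
        dd <- class_distance_distributions(ann, reference = "root",
                                           group_by = "class")
        test <- proximal_bias_test(
          dd$distance[dd$class == "inhibitory"],
          dd$distance[dd$class == "excitatory"],
          n_permutations = 2000L, seed = stage_seed(cfg, 7L))
        utils::write.csv(dd, file.path(cfg$out_dir, "geodesic.csv"),
                         row.names = FALSE)
        write_report(cfg, "dendritic", list(
          statistic = test$statistic, p_value = test$p_value,
          direction = test$direction))
        list(distances = dd, test = test)
      })
    }
    invisible(results)
  }, error = function(e) {
    writeLines(c(paste("stage:", current_stage), paste("error:",
                                                       conditionMessage(e))),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}
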