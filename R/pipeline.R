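#' Pipeline configuration
#'
#' A single list of every stage parameter, defaulting to the conventional
#' analysis settings: top 20% abundance rank, prevalence > 60%, |rho| > 0.6,
#' FDR q < 0.01, cluster alpha 0.05, Zi/Pi thresholds 2.5/0.62, 999 MRM and
#' 9,999 Mantel permutations. When no input paths are given the synthetic
#' stage runs with the bundled study conditions (90 samples, pH 4.5-9,
#' 600 bacterial + 100 fungal taxa, 8 guilds, 20,000 reads/sample).
#'
#' @param ... overrides of any default (e.g. `rho_min = 0.8`,
#'   `otu_path = "otu.tsv"`); unknown names are an error.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    schema = 1L,
    seed = 1L,
    # inputs; NULL means simulate
    otu_path = NULL, kingdom_path = NULL, env_path = NULL,
    # synthetic stage
    n_samples = 90, ph_min = 4.5, ph_max = 9, n_covariates = 19,
    cov_cor = 0.4, n_bacteria = 600, n_fungi = 100, n_guilds = 8,
    frac_low_ph = 0.5, guild_member_frac = 0.5, guild_low_ph_weight = 0.8,
    depth = 20000, dispersion = 10,
    # filtering
    top_frac = 0.2, min_prev = 0.6, per_kingdom = TRUE,
    # network
    rho_min = 0.6, q_max = 0.01, use_abs = TRUE,
    # ecology
    cluster_alpha = 0.05,
    # keystone
    module_method = "greedy", zi_threshold = 2.5, pi_threshold = 0.62,
    # robustness
    rob_fractions = seq(0, 0.8, by = 0.05), rob_reps = 100,
    # drivers
    mrm_perm = 999, mantel_perm = 9999, screen_rho2 = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  stop_if_not(length(bad) == 0,
              paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of config overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full co-occurrence analysis pipeline
#'
#' Stages, in dependency order: load or simulate inputs; convert to relative
#' abundances; select core taxa; all-pairs Spearman + BH; build the
#' thresholded network; node/network topology and per-sample subnetworks;
#' pH ecological clusters and niche breadth; module detection, Zi-Pi and
#' keystone classification; cluster robustness curves; MRM feature drivers
#' and Mantel edge-count drivers. All outputs are written under `out_dir`
#' together with a provenance manifest (config, seed, file list); reruns
#' with the same config are bit-identical.
#'
#' @param config a `pipeline_config` (or YAML path).
#' @param out_dir output directory.
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stop_if_not(inherits(config, "pipeline_config"), "invalid config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  res <- list(config = cfg)
  truth <- NULL
  if (is.null(cfg$otu_path)) {
    sim <- stage("simulate", simulate_community(
      n_samples = cfg$n_samples, ph_min = cfg$ph_min, ph_max = cfg$ph_max,
      n_covariates = cfg$n_covariates, cov_cor = cfg$cov_cor,
      n_bacteria = cfg$n_bacteria, n_fungi = cfg$n_fungi,
      n_guilds = cfg$n_guilds, frac_low_ph = cfg$frac_low_ph,
      guild_member_frac = cfg$guild_member_frac,
      guild_low_ph_weight = cfg$guild_low_ph_weight,
      depth = cfg$depth, dispersion = cfg$dispersion, seed = cfg$seed))
    otu <- sim$otu
    env <- sim$env
    truth <- sim$truth
    write_simulation(sim, file.path(out_dir, "simulated_input"))
  } else {
    otu <- stage("read_otu", read_otu_table(cfg$otu_path,
                                            kingdom_path = cfg$kingdom_path))
    env <- stage("read_env", read_env_table(cfg$env_path))
  }
  stop_if_not(nrow(env) == ncol(otu), "env/OTU sample mismatch")
  res$env <- env
  res$otu <- otu
  res$truth <- truth

  rel <- stage("to_relative", to_relative(otu))
  core <- stage("filter", select_core(rel, cfg$top_frac, cfg$min_prev,
                                      cfg$per_kingdom))
  res$core <- core
  write.csv(core$report, file.path(out_dir, "core_taxa.csv"),
            row.names = FALSE)

  corr <- stage("correlate", spearman_all_pairs(rel, core$taxon_ids))
  net <- stage("network", build_network(corr, rel, cfg$rho_min, cfg$q_max,
                                        cfg$use_abs))
  res$network <- net
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  write_network(net, file.path(out_dir, "network_edges.tsv"), "edge_list")
  jsonlite::write_json(as.list(net$summary),
                       file.path(out_dir, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  if (nrow(net$nodes) == 0) {
    warning("network has no nodes at these thresholds; ",
            "graph-level stages skipped")
    nodes <- data.frame(node = character(), degree = numeric(),
                        betweenness = numeric(), closeness = numeric(),
                        eigenvector = numeric())
    part <- NULL
    topo <- NULL
  } else {
    nodes <- stage("node_features", node_features(net))
    part <- stage("modules", detect_modules(net, method = cfg$module_method,
                                            seed = cfg$seed))
    topo <- stage("topology", network_features(net, partition = part))
  }
  write.csv(nodes, file.path(out_dir, "node_features.csv"), row.names = FALSE)
  if (!is.null(topo)) {
    jsonlite::write_json(topo, file.path(out_dir, "network_topology.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  pst <- stage("per_sample", per_sample_topology(net, rel, seed = cfg$seed))
  write.csv(pst, file.path(out_dir, "per_sample_topology.csv"),
            row.names = FALSE)
  res$node_features <- nodes
  res$topology <- topo
  res$per_sample <- pst

  clus <- stage("clusters", assign_clusters(rel, env$pH,
                                            alpha = cfg$cluster_alpha))
  b <- stage("niche", niche_breadth(rel))
  clus$niche_breadth <- unname(b[clus$taxon_id])
  write.csv(clus, file.path(out_dir, "clusters_niche.csv"), row.names = FALSE)
  res$clusters <- clus

  if (!is.null(part)) {
    roles <- stage("zipi", classify_roles(zi_pi(net, part),
                                          cfg$zi_threshold, cfg$pi_threshold))
    write.csv(roles, file.path(out_dir, "zipi_roles.csv"), row.names = FALSE)
    res$roles <- roles
  }

  cl <- setNames(clus$cluster, clus$taxon_id)
  cl <- cl[cl %in% c("high_pH", "low_pH")]
  cl <- cl[names(cl) %in% net$nodes$taxon_id]
  if (length(unique(cl)) == 2) {
    curves <- stage("robustness", compare_cluster_robustness(
      net, cl, fractions = cfg$rob_fractions, n_reps = cfg$rob_reps,
      seed = cfg$seed))
    rob <- do.call(rbind, lapply(names(curves), function(g) {
      cbind(data.frame(group = g), as.data.frame(curves[[g]]))
    }))
    write.csv(rob, file.path(out_dir, "robustness_curves.csv"),
              row.names = FALSE)
    res$robustness <- curves
  }

  vars <- setdiff(names(env), "sample_id")
  if (!is.null(cfg$screen_rho2)) {
    vars <- stage("screen_env", screen_env(env, cfg$screen_rho2))
  }
  drv <- stage("drivers", feature_driver_table(
    pst, env, variables = vars, n_perm = cfg$mrm_perm, seed = cfg$seed))
  if (!is.null(drv)) {
    write.csv(drv, file.path(out_dir, "feature_drivers.csv"),
              row.names = FALSE)
    res$drivers <- drv
  }
  mant <- stage("edge_drivers", edge_count_driver_analysis(
    pst, env, variables = vars, n_perm = cfg$mantel_perm, seed = cfg$seed))
  write.csv(mant, file.path(out_dir, "edge_count_drivers.csv"),
            row.names = FALSE)
  res$edge_drivers <- mant

  manifest <- list(
    package = "soilcooc",
    config = cfg[setdiff(names(cfg), "schema")],
    files = sort(setdiff(list.files(out_dir, recursive = TRUE),
                         "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
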