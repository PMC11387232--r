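#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates motif-cluster selection, stratified network building,
#' hierarchy reconstruction, structural properties, degree-distribution
#' fitting and genome-context analysis, writing each stage's table under
#' `out_dir` together with a manifest. The configuration (a YAML/JSON file
#' or an equivalent list) names either a `synthetic` block (a
#' [synth_config()] parameter list — inputs are generated) or an `inputs`
#' block with `genome`, `hits` and `clusters` paths. Identical configuration
#' and seed reproduce byte-identical numeric outputs.
#'
#' @param config path to a YAML config, or a list.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return List with the built objects (`genome`, `network`, `layering`,
#'   `properties`, `fits`, ...) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) abort("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages)) {
    stages <- c("cluster", "build", "hierarchy", "props", "fit", "context")
  }

  manifest <- list(seed = seed, stages = as.list(stages), counts = list())

  if (!is.null(config$synthetic)) {
    cfg <- do.call(synth_config, c(config$synthetic, list(seed = seed)))
    synth <- generate_synthetic_dataset(cfg, file.path(out_dir, "inputs"))
    genome <- synth$genome
    hits <- synth$hits
    clusters <- synth$pwms$clusters
    manifest$inputs <- lapply(synth$files, normalizePath)
  } else {
    inp <- config$inputs
    for (need in c("genome", "hits", "clusters")) {
      if (is.null(inp[[need]]) || !file.exists(inp[[need]])) {
        abort(paste0("config inputs must name an existing '", need, "' file"))
      }
    }
    genome <- read_genome_tsv(inp$genome)
    hits <- read_scan_hits(inp$hits)
    clusters <- parse_cluster_file(inp$clusters, genome)
    manifest$inputs <- lapply(inp, normalizePath)
  }
  manifest$counts$genome_genes <- nrow(genome)
  manifest$counts$scan_hits <- nrow(hits)
  manifest$counts$clusters_in <- length(clusters)

  out <- list(genome = genome, manifest = manifest)

  selection <- NULL
  if ("cluster" %in% stages) {
    selection <- select_clustered_tf_clusters(clusters, genome)
    write_cluster_selection(selection, file.path(out_dir, "selected_clusters.tsv"))
    manifest$counts$clusters_kept <- length(selection$clusters)
    manifest$counts$clustered_tf_genes <- length(selection$genes)
    out$selection <- selection
  }

  net <- NULL
  if ("build" %in% stages) {
    if (is.null(selection)) abort("'build' requires the 'cluster' stage")
    net <- stratified_target_search(selection$tfs, selection$genes, hits,
                                    genome = genome,
                                    name = config$name %||% "clustered-TF network")
    write_edge_list(net, file.path(out_dir, "network_edges.tsv"))
    write_sif(net, file.path(out_dir, "network.sif"))
    readr::write_tsv(tier_composition(net), file.path(out_dir, "tier_composition.tsv"))
    manifest$counts$network_nodes <- nrow(net$nodes)
    manifest$counts$network_edges <- nrow(net$edges)
    out$network <- net
  }

  if ("hierarchy" %in% stages && !is.null(net) && nrow(net$edges) > 0L) {
    layering <- layer_hierarchy(net)
    write_layering(layering, net, file.path(out_dir, "hierarchy_layers.tsv"))
    readr::write_tsv(layering$ascendant_edges,
                     file.path(out_dir, "ascendant_edges.tsv"))
    manifest$counts$hierarchy_layers <- layering$n_layers
    out$layering <- layering
    out$bfs <- bfs_hierarchy(net, root = "auto")
  }

  if ("props" %in% stages && !is.null(net) && nrow(net$nodes) >= 3L) {
    props <- compute_properties(net)
    readr::write_tsv(props, file.path(out_dir, "properties.tsv"))
    manifest$counts$properties <- length(PROPERTY_NAMES)
    out$properties <- props
  }

  if ("fit" %in% stages && !is.null(net)) {
    degs <- network_degrees(net)
    if (length(degs) >= 10L && length(unique(degs)) > 1L) {
      fits <- fit_distributions(degs)
      readr::write_tsv(fits, file.path(out_dir, "degree_fits.tsv"))
      out$fits <- fits
      out$preference <- preference_report(setNames(list(fits), net$name))
    }
  }

  if ("context" %in% stages && !is.null(net)) {
    regulons <- build_regulons(net, genome)
    manifest$counts$regulons <- length(regulons)
    groups <- find_neighbor_groups(net$nodes$gene, genome)
    readr::write_tsv(groups, file.path(out_dir, "neighbor_groups.tsv"))
    manifest$counts$neighbor_groups <- length(unique(groups$group))
    out$regulons <- regulons
    out$neighbor_groups <- groups
  }

  out$manifest <- manifest
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
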