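#' Stratified three-tier target search
#'
#' Assembles a regulatory network from scan hits by successive stringency
#' passes. Pass 1: every candidate hit by ANY regulator at p <= 1e-06
#' acquires edges from ALL regulators hitting it at that threshold
#' (tier STRICT) and leaves the candidate list. Pass 2: the remaining
#' candidates acquire MEDIUM edges from all regulators hitting them at
#' p <= 1e-05; pass 3 likewise at p <= 1e-04 (LOW). Thresholds are
#' inclusive. A target therefore holds edges in exactly one tier — the
#' strictest stratum any regulator reaches — and within that tier all
#' qualifying regulator edges are kept. Duplicate hits (a gene carries up to
#' five matrices) collapse to the minimum p-value per (regulator, target)
#' pair. Candidates never hit at p <= 1e-04 are excluded from the node set
#' unless `keep_isolated` is set.
#'
#' @param tfs character vector of regulator gene ids to search with.
#' @param candidates character vector of candidate target gene ids (may
#'   include the regulators themselves; self-regulations are retained).
#' @param hits scan-hit tibble (`tf_id`, `target_id`, `p_value`). Hits whose
#'   `tf_id` is not in `tfs` or whose `target_id` is not in `candidates` are
#'   ignored with a logged count.
#' @param tiers increasing p-value thresholds of the three passes.
#' @param genome optional `genome_table` for node flags; defaults flag the
#'   searched regulators as TFs.
#' @param keep_isolated keep never-targeted candidates as isolated nodes.
#' @param name network label.
#' @return A `reg_network` with per-edge `tier` and `p_value`.
#' @export
stratified_target_search <- function(tfs, candidates, hits,
                                     tiers = c(1e-06, 1e-05, 1e-04),
                                     genome = NULL, keep_isolated = FALSE,
                                     name = "clustered-TF network") {
  stopifnot(length(tiers) == 3L, all(diff(tiers) > 0))
  hits <- as_tibble(hits)
  if (nrow(hits) > 0L && any(hits$p_value <= 0)) {
    abort("non-positive p-value in hit table")
  }
  n_foreign <- sum(!(hits$tf_id %in% tfs) | !(hits$target_id %in% candidates))
  if (n_foreign > 0L) {
    inform(paste0(n_foreign, " hit(s) outside the searched TF/candidate sets ignored"))
  }
  hits <- filter(hits, .data$tf_id %in% tfs, .data$target_id %in% candidates)
  # up to five matrices per gene produce repeated hits: keep the minimum p
  hits <- hits |>
    group_by(.data$tf_id, .data$target_id) |>
    summarise(p_value = min(.data$p_value), .groups = "drop")

  remaining <- unique(candidates)
  edge_parts <- list()
  for (k in seq_along(tiers)) {
    pass <- filter(hits, .data$target_id %in% remaining,
                   .data$p_value <= tiers[k])
    if (nrow(pass) > 0L) {
      pass$tier <- TIER_LEVELS[k]
      edge_parts[[k]] <- pass
      remaining <- setdiff(remaining, unique(pass$target_id))
    }
  }
  edges <- if (length(edge_parts) > 0L) bind_rows(edge_parts) else {
    tibble(tf_id = character(0), target_id = character(0),
           p_value = numeric(0), tier = character(0))
  }
  edges <- tibble(tf = edges$tf_id, target = edges$target_id,
                  tier = edges$tier, p_value = edges$p_value)
  node_genes <- unique(c(edges$tf, edges$target))
  if (keep_isolated) node_genes <- unique(c(node_genes, candidates))
  if (!is.null(genome)) {
    nodes <- genome |>
      filter(.data$locus_tag %in% node_genes) |>
      select(gene = "locus_tag", "is_tf", "is_sigma")
    extra <- setdiff(node_genes, nodes$gene)
    if (length(extra) > 0L) {
      nodes <- bind_rows(nodes, tibble(gene = extra, is_tf = extra %in% tfs,
                                       is_sigma = FALSE))
    }
  } else {
    nodes <- tibble(gene = node_genes, is_tf = node_genes %in% tfs,
                    is_sigma = FALSE)
  }
  reg_network(edges, nodes = nodes, name = name)
}

#' Tier composition of a network
#'
#' Count and percentage of edges per stringency tier — the quality summary
#' used to verify that a network is dominated by strict (p <= 1e-06)
#' regulator-target relationships with well under a percent in the low tier.
#'
#' @param net a `reg_network` with edge tiers.
#' @return Tibble with `tier`, `n_edges`, `percent`.
#' @export
tier_composition <- function(net) {
  tiers <- factor(net$edges$tier, levels = TIER_LEVELS)
  counts <- table(tiers)
  total <- nrow(net$edges)
  tibble(tier = TIER_LEVELS,
         n_edges = as.integer(counts),
         percent = if (total > 0) 100 * as.integer(counts) / total else rep(0, 3L))
}

#' Extract regulons from a network
#'
#' One regulon per regulator with out-degree > 0: the regulator plus the set
#' of genes carrying its motif. Targets are annotated with ordinal and COG
#' letter when a genome is supplied.
#'
#' @param net a `reg_network`.
#' @param genome optional `genome_table` for annotation.
#' @return Named list of tibbles (one per regulator), each with columns
#'   `target`, `tier`, `p_value` and, with a genome, `ordinal`, `cog`,
#'   `is_tf`, `product`.
#' @export
build_regulons <- function(net, genome = NULL) {
  if (nrow(net$edges) == 0L) return(list())
  regs <- split(net$edges[, c("target", "tier", "p_value")], net$edges$tf)
  regs <- lapply(regs, as_tibble)
  if (!is.null(genome)) {
    ann <- select(genome, target = "locus_tag", "ordinal", "cog", "is_tf", "product")
    regs <- lapply(regs, function(r) left_join(r, ann, by = "target"))
  }
  regs
}

#' Most regulated genes
#'
#' Genes ranked by in-degree (times regulated), descending, ties broken
#' lexicographically by locus tag.
#'
#' @param net a `reg_network`.
#' @param k number of genes to report.
#' @return Tibble with `gene`, `in_degree`.
#' @export
most_regulated <- function(net, k = 5L) {
  if (k <= 0) abort("k must be positive")
  if (nrow(net$edges) == 0L) {
    return(tibble(gene = character(0), in_degree = integer(0)))
  }
  kin <- in_degrees(net)
  kin <- kin[kin > 0]
  ord <- order(-kin, names(kin))
  head(tibble(gene = names(kin)[ord], in_degree = as.integer(kin[ord])), k)
}

#' Regulators exclusive to each of two networks
#'
#' Set differences of the regulator sets (TFs plus sigma factors) of two
#' condition-dependent networks, used to contrast e.g. free-living growth
#' against the nitrogen-fixing bacteroid state. When a genome is supplied,
#' product annotations are attached so TF families can be tallied.
#'
#' @param netA,netB `reg_network` objects over the same genome.
#' @param genome optional `genome_table`.
#' @return List with `only_A` and `only_B`, each a tibble of `gene` (and
#'   `product` when annotated).
#' @export
exclusive_tfs <- function(netA, netB, genome = NULL) {
  regs <- function(net) net$nodes$gene[net$nodes$is_tf | net$nodes$is_sigma]
  annotate <- function(genes) {
    tab <- tibble(gene = sort(genes))
    if (!is.null(genome)) {
      tab <- left_join(tab, select(genome, gene = "locus_tag", "product"),
                       by = "gene")
    }
    tab
  }
  a <- regs(netA); b <- regs(netB)
  list(only_A = annotate(setdiff(a, b)), only_B = annotate(setdiff(b, a)))
}
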