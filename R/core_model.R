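#' Validate and index a genome annotation table
#'
#' A genome is a tibble with one row per annotated feature. Locus tags and
#' ordinal genome-order indices must be unique; ordinals are 1-based over the
#' replicons concatenated in annotation order, matching the "number of the
#' gene" used in regulon tables. Sigma factors are flagged separately from
#' transcription factors so that network composition can be reported as
#' disjoint TF and sigma-factor tallies.
#'
#' @param genes data frame with columns `locus_tag`, `replicon`, `ordinal`,
#'   `strand`, `is_tf`, `is_sigma`; optional `cog`, `product`.
#' @return A validated tibble of class `genome_table`, sorted by ordinal.
#' @export
validate_genome <- function(genes) {
  if (is.null(genes) || nrow(as.data.frame(genes)) == 0L) {
    abort("genome table is empty")
  }
  genes <- as_tibble(genes)
  required <- c("locus_tag", "replicon", "ordinal", "strand", "is_tf", "is_sigma")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0L) {
    abort(paste0("genome table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"cog" %in% names(genes)) genes$cog <- ""
  if (!"product" %in% names(genes)) genes$product <- ""
  genes$ordinal <- as.integer(genes$ordinal)
  if (anyNA(genes$ordinal) || any(genes$ordinal < 1L)) {
    abort("ordinals must be positive integers")
  }
  dup_tag <- genes$locus_tag[duplicated(genes$locus_tag)]
  if (length(dup_tag) > 0L) {
    abort(paste0("duplicate locus_tag: ", paste(unique(dup_tag), collapse = ", ")))
  }
  dup_ord <- genes$ordinal[duplicated(genes$ordinal)]
  if (length(dup_ord) > 0L) {
    abort(paste0("duplicate ordinal: ", paste(unique(dup_ord), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  genes$is_tf <- as.logical(genes$is_tf)
  genes$is_sigma <- as.logical(genes$is_sigma)
  out <- arrange(genes[, c(required, "cog", "product")], .data$ordinal)
  class(out) <- c("genome_table", class(out))
  out
}

#' Regulator locus tags of a genome (TFs plus sigma factors)
#' @param genome a `genome_table`.
#' @return Character vector of locus tags.
#' @export
regulator_ids <- function(genome) {
  genome$locus_tag[genome$is_tf | genome$is_sigma]
}

#' Construct a position count matrix record
#'
#' Matrix identifiers follow the `<gene>_m<k>` convention: each gene may carry
#' one to five deduced matrices. Counts are a width x 4 non-negative grid over
#' A, C, G, T with every position (column of the motif) summing to a positive
#' total.
#'
#' @param matrix_id identifier of the form `<gene_id>_m<k>`.
#' @param counts numeric matrix, `width` rows by 4 columns (A, C, G, T).
#' @return A `motif_matrix` object.
#' @export
motif_matrix <- function(matrix_id, counts) {
  parsed <- parse_matrix_id(matrix_id)
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) abort("counts must have 4 columns (A, C, G, T)")
  if (nrow(counts) < 1L) abort("counts must have at least one position")
  if (any(counts < 0) || anyNA(counts)) abort("counts must be non-negative")
  if (any(rowSums(counts) <= 0)) {
    abort(paste0("matrix ", matrix_id, ": every position must have a positive count sum"))
  }
  colnames(counts) <- c("A", "C", "G", "T")
  structure(
    list(matrix_id = matrix_id, gene_id = parsed$gene_id,
         counts = counts, width = nrow(counts)),
    class = "motif_matrix"
  )
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("<motif_matrix>", x$matrix_id, "gene", x$gene_id, "width", x$width, "\n")
  invisible(x)
}

parse_matrix_id <- function(matrix_id) {
  m <- regmatches(matrix_id, regexec("^(.*)_m([0-9]+)$", matrix_id))[[1]]
  if (length(m) != 3L || m[2] == "") {
    abort(paste0("matrix id '", matrix_id, "' does not match '<gene>_m<k>'"))
  }
  list(gene_id = m[2], index = as.integer(m[3]))
}

#' Construct a motif cluster
#'
#' A cluster groups matrix names; the unique-gene set is derived by stripping
#' the `_m<k>` suffix, and the TF subset is resolved against a genome table
#' when one is supplied (sigma factors count as TFs for cluster selection).
#'
#' @param cluster_id cluster name, e.g. `"cluster_3"`.
#' @param matrix_ids character vector of matrix names.
#' @param genome optional `genome_table` used to flag TF genes.
#' @return A `motif_cluster` object with `unique_genes` and `tf_genes`.
#' @export
motif_cluster <- function(cluster_id, matrix_ids, genome = NULL) {
  genes <- vapply(matrix_ids, function(id) parse_matrix_id(id)$gene_id, character(1))
  unique_genes <- unique(unname(genes))
  tf_genes <- character(0)
  if (!is.null(genome)) {
    tf_genes <- intersect(unique_genes, regulator_ids(genome))
  }
  structure(
    list(cluster_id = cluster_id, matrix_ids = unname(matrix_ids),
         unique_genes = unique_genes, tf_genes = tf_genes),
    class = "motif_cluster"
  )
}

#' Construct a scan-hit table
#'
#' Each row records one motif-scan hit of a regulator's matrix in a target
#' gene's promoter, with its p-value. P-values must lie in (0, 1].
#'
#' @param tf_id,target_id,p_value vectors of equal length.
#' @return Tibble with columns `tf_id`, `target_id`, `p_value`.
#' @export
scan_hits <- function(tf_id, target_id, p_value) {
  p_value <- as.numeric(p_value)
  if (any(!is.finite(p_value)) || any(p_value <= 0) || any(p_value > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  tibble(tf_id = as.character(tf_id), target_id = as.character(target_id),
         p_value = p_value)
}

#' Construct a regulatory network
#'
#' A directed network of regulator -> target edges. Every edge source must be
#' a regulator (TF or sigma factor); duplicate (source, target) pairs are
#' forbidden at construction (collapse them upstream); self-regulations are
#' permitted.
#'
#' @param edges tibble with columns `tf`, `target`; optional `tier`
#'   (`"STRICT"`, `"MEDIUM"` or `"LOW"`) and `p_value`.
#' @param nodes optional tibble with columns `gene`, `is_tf`, `is_sigma`.
#'   When absent, nodes are inferred from the edges and every edge source is
#'   flagged as a TF.
#' @param name network label used in reports.
#' @return A `reg_network` object.
#' @export
reg_network <- function(edges, nodes = NULL, name = "network") {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0L) {
    if (!all(c("tf", "target") %in% names(edges))) {
      abort("edges need columns 'tf' and 'target'")
    }
    edges$tf <- as.character(edges$tf)
    edges$target <- as.character(edges$target)
    if (anyDuplicated(paste(edges$tf, edges$target, sep = "\r"))) {
      abort("duplicate (tf, target) edges; collapse to minimum p-value first")
    }
  } else {
    edges <- tibble(tf = character(0), target = character(0))
  }
  if (!"tier" %in% names(edges)) edges$tier <- rep(NA_character_, nrow(edges))
  if (!"p_value" %in% names(edges)) edges$p_value <- rep(NA_real_, nrow(edges))
  if (!all(is.na(edges$tier)) && !all(edges$tier[!is.na(edges$tier)] %in% TIER_LEVELS)) {
    abort("tier must be STRICT, MEDIUM or LOW")
  }
  if (is.null(nodes)) {
    genes <- unique(c(edges$tf, edges$target))
    nodes <- tibble(gene = genes, is_tf = genes %in% edges$tf,
                    is_sigma = FALSE)
  } else {
    nodes <- as_tibble(nodes)
    if (!all(c("gene", "is_tf", "is_sigma") %in% names(nodes))) {
      abort("nodes need columns 'gene', 'is_tf', 'is_sigma'")
    }
    nodes$gene <- as.character(nodes$gene)
    if (anyDuplicated(nodes$gene)) abort("duplicate node gene ids")
    dangling <- setdiff(unique(c(edges$tf, edges$target)), nodes$gene)
    if (length(dangling) > 0L) {
      abort(paste0("edges reference unknown node(s): ",
                   paste(head(dangling, 5), collapse = ", ")))
    }
    reg <- nodes$gene[nodes$is_tf | nodes$is_sigma]
    bad <- setdiff(unique(edges$tf), reg)
    if (length(bad) > 0L) {
      abort(paste0("edge source(s) not flagged as regulator: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  structure(
    list(name = name,
         nodes = nodes[, c("gene", "is_tf", "is_sigma")],
         edges = edges[, c("tf", "target", "tier", "p_value")]),
    class = "reg_network"
  )
}

#' @export
print.reg_network <- function(x, ...) {
  cat("<reg_network>", x$name, "-", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  reg <- sum(x$nodes$is_tf | x$nodes$is_sigma)
  cat("  regulator-flagged nodes:", reg,
      "| self-regulations:", sum(x$edges$tf == x$edges$target), "\n")
  invisible(x)
}

#' Convert a regulatory network to an igraph object
#'
#' Node attributes `is_tf` and `is_sigma` and edge attributes `tier` and
#' `p_value` are carried over. Self-loops are kept.
#'
#' @param net a `reg_network`.
#' @return A directed `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$tf, to = net$edges$target,
                   tier = net$edges$tier, p_value = net$edges$p_value,
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes$gene, is_tf = net$nodes$is_tf,
                          is_sigma = net$nodes$is_sigma,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Out-degree of every node, self-loops included
#'
#' Self-regulations are first-class in the property suite, so a self-loop
#' contributes 1 to its node's out-connectivity.
#'
#' @param net a `reg_network`.
#' @return Named integer vector over all nodes.
#' @export
out_degrees <- function(net) {
  k <- table(factor(net$edges$tf, levels = net$nodes$gene))
  setNames(as.integer(k), net$nodes$gene)
}

in_degrees <- function(net) {
  k <- table(factor(net$edges$target, levels = net$nodes$gene))
  setNames(as.integer(k), net$nodes$gene)
}
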