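#' Classify edges as descendent or ascendant
#'
#' An edge (a, b) is "descendent" when the out-connectivity of a strictly
#' exceeds that of b (kout computed on the full network, self-loops
#' included); otherwise — ties, reversals, and every self-loop — it is
#' "ascendant". Ascendant edges constitute the feedback of the network: the
#' descendent subgraph is acyclic because kout strictly decreases along every
#' descendent edge.
#'
#' @param net a `reg_network` with at least one edge.
#' @return List with `descendent` and `ascendant` edge tibbles (columns of
#'   `net$edges` plus `kout_src`, `kout_dst`).
#' @export
classify_edges <- function(net) {
  if (nrow(net$edges) == 0L) abort("network has no edges")
  kout <- out_degrees(net)
  e <- net$edges
  e$kout_src <- unname(kout[e$tf])
  e$kout_dst <- unname(kout[e$target])
  desc <- e$kout_src > e$kout_dst
  list(descendent = e[desc, ], ascendant = e[!desc, ])
}

#' Reconstruct the hierarchy of a network by topological layering
#'
#' Removes all ascendant edges (which eliminates feedback and leaves a
#' directed acyclic graph), then peels layers Kahn-style: layer 1 is the set
#' of nodes with no remaining incoming descendent edge; those nodes and their
#' out-edges are removed and the peeling repeats. Every retained edge points
#' from an earlier to a strictly later layer, so each node can only regulate
#' nodes in lower layers. No node is removed: nodes losing all edges still
#' appear in a layer, and the ascendant edges are recorded so feedback can be
#' re-attached for display.
#'
#' @param net a `reg_network`.
#' @return A `hierarchy_layering` list: `layers` (list of character vectors,
#'   layer 1 = top), `ascendant_edges` (tibble), `ascendant_fraction`,
#'   `kout` (named vector), `n_layers`.
#' @export
layer_hierarchy <- function(net) {
  nodes <- net$nodes$gene
  if (length(nodes) == 0L) {
    return(structure(list(layers = list(), ascendant_edges = tibble(),
                          ascendant_fraction = NA_real_, kout = integer(0),
                          n_layers = 0L),
                     class = "hierarchy_layering"))
  }
  kout <- out_degrees(net)
  if (nrow(net$edges) == 0L) {
    return(structure(list(layers = list(sort(nodes)),
                          ascendant_edges = net$edges,
                          ascendant_fraction = NA_real_, kout = kout,
                          n_layers = 1L),
                     class = "hierarchy_layering"))
  }
  cls <- classify_edges(net)
  desc <- cls$descendent
  layers <- list()
  remaining <- nodes
  edges <- desc
  while (length(remaining) > 0L) {
    kin <- table(factor(edges$target, levels = remaining))
    top <- remaining[kin == 0L]
    # cannot stall: the descendent subgraph is acyclic
    layers[[length(layers) + 1L]] <- sort(top)
    remaining <- setdiff(remaining, top)
    edges <- edges[!(edges$tf %in% top), , drop = FALSE]
  }
  structure(
    list(layers = layers, ascendant_edges = cls$ascendant,
         ascendant_fraction = nrow(cls$ascendant) / nrow(net$edges),
         kout = kout, n_layers = length(layers)),
    class = "hierarchy_layering"
  )
}

#' @export
print.hierarchy_layering <- function(x, ...) {
  cat("<hierarchy_layering>", x$n_layers, "layers;",
      if (is.na(x$ascendant_fraction)) "no edges" else
        sprintf("%.2f%% ascendant (feedback) edges", 100 * x$ascendant_fraction),
      "\n")
  for (i in seq_along(x$layers)) {
    cat(sprintf("  layer %d: %d node(s)\n", i, length(x$layers[[i]])))
  }
  invisible(x)
}

#' Layer index of every node in a layering
#'
#' @param layering a `hierarchy_layering`.
#' @return Named integer vector: layer index per node (1 = top).
#' @export
layer_index <- function(layering) {
  idx <- rep(seq_along(layering$layers),
             vapply(layering$layers, length, integer(1)))
  setNames(idx, unlist(layering$layers))
}

#' Breadth-first hierarchy from a root node
#'
#' Emulates a breadth-first layout: the root is level 0; level k+1 collects
#' the yet-unvisited direct targets of level-k nodes, following directed
#' edges source -> target (an undirected traversal is available by flag).
#' Nodes unreachable from the root are reported separately.
#'
#' @param net a `reg_network`.
#' @param root a gene id, or `"auto"` to use the node with maximal
#'   undirected degree (ties broken lexicographically).
#' @param directed follow edge direction (default) or traverse undirected.
#' @return List with `root`, `levels` (list of character vectors; level 0 =
#'   root), `n_levels` (levels below the root) and `unreachable`.
#' @export
bfs_hierarchy <- function(net, root = "auto", directed = TRUE) {
  nodes <- net$nodes$gene
  if (identical(root, "auto")) {
    deg <- out_degrees(net) + in_degrees(net)
    root <- sort(names(deg)[deg == max(deg)])[1]
  }
  if (!root %in% nodes) abort(paste0("root '", root, "' not in network"))
  succ <- split(net$edges$target, net$edges$tf)
  if (!directed) {
    pred <- split(net$edges$tf, net$edges$target)
    for (g in names(pred)) succ[[g]] <- c(succ[[g]], pred[[g]])
  }
  visited <- root
  levels <- list(root)
  frontier <- root
  repeat {
    nxt <- sort(setdiff(unique(unlist(succ[frontier], use.names = FALSE)), visited))
    if (length(nxt) == 0L) break
    levels[[length(levels) + 1L]] <- nxt
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  list(root = root, levels = levels, n_levels = length(levels) - 1L,
       unreachable = sort(setdiff(nodes, visited)))
}

#' Write a layering as TSV
#'
#' @param layering a `hierarchy_layering`.
#' @param net the `reg_network` it came from (for TF flags).
#' @param path output TSV path.
#' @return The tibble written, invisibly.
#' @export
write_layering <- function(layering, net, path) {
  idx <- layer_index(layering)
  tab <- tibble(node = names(idx), layer = unname(idx)) |>
    left_join(rename(net$nodes, node = "gene"), by = "node") |>
    arrange(.data$layer, .data$node)
  readr::write_tsv(tab, path)
  invisible(tab)
}
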