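PROPERTY_NAMES <- c(
  "regulators_frac", "selfreg_frac", "kmax_out_frac", "giant_component_frac",
  "density_times_reg_frac", "ffl_norm", "complex_ffl_norm", "fbl3_norm",
  "avg_shortest_path", "diameter_norm", "avg_clustering", "r2adj_pk",
  "r2adj_ck"
)

#' Count 3-node motifs
#'
#' Counts feed-forward loops (A -> B, A -> C, B -> C), complex feed-forward
#' loops (mutual regulation A <-> B with both A -> C and B -> C) and
#' 3-feedback loops (directed cycles A -> B -> C -> A). Self-loops are
#' ignored for motif membership. Counting is per unordered node triple: each
#' triple contributes at most once to each motif class; a triple realizing
#' the complex pattern is counted as complex, not as a simple feed-forward
#' loop.
#'
#' @param net a `reg_network`.
#' @return Named integer vector `c(ffl, complex_ffl, fbl3)`.
#' @export
count_motifs <- function(net) {
  e <- net$edges[net$edges$tf != net$edges$target, c("tf", "target")]
  zero <- c(ffl = 0L, complex_ffl = 0L, fbl3 = 0L)
  if (nrow(e) == 0L) return(zero)
  g <- igraph::graph_from_data_frame(e, directed = TRUE)
  und <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  tri <- igraph::triangles(und)
  if (length(tri) == 0L) return(zero)
  nm <- igraph::V(und)$name
  tri <- matrix(nm[as.integer(tri)], nrow = 3L)
  key <- paste(e$tf, e$target, sep = "\r")
  has <- function(x, y) paste(x, y, sep = "\r") %in% key
  a <- tri[1, ]; b <- tri[2, ]; c_ <- tri[3, ]
  ab <- has(a, b); ba <- has(b, a)
  ac <- has(a, c_); ca <- has(c_, a)
  bc <- has(b, c_); cb <- has(c_, b)
  cyc <- (ab & bc & ca) | (ac & cb & ba)
  conv_c <- ac & bc   # a and b converge on c
  conv_a <- ba & ca
  conv_b <- ab & cb
  complex <- (conv_c & ab & ba) | (conv_a & bc & cb) | (conv_b & ac & ca)
  ffl_any <- (conv_c & (ab | ba)) | (conv_a & (bc | cb)) | (conv_b & (ac | ca))
  c(ffl = sum(ffl_any & !complex), complex_ffl = sum(complex), fbl3 = sum(cyc))
}

#' Potential-motif normalization denominator
#'
#' The number of potential motifs in a network of `n` nodes with `tfn`
#' regulators: n!/(n-r)! * (tfn/n)^tfm, where `r` is the motif size (3 for
#' all three counted motifs) and `tfm` the number of regulators the motif
#' requires (3 for 3-feedback loops, 2 for feed-forward and complex
#' feed-forward loops). Computed as a falling factorial, without evaluating
#' factorials.
#'
#' @param n node count (n >= r).
#' @param tfn regulator count (0 <= tfn <= n).
#' @param r motif size.
#' @param tfm regulators required per motif.
#' @return The (real-valued) potential-motif count.
#' @export
potential_motifs <- function(n, tfn, r = 3, tfm) {
  if (n < r) abort("n must be at least the motif size r")
  if (tfn < 0 || tfn > n) abort("tfn must lie in [0, n]")
  prod(seq(n, n - r + 1)) * (tfn / n)^tfm
}

r2adj_loglog <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- lm(log10(y[keep]) ~ log10(x[keep]))
  r2 <- summary(fit)$r.squared
  nb <- sum(keep)
  1 - (1 - r2) * (nb - 1) / (nb - 2)
}

#' Compute the normalized structural property vector of a network
#'
#' Thirteen analysis properties: fraction of regulators (kout > 0), of
#' self-regulations, maximum out-connectivity and giant (weakly connected)
#' component size, all normalized by node count; directed density
#' (self-loops excluded) times the regulator fraction; feed-forward, complex
#' feed-forward and 3-feedback loop counts normalized by
#' [potential_motifs()]; mean directed shortest-path length over reachable
#' ordered pairs; diameter (longest directed shortest path) normalized by
#' (n - 2), as if no shortcuts existed (divisor n/2 available via
#' `diameter_divisor`); mean Watts-Strogatz local clustering on the
#' undirected projection (degree < 2 nodes contribute 0); and adjusted R^2
#' of log10-log10 least-squares fits of P(k) (fraction of nodes at total
#' degree k) and C(k) (mean clustering at degree k) over nonzero bins.
#' Degenerate fits (< 3 nonzero bins) yield NA.
#'
#' @param net a `reg_network` with at least 3 nodes.
#' @param diameter_divisor `"n-2"` (default) or `"n/2"`.
#' @return One-row tibble: `name`, `n_nodes`, `n_edges`, then the 13
#'   properties.
#' @export
compute_properties <- function(net, diameter_divisor = c("n-2", "n/2")) {
  diameter_divisor <- match.arg(diameter_divisor)
  n <- nrow(net$nodes)
  if (n < 3L) abort("network must have at least 3 nodes")
  m_total <- nrow(net$edges)
  self <- sum(net$edges$tf == net$edges$target)
  m <- m_total - self
  kout <- out_degrees(net)
  regulators_frac <- sum(kout > 0) / n
  tfn <- sum(net$nodes$is_tf | net$nodes$is_sigma)
  g <- as_igraph(net)
  giant <- max(igraph::components(g, mode = "weak")$csize) / n
  density <- m / (n * (n - 1))
  motifs <- count_motifs(net)
  ffl_norm <- if (tfn > 0) motifs[["ffl"]] / potential_motifs(n, tfn, 3, 2) else 0
  cffl_norm <- if (tfn > 0) motifs[["complex_ffl"]] / potential_motifs(n, tfn, 3, 2) else 0
  fbl3_norm <- if (tfn > 0) motifs[["fbl3"]] / potential_motifs(n, tfn, 3, 3) else 0
  asp <- igraph::mean_distance(g, directed = TRUE, unconnected = TRUE)
  diam <- igraph::diameter(g, directed = TRUE, unconnected = TRUE, weights = NA)
  diam_div <- if (diameter_divisor == "n-2") n - 2 else n / 2
  und <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  localc <- igraph::transitivity(und, type = "local", isolates = "zero")
  localc[!is.finite(localc)] <- 0
  deg <- igraph::degree(und)
  ktab <- table(deg[deg > 0])
  pk_k <- as.numeric(names(ktab))
  pk_f <- as.numeric(ktab) / n
  ck <- tapply(localc, deg, mean)
  ck_k <- as.numeric(names(ck))
  ck_v <- as.numeric(ck)
  tibble(
    name = net$name, n_nodes = n, n_edges = m_total,
    regulators_frac = regulators_frac,
    selfreg_frac = self / n,
    kmax_out_frac = max(kout) / n,
    giant_component_frac = giant,
    density_times_reg_frac = density * regulators_frac,
    ffl_norm = unname(ffl_norm),
    complex_ffl_norm = unname(cffl_norm),
    fbl3_norm = unname(fbl3_norm),
    avg_shortest_path = asp,
    diameter_norm = diam / diam_div,
    avg_clustering = mean(localc),
    r2adj_pk = r2adj_loglog(pk_k, pk_f),
    r2adj_ck = r2adj_loglog(ck_k, ck_v)
  )
}

#' Erdos-Renyi G(n, m) null ensemble
#'
#' Each replicate is a directed G(n, m) graph: m distinct ordered pairs
#' without self-loops sampled uniformly. The per-property arithmetic mean
#' over replicates (`er_avg`) is the random-network reference profile a
#' deduced network is compared against.
#'
#' @param n nodes per replicate.
#' @param m edges per replicate (m <= n(n-1)).
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param name_prefix label prefix for the replicates.
#' @return List with `networks` (list of `reg_network`), `properties`
#'   (tibble, one row per replicate) and `er_avg` (one-row tibble named
#'   `<name_prefix>_avg`).
#' @export
er_ensemble <- function(n, m, reps = 50L, seed = 1L, name_prefix = "ER") {
  if (m > n * (n - 1)) abort("m exceeds the number of ordered pairs")
  if (reps < 1L) abort("reps must be >= 1")
  set.seed(seed)
  nets <- vector("list", reps)
  for (i in seq_len(reps)) {
    g <- igraph::sample_gnm(n, m, directed = TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
    nodes <- tibble(gene = sprintf("v%03d", seq_len(n)), is_tf = FALSE,
                    is_sigma = FALSE)
    edges <- tibble(tf = nodes$gene[el[, 1]], target = nodes$gene[el[, 2]])
    nodes$is_tf <- nodes$gene %in% edges$tf
    nets[[i]] <- reg_network(edges, nodes = nodes,
                             name = sprintf("%s_%03d", name_prefix, i))
  }
  props <- bind_rows(lapply(nets, compute_properties))
  avg <- props |>
    summarise(across(c("n_nodes", "n_edges", dplyr::all_of(PROPERTY_NAMES)),
                     ~ mean(.x, na.rm = TRUE)))
  avg <- bind_cols(tibble(name = paste0(name_prefix, "_avg")), avg)
  list(networks = nets, properties = props, er_avg = avg)
}

#' Compare networks by their property profiles
#'
#' Scales each property column across networks to \[0, 1\] (constant columns
#' become 0), clusters networks and properties by Ward's method on Euclidean
#' distances of the scaled matrix, and computes the pairwise Pearson
#' correlation matrix of the raw profiles. Undefined property values are
#' handled pairwise-complete and reported in `na_mask`.
#'
#' @param props tibble of property rows as returned by
#'   [compute_properties()] / `er_ensemble()$er_avg` (>= 2 rows).
#' @return List with `scaled` (matrix), `network_linkage` and
#'   `property_linkage` (`hclust` objects), `pearson` (matrix),
#'   `network_order` (dendrogram order of network names), `na_mask`.
#' @export
compare_networks <- function(props) {
  props <- as_tibble(props)
  if (nrow(props) < 2L) abort("need at least two networks to compare")
  raw <- as.matrix(props[, PROPERTY_NAMES])
  rownames(raw) <- props$name
  na_mask <- is.na(raw)
  if (any(na_mask)) {
    inform(paste0(sum(na_mask), " undefined property value(s); ",
                  "pairwise-complete handling in effect"))
  }
  scaled <- apply(raw, 2, function(col) {
    rng <- suppressWarnings(range(col, na.rm = TRUE))
    if (!all(is.finite(rng)) || diff(rng) == 0) return(rep(0, length(col)))
    (col - rng[1]) / diff(rng)
  })
  rownames(scaled) <- props$name
  net_link <- hclust(dist(scaled), method = "ward.D2")
  prop_link <- hclust(dist(t(scaled)), method = "ward.D2")
  pearson <- suppressWarnings(cor(t(raw), use = "pairwise.complete.obs"))
  list(scaled = scaled, network_linkage = net_link,
       property_linkage = prop_link, pearson = pearson,
       network_order = props$name[net_link$order], na_mask = na_mask)
}

#' Fraction of shortcut edges
#'
#' An edge is a shortcut when its range exceeds 2: on the undirected
#' projection with the edge removed, the shortest alternative path between
#' its endpoints is longer than 2 or absent — equivalently, the endpoints
#' share no common neighbor. Shortcut abundance relates to small-world
#' navigability. Self-loops have no range and are excluded.
#'
#' @param net a `reg_network` with at least one edge.
#' @return Fraction of non-loop edges that are shortcuts, in \[0, 1\].
#' @export
shortcut_fraction <- function(net) {
  e <- net$edges[net$edges$tf != net$edges$target, c("tf", "target")]
  if (nrow(e) == 0L) abort("network has no non-loop edges")
  g <- igraph::graph_from_data_frame(
    e, directed = TRUE,
    vertices = data.frame(name = net$nodes$gene))
  und <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  adj <- igraph::as_adjacency_matrix(und, sparse = TRUE)
  two_paths <- adj %*% adj  # [u,v] = number of common neighbors
  u <- match(e$tf, net$nodes$gene)
  v <- match(e$target, net$nodes$gene)
  is_shortcut <- two_paths[cbind(u, v)] == 0
  mean(is_shortcut)
}

#' Proportion of regulator and structural genes
#'
#' Partitions the node set into regulators (TF or sigma flag) and structural
#' genes; the two fractions sum to 1.
#'
#' @param net a `reg_network`.
#' @return Named numeric vector `c(regulator_frac, structural_frac)`.
#' @export
tf_structural_proportion <- function(net) {
  n <- nrow(net$nodes)
  reg <- sum(net$nodes$is_tf | net$nodes$is_sigma)
  c(regulator_frac = reg / n, structural_frac = (n - reg) / n)
}
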