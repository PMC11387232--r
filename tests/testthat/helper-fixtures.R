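# small in-code fixtures shared across the suite

tiny_genome <- function(n = 10L, tf = c(1L, 2L), sigma = integer(0),
                        replicon = rep("chr", n)) {
  validate_genome(tibble::tibble(
    locus_tag = sprintf("G%03d", seq_len(n)),
    replicon = replicon,
    ordinal = seq_len(n),
    strand = rep(c("+", "-"), length.out = n),
    is_tf = seq_len(n) %in% tf,
    is_sigma = seq_len(n) %in% sigma,
    cog = rep(c("K", "E", "C"), length.out = n),
    product = ifelse(seq_len(n) %in% tf, "transcriptional regulator", "protein")
  ))
}

# random directed graph as a reg_network; no duplicate pairs
random_net <- function(n, p = 0.08, self_loops = FALSE) {
  genes <- sprintf("n%03d", seq_len(n))
  pairs <- expand.grid(tf = genes, target = genes, stringsAsFactors = FALSE)
  if (!self_loops) pairs <- pairs[pairs$tf != pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, ]
  nodes <- tibble::tibble(gene = genes, is_tf = genes %in% edges$tf,
                          is_sigma = FALSE)
  reg_network(edges, nodes = nodes)
}

# exhaustive per-triple motif oracle, vectorized over all unordered triples
brute_motifs <- function(net) {
  e <- net$edges[net$edges$tf != net$edges$target, ]
  genes <- net$nodes$gene
  if (length(genes) < 3L || nrow(e) == 0L) {
    return(c(ffl = 0L, complex_ffl = 0L, fbl3 = 0L))
  }
  key <- paste(e$tf, e$target)
  tri <- utils::combn(genes, 3L)
  a <- tri[1, ]; b <- tri[2, ]; c_ <- tri[3, ]
  has <- function(x, y) paste(x, y) %in% key
  ab <- has(a, b); ba <- has(b, a); ac <- has(a, c_); ca <- has(c_, a)
  bc <- has(b, c_); cb <- has(c_, b)
  cyc <- (ab & bc & ca) | (ac & cb & ba)
  cx <- (ac & bc & ab & ba) | (ba & ca & bc & cb) | (ab & cb & ac & ca)
  fa <- (ac & bc & (ab | ba)) | (ba & ca & (bc | cb)) | (ab & cb & (ac | ca))
  c(ffl = sum(fa & !cx), complex_ffl = sum(cx), fbl3 = sum(cyc))
}

# adjusted Rand index between two labelings
rand_index_adj <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

edge_key <- function(net) paste(net$edges$tf, net$edges$target)
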