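#' Configuration for the synthetic-data generator
#'
#' The generator emulates the inputs of the motif-based TRN pipeline: a
#' multi-replicon bacterial genome, planted regulons, stratified scan-hit
#' tables and a motif-cluster file. Defaults mirror the conditions the
#' pipeline is designed for: a genome where roughly a tenth of genes encode
#' regulators, regulons of a few targets each, about 60% of true hits in the
#' strict (p <= 1e-06) stratum and well under 1% in the low stratum.
#'
#' @param n_genes total genes in the genome.
#' @param n_tfs number of transcription-factor genes.
#' @param n_sigma number of sigma-factor genes (disjoint from TFs).
#' @param n_replicons number of replicons (chromosome plus plasmids/chromids).
#' @param regulon_mean,regulon_dispersion negative-binomial mean and size for
#'   the number of targets per regulator.
#' @param tier_mixture length-3 probability vector that a true edge's p-value
#'   falls in the STRICT, MEDIUM or LOW stratum; must sum to 1.
#' @param false_hit_rate probability that a (regulator, non-target) pair emits
#'   a spurious scan hit.
#' @param operon_block_prob probability that a drawn target is re-placed
#'   within the neighbor window of its regulator's ordinal, emulating
#'   operon-like co-location.
#' @param neighbor_gap maximum number of intervening genes for two genes to
#'   count as neighbors; shared with [find_neighbor_groups()].
#' @param selfreg_prob probability that a regulator with at least one target
#'   also regulates itself.
#' @param motif_width width of generated motif count matrices.
#' @param pwm_noise non-negative noise level for target-gene copies of a
#'   regulator's matrix (0 = exact copies); see [generate_pwms_and_clusters()].
#' @param seed integer seed; all generators are deterministic given the seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 300, n_tfs = 40, n_sigma = 4,
                         n_replicons = 3, regulon_mean = 6,
                         regulon_dispersion = 2,
                         tier_mixture = c(0.60, 0.396, 0.004),
                         false_hit_rate = 0.001, operon_block_prob = 0.3,
                         neighbor_gap = 3, selfreg_prob = 0.2,
                         motif_width = 12, pwm_noise = 0.05, seed = 1L) {
  if (n_genes < 1 || n_tfs < 0 || n_sigma < 0 || n_replicons < 1) {
    abort("counts must be positive")
  }
  if (n_tfs + n_sigma > n_genes) {
    abort("n_tfs + n_sigma must not exceed n_genes")
  }
  if (length(tier_mixture) != 3L || any(tier_mixture < 0) ||
      abs(sum(tier_mixture) - 1) > 1e-08) {
    abort("tier_mixture must be 3 non-negative probabilities summing to 1")
  }
  if (false_hit_rate < 0 || false_hit_rate > 1) abort("false_hit_rate in [0,1]")
  if (operon_block_prob < 0 || operon_block_prob > 1) {
    abort("operon_block_prob in [0,1]")
  }
  if (pwm_noise < 0) abort("pwm_noise must be >= 0")
  structure(
    list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
         n_sigma = as.integer(n_sigma), n_replicons = as.integer(n_replicons),
         regulon_mean = regulon_mean, regulon_dispersion = regulon_dispersion,
         tier_mixture = tier_mixture, false_hit_rate = false_hit_rate,
         operon_block_prob = operon_block_prob,
         neighbor_gap = as.integer(neighbor_gap),
         selfreg_prob = selfreg_prob, motif_width = as.integer(motif_width),
         pwm_noise = pwm_noise, seed = as.integer(seed)),
    class = "synth_config"
  )
}

COG_LETTERS <- c("C", "E", "G", "H", "I", "J", "K", "L", "M", "N", "O", "P",
                 "Q", "R", "S", "T", "U", "V")

#' Generate a synthetic annotated genome
#'
#' Genes are laid out over `n_replicons` replicons with contiguous 1-based
#' ordinals in annotation order; TF and sigma-factor flags are assigned to
#' random genes (disjoint sets), strands and COG letters uniformly.
#'
#' @param cfg a [synth_config()].
#' @return A `genome_table` of `n_genes` records.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  # replicon sizes: roughly a large chromosome plus smaller plasmids
  cuts <- sort(sample.int(n - 1L, cfg$n_replicons - 1L))
  sizes <- diff(c(0L, cuts, n))
  replicon <- rep(sprintf("replicon_%02d", seq_len(cfg$n_replicons)), sizes)
  reg_idx <- sample.int(n, cfg$n_tfs + cfg$n_sigma)
  tf_idx <- reg_idx[seq_len(cfg$n_tfs)]
  sigma_idx <- setdiff(reg_idx, tf_idx)
  genes <- tibble(
    locus_tag = sprintf("SYN_RS%05d", seq_len(n) * 5L),
    replicon = replicon,
    ordinal = seq_len(n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    is_tf = seq_len(n) %in% tf_idx,
    is_sigma = seq_len(n) %in% sigma_idx,
    cog = sample(COG_LETTERS, n, replace = TRUE),
    product = ifelse(seq_len(n) %in% tf_idx, "transcriptional regulator",
                     ifelse(seq_len(n) %in% sigma_idx,
                            "RNA polymerase sigma factor", "hypothetical protein"))
  )
  validate_genome(genes)
}

#' Generate a planted regulatory network over a synthetic genome
#'
#' Each regulator (TF or sigma factor) draws a negative-binomial number of
#' distinct non-self targets; with probability `operon_block_prob` a target is
#' re-placed inside the regulator's neighbor window (same replicon, at most
#' `neighbor_gap` intervening genes), emulating operon-like blocks. A
#' regulator with at least one target gains a self-regulation with
#' probability `selfreg_prob`.
#'
#' @param genome a `genome_table` from [generate_genome()].
#' @param cfg the same [synth_config()].
#' @return A `reg_network` named `"planted_truth"`.
#' @export
generate_truth_network <- function(genome, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  regs <- regulator_ids(genome)
  edges <- list()
  for (tf in regs) {
    tf_row <- which(genome$locus_tag == tf)
    size <- rnbinom(1L, mu = cfg$regulon_mean, size = cfg$regulon_dispersion)
    size <- min(size, cfg$n_genes - 1L)
    if (size == 0L) next
    pool <- setdiff(genome$locus_tag, tf)
    targets <- sample(pool, size)
    # operon-like re-placement into the regulator's neighborhood
    window <- which(genome$replicon == genome$replicon[tf_row] &
                      abs(genome$ordinal - genome$ordinal[tf_row]) <=
                        cfg$neighbor_gap + 1L &
                      genome$locus_tag != tf)
    if (length(window) > 0L && cfg$operon_block_prob > 0) {
      move <- runif(size) < cfg$operon_block_prob
      if (any(move)) {
        repl <- sample(genome$locus_tag[window], sum(move), replace = TRUE)
        targets[move] <- repl
        targets <- unique(targets)
      }
    }
    if (runif(1L) < cfg$selfreg_prob) targets <- c(targets, tf)
    edges[[tf]] <- tibble(tf = tf, target = unique(targets))
  }
  edges <- if (length(edges) > 0L) bind_rows(edges) else {
    tibble(tf = character(0), target = character(0))
  }
  nodes <- tibble(gene = genome$locus_tag, is_tf = genome$is_tf,
                  is_sigma = genome$is_sigma)
  reg_network(edges, nodes = nodes, name = "planted_truth")
}

#' Generate a stratified scan-hit table from a planted network
#'
#' Every true edge emits one hit whose p-value is drawn uniformly inside the
#' stratum sampled from `tier_mixture` (STRICT (0, 1e-06], MEDIUM
#' (1e-06, 1e-05], LOW (1e-05, 1e-04]). Spurious hits on (regulator,
#' non-target) pairs occur independently at `false_hit_rate`; half of them
#' fall in the LOW stratum and half above 1e-04 (where the network builder
#' discards them).
#'
#' @param truth a `reg_network` from [generate_truth_network()].
#' @param genome the `genome_table` the truth network was built over.
#' @param cfg the same [synth_config()].
#' @return Scan-hit tibble (`tf_id`, `target_id`, `p_value`).
#' @export
generate_scan_hits <- function(truth, genome, cfg) {
  stopifnot(inherits(truth, "reg_network"), inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  lo <- c(0, 1e-06, 1e-05)
  hi <- c(1e-06, 1e-05, 1e-04)
  n_true <- nrow(truth$edges)
  hits <- tibble(tf_id = character(0), target_id = character(0),
                 p_value = numeric(0))
  if (n_true > 0L) {
    stratum <- sample.int(3L, n_true, replace = TRUE, prob = cfg$tier_mixture)
    p <- runif(n_true, lo[stratum], hi[stratum])
    hits <- tibble(tf_id = truth$edges$tf, target_id = truth$edges$target,
                   p_value = p)
  }
  if (cfg$false_hit_rate > 0) {
    regs <- regulator_ids(genome)
    true_key <- paste(truth$edges$tf, truth$edges$target, sep = "\r")
    pairs <- expand.grid(tf_id = regs, target_id = genome$locus_tag,
                         stringsAsFactors = FALSE)
    pairs <- pairs[!(paste(pairs$tf_id, pairs$target_id, sep = "\r") %in% true_key), ]
    hit <- runif(nrow(pairs)) < cfg$false_hit_rate
    if (any(hit)) {
      sp <- pairs[hit, ]
      weak <- runif(nrow(sp)) < 0.5
      p <- ifelse(weak, runif(nrow(sp), 1e-05, 1e-04),
                  runif(nrow(sp), 1e-04, 1e-02))
      hits <- bind_rows(hits, tibble(tf_id = sp$tf_id, target_id = sp$target_id,
                                     p_value = p))
    }
  }
  scan_hits(hits$tf_id, hits$target_id, hits$p_value)
}

random_pwm <- function(width) {
  counts <- t(vapply(seq_len(width), function(i) {
    as.numeric(rmultinom(1L, size = 20L, prob = stats::rgamma(4, 1)))
  }, numeric(4)))
  counts[rowSums(counts) == 0, 1] <- 1
  counts
}

noisy_copy <- function(counts, noise) {
  if (noise <= 0) return(counts)
  # Poisson resampling scaled by the noise level; preserves non-negativity
  lam <- counts / noise
  new <- matrix(rpois(length(lam), lam) * noise, nrow = nrow(counts))
  zero <- rowSums(new) == 0
  new[zero, ] <- counts[zero, , drop = FALSE]
  colnames(new) <- colnames(counts)
  new
}

#' Generate motif matrices and a cluster file for a planted network
#'
#' Each regulator receives a base count matrix; each of its targets receives
#' one to five noisy copies of that matrix, so that motif similarity groups a
#' regulator with its regulon. Genes outside every regulon receive one to
#' five independent random matrices (their clusters contain a single unique
#' gene and are discarded by downstream selection). One cluster line per
#' regulator with targets, plus one per unrelated gene, is written in the
#' `clusters_motif_names.tab` dialect.
#'
#' @param truth planted `reg_network`.
#' @param genome `genome_table`.
#' @param cfg [synth_config()]; `pwm_noise` controls copy fidelity.
#' @param cluster_file optional path; when given, the cluster table is written
#'   there (tab-separated: cluster id, then comma-separated matrix names).
#' @return List with `matrices` (list of `motif_matrix`) and `clusters`
#'   (list of `motif_cluster`).
#' @export
generate_pwms_and_clusters <- function(truth, genome, cfg, cluster_file = NULL) {
  stopifnot(inherits(truth, "reg_network"), inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 3L)
  matrices <- list()
  per_gene_ids <- list()
  regulons <- split(truth$edges$target, truth$edges$tf)
  reg_with_targets <- names(regulons)
  covered <- unique(c(truth$edges$tf, truth$edges$target))

  add_matrices <- function(gene, base_counts, n_copies, noise) {
    # a gene carries at most 5 matrices; genes reached by several regulators
    # re-expose their existing matrices in later clusters instead
    existing <- per_gene_ids[[gene]]
    n_new <- min(n_copies, 5L - length(existing))
    if (n_new < 1L) return(existing[length(existing)])
    ids <- character(n_new)
    for (k in seq_len(n_new)) {
      id <- sprintf("%s_m%d", gene, length(existing) + k)
      counts <- if (noise > 0) noisy_copy(base_counts, noise) else base_counts
      matrices[[id]] <<- motif_matrix(id, counts)
      ids[k] <- id
    }
    per_gene_ids[[gene]] <<- c(existing, ids)
    ids
  }

  clusters <- list()
  for (tf in reg_with_targets) {
    base <- random_pwm(cfg$motif_width)
    member_ids <- add_matrices(tf, base, sample.int(2L, 1L), 0)
    for (tg in setdiff(unique(regulons[[tf]]), tf)) {
      n_cop <- sample.int(5L, 1L)
      member_ids <- c(member_ids, add_matrices(tg, base, n_cop, cfg$pwm_noise))
    }
    clusters[[length(clusters) + 1L]] <-
      motif_cluster(sprintf("cluster_%d", length(clusters) + 1L),
                    member_ids, genome)
  }
  for (gene in setdiff(genome$locus_tag, covered)) {
    ids <- add_matrices(gene, random_pwm(cfg$motif_width), sample.int(5L, 1L), 0)
    clusters[[length(clusters) + 1L]] <-
      motif_cluster(sprintf("cluster_%d", length(clusters) + 1L), ids, genome)
  }
  if (!is.null(cluster_file)) {
    lines <- vapply(clusters, function(cl) {
      paste0(cl$cluster_id, "\t", paste(cl$matrix_ids, collapse = ", "))
    }, character(1))
    writeLines(lines, cluster_file)
  }
  list(matrices = matrices, clusters = clusters)
}

#' Run the full synthetic generator and write all interchange files
#'
#' Convenience wrapper producing annotation TSV, scan-hit TSV, cluster file
#' and TRANSFAC matrices under `dir`, plus the in-memory objects.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return List with `genome`, `truth`, `hits`, `pwms`, and the file paths.
#' @export
generate_synthetic_dataset <- function(cfg, dir = tempfile("synth")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(cfg)
  truth <- generate_truth_network(genome, cfg)
  hits <- generate_scan_hits(truth, genome, cfg)
  cluster_file <- file.path(dir, "clusters_motif_names.tab")
  pwms <- generate_pwms_and_clusters(truth, genome, cfg, cluster_file)
  genome_file <- file.path(dir, "genome.tsv")
  hits_file <- file.path(dir, "scan_hits.tsv")
  transfac_file <- file.path(dir, "matrices.transfac")
  readr::write_tsv(genome, genome_file)
  readr::write_tsv(hits, hits_file)
  write_transfac(pwms$matrices, transfac_file)
  list(genome = genome, truth = truth, hits = hits, pwms = pwms,
       files = list(genome = genome_file, hits = hits_file,
                    clusters = cluster_file, matrices = transfac_file))
}
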