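#' Parse a matrix-cluster file
#'
#' Reads the `clusters_motif_names.tab` dialect: one cluster per line, the
#' cluster id first, followed by matrix names separated by tabs and/or commas
#' (both dialects occur in the wild; the separator is auto-detected per line).
#' Matrix names must carry the `_m<k>` suffix.
#'
#' @param path path to the cluster file.
#' @param genome optional `genome_table` used to resolve TF flags.
#' @return List of `motif_cluster` objects, in file order.
#' @export
parse_cluster_file <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[i]), "[\t, ]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) < 2L) {
      abort(paste0("line ", i, ": expected a cluster id and at least one matrix name"))
    }
    cluster_id <- tokens[1]
    matrix_ids <- tokens[-1]
    ok <- grepl("_m[0-9]+$", matrix_ids)
    if (!all(ok)) {
      abort(paste0("line ", i, ": malformed matrix name(s): ",
                   paste(matrix_ids[!ok], collapse = ", ")))
    }
    out[[i]] <- motif_cluster(cluster_id, matrix_ids, genome)
  }
  out
}

#' Select clustered-TF clusters
#'
#' Keeps exactly the clusters with at least two distinct genes AND at least
#' one regulator gene (TF or sigma factor — sigma factors act as regulators
#' throughout). Clusters are frequently formed by several matrices of the
#' same gene (each gene carries one to five matrices), so deduplication to
#' unique genes precedes the two-gene rule. Genes absent from the genome are
#' dropped from clusters with a warning.
#'
#' @param clusters list of `motif_cluster` from [parse_cluster_file()].
#' @param genome a `genome_table`.
#' @return List with `clusters` (the kept `motif_cluster`s, TF sets
#'   populated), `tfs` (union of regulator genes over kept clusters) and
#'   `genes` (union of all unique genes over kept clusters).
#' @export
select_clustered_tf_clusters <- function(clusters, genome) {
  regs <- regulator_ids(genome)
  known <- genome$locus_tag
  kept <- list()
  n_dropped_genes <- 0L
  for (cl in clusters) {
    genes <- cl$unique_genes
    missing <- setdiff(genes, known)
    if (length(missing) > 0L) {
      n_dropped_genes <- n_dropped_genes + length(missing)
      genes <- setdiff(genes, missing)
    }
    tf_genes <- intersect(genes, regs)
    if (length(genes) >= 2L && length(tf_genes) >= 1L) {
      cl$unique_genes <- genes
      cl$tf_genes <- tf_genes
      kept[[length(kept) + 1L]] <- cl
    }
  }
  if (n_dropped_genes > 0L) {
    warn(paste0(n_dropped_genes,
                " cluster gene reference(s) absent from the genome were dropped"))
  }
  list(
    clusters = kept,
    tfs = sort(unique(unlist(lapply(kept, `[[`, "tf_genes")))),
    genes = sort(unique(unlist(lapply(kept, `[[`, "unique_genes"))))
  )
}

pwm_freqs <- function(counts) {
  sweep(counts, 1, rowSums(counts), "/")
}

revcomp_pwm <- function(counts) {
  # reverse positions and swap A<->T, C<->G
  counts[rev(seq_len(nrow(counts))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Pairwise similarity of two count matrices
#'
#' The maximum Pearson correlation of flattened column-frequency vectors over
#' all ungapped offsets of the shorter matrix against the longer, in both
#' orientations (as-is and reverse complement).
#'
#' @param a,b `motif_matrix` objects or count matrices.
#' @return Similarity in \[-1, 1\].
#' @export
pwm_similarity <- function(a, b) {
  ca <- if (inherits(a, "motif_matrix")) a$counts else as.matrix(a)
  cb <- if (inherits(b, "motif_matrix")) b$counts else as.matrix(b)
  if (nrow(ca) > nrow(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  fa <- pwm_freqs(ca)
  best <- -1
  for (orient in 1:2) {
    fb <- pwm_freqs(if (orient == 1) cb else revcomp_pwm(cb))
    w <- nrow(fa)
    for (off in 0:(nrow(fb) - w)) {
      win <- fb[(off + 1):(off + w), , drop = FALSE]
      r <- suppressWarnings(cor(as.vector(fa), as.vector(win)))
      if (is.finite(r) && r > best) best <- r
    }
  }
  best
}

#' Cluster motif matrices by similarity
#'
#' A lightweight hierarchical clustering of count matrices for fully
#' synthetic runs: pairwise similarity via [pwm_similarity()],
#' average-linkage agglomeration on distance 1 - similarity, cut at height
#' 1 - `similarity_threshold`. Clusters are named `cluster_1` ...
#' `cluster_K` in dendrogram leaf order.
#'
#' @param matrices list of `motif_matrix`.
#' @param similarity_threshold similarity in (0, 1\] above which matrices are
#'   grouped.
#' @param genome optional `genome_table` for TF flags.
#' @return List of `motif_cluster`.
#' @export
cluster_pwms <- function(matrices, similarity_threshold = 0.8, genome = NULL) {
  if (length(matrices) < 1L) abort("need at least one matrix")
  if (similarity_threshold <= 0 || similarity_threshold > 1) {
    abort("similarity_threshold must be in (0, 1]")
  }
  widths <- vapply(matrices, `[[`, integer(1), "width")
  if (any(widths < 4L)) abort("matrices of width < 4 are rejected")
  ids <- vapply(matrices, `[[`, character(1), "matrix_id")
  n <- length(matrices)
  if (n == 1L) {
    return(list(motif_cluster("cluster_1", ids, genome)))
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- pwm_similarity(matrices[[i]], matrices[[j]])
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  hc <- hclust(stats::as.dist(d), method = "average")
  member <- cutree(hc, h = 1 - similarity_threshold)
  # number clusters in dendrogram leaf order
  leaf_order <- hc$order
  seen <- unique(member[leaf_order])
  renum <- setNames(seq_along(seen), seen)
  lapply(seq_along(seen), function(k) {
    motif_cluster(sprintf("cluster_%d", k),
                  ids[member == as.integer(seen[k])], genome)
  })
}

#' Write selected clusters as a TSV summary
#'
#' @param selection result of [select_clustered_tf_clusters()].
#' @param path output TSV path.
#' @return The tibble written, invisibly.
#' @export
write_cluster_selection <- function(selection, path) {
  tab <- tibble(
    cluster_id = vapply(selection$clusters, `[[`, character(1), "cluster_id"),
    unique_genes = vapply(selection$clusters, function(cl) {
      paste(cl$unique_genes, collapse = ",")
    }, character(1)),
    tf_genes = vapply(selection$clusters, function(cl) {
      paste(cl$tf_genes, collapse = ",")
    }, character(1))
  )
  readr::write_tsv(tab, path)
  invisible(tab)
}
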