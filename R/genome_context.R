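#' Annotate a regulon with COG category and genome order
#'
#' Orders the regulon's genes by COG letter, then by ordinal (the "number of
#' the gene" in genome order), so that neighboring genes — candidates for
#' operon-like co-regulation — are easy to spot. Genes absent from the
#' genome are flagged, not dropped.
#'
#' @param regulon character vector of locus tags, or a regulon tibble from
#'   [build_regulons()] (its `target` column is used).
#' @param genome a `genome_table`.
#' @return List with `table` (tibble: `locus`, `ordinal`, `cog`, `is_tf`,
#'   `product`, `missing`) and `cog_summary` (counts per COG letter).
#' @export
annotate_regulon <- function(regulon, genome) {
  loci <- if (is.data.frame(regulon)) regulon$target else as.character(regulon)
  tab <- tibble(locus = loci) |>
    left_join(select(genome, locus = "locus_tag", "ordinal", "cog",
                     "is_tf", "product"),
              by = "locus") |>
    mutate(missing = is.na(.data$ordinal)) |>
    arrange(.data$cog, .data$ordinal)
  list(table = tab,
       cog_summary = count(filter(tab, !tab$missing), .data$cog, name = "n_genes"))
}

#' Detect neighbor-gene groups within a gene set
#'
#' Two genes of the set are linked when they lie on the same replicon with at
#' most `max_gap` intervening genes (ordinal difference <= max_gap + 1);
#' groups are the connected components of this linkage. Strand is not used
#' to break groups — co-located genes on both strands group together. Groups
#' are numbered from 0 in ascending order of their smallest ordinal;
#' singleton genes are not reported.
#'
#' @param gene_set character vector of locus tags.
#' @param genome a `genome_table`.
#' @param max_gap maximum number of intervening genes (default 3).
#' @return Tibble with `group`, `locus`, `ordinal`, `replicon`, `strand`.
#' @export
find_neighbor_groups <- function(gene_set, genome, max_gap = 3L) {
  members <- genome |>
    filter(.data$locus_tag %in% unique(gene_set)) |>
    arrange(.data$replicon, .data$ordinal)
  if (nrow(members) == 0L) {
    return(tibble(group = integer(0), locus = character(0),
                  ordinal = integer(0), replicon = character(0),
                  strand = character(0)))
  }
  # within a replicon, a new component starts where the gap exceeds the window
  members <- members |>
    group_by(.data$replicon) |>
    mutate(new_comp = c(TRUE, diff(.data$ordinal) > max_gap + 1L)) |>
    ungroup() |>
    mutate(comp = cumsum(.data$new_comp))
  groups <- members |>
    group_by(.data$comp) |>
    filter(n() >= 2L) |>
    ungroup()
  if (nrow(groups) == 0L) {
    return(tibble(group = integer(0), locus = character(0),
                  ordinal = integer(0), replicon = character(0),
                  strand = character(0)))
  }
  first_ord <- tapply(groups$ordinal, groups$comp, min)
  renum <- setNames(seq_along(sort(first_ord)) - 1L,
                    names(sort(first_ord)))
  groups$group <- unname(renum[as.character(groups$comp)])
  groups |>
    select("group", locus = "locus_tag", "ordinal", "replicon", "strand") |>
    arrange(.data$group, .data$ordinal)
}

#' Flag transcription factors inside neighbor groups
#'
#' Neighbor groups frequently contain a TF likely regulating its contiguous
#' genes; this annotates each group with its regulator members.
#'
#' @param groups tibble from [find_neighbor_groups()].
#' @param genome a `genome_table`.
#' @return List with `groups` (per-group tibble: `group`, `n_genes`,
#'   `tf_loci`, `has_tf`) and `n_groups_with_tf`.
#' @export
flag_tf_in_groups <- function(groups, genome) {
  regs <- regulator_ids(genome)
  per <- groups |>
    group_by(.data$group) |>
    summarise(
      n_genes = n(),
      tf_loci = paste(intersect(.data$locus, regs), collapse = ","),
      has_tf = any(.data$locus %in% regs),
      .groups = "drop"
    )
  list(groups = per, n_groups_with_tf = sum(per$has_tf))
}

#' Cross-tabulate gene sets against external module labels
#'
#' For each named gene set, the percentage of its genes falling in each
#' module (e.g. co-expression module colors supplied by an external
#' analysis); unlabeled genes are reported as `"unassigned"`. Percentages
#' per set sum to 100.
#'
#' @param gene_sets named list of character vectors.
#' @param module_labels named character vector (names = locus tags, values =
#'   module names) or a two-column data frame (`locus`, `module`).
#' @return Tibble with `set`, `module`, `n_genes`, `percent`.
#' @export
crosstab_modules <- function(gene_sets, module_labels) {
  if (is.data.frame(module_labels)) {
    module_labels <- setNames(as.character(module_labels[[2]]),
                              as.character(module_labels[[1]]))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    genes <- unique(gene_sets[[nm]])
    if (length(genes) == 0L) {
      return(tibble(set = character(0), module = character(0),
                    n_genes = integer(0), percent = numeric(0)))
    }
    mod <- unname(module_labels[genes])
    mod[is.na(mod)] <- "unassigned"
    tab <- table(mod)
    tibble(set = nm, module = names(tab), n_genes = as.integer(tab),
           percent = 100 * as.integer(tab) / length(genes))
  })
  bind_rows(rows) |> arrange(.data$set, desc(.data$percent))
}
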