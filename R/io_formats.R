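#' Read motif count matrices in TRANSFAC format
#'
#' Parses the TRANSFAC dialect: `ID <matrix_id>`, optional `BF <gene>`, a
#' `P0 A C G T` header, numbered count rows, `XX`, and a `//` record
#' terminator. The matrix width is the number of position rows.
#'
#' @param path path to a TRANSFAC matrix file (one or more records).
#' @return List of `motif_matrix`, in file order.
#' @export
read_transfac <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  matrices <- list()
  cur_id <- NULL
  cur_rows <- list()
  terminated <- TRUE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tag <- sub("^([A-Za-z0-9/]+).*", "\\1", ln)
    if (tag == "ID") {
      if (!terminated) {
        abort(paste0("record '", cur_id, "' not terminated before line ", i))
      }
      cur_id <- trimws(sub("^ID\\s+", "", ln))
      cur_rows <- list()
      terminated <- FALSE
    } else if (tag == "//") {
      if (is.null(cur_id)) abort(paste0("stray record terminator at line ", i))
      if (length(cur_rows) == 0L) {
        abort(paste0("record '", cur_id, "' has no count rows (line ", i, ")"))
      }
      counts <- do.call(rbind, cur_rows)
      matrices[[length(matrices) + 1L]] <- motif_matrix(cur_id, counts)
      cur_id <- NULL
      terminated <- TRUE
    } else if (tag %in% c("BF", "P0", "PO", "XX", "CC", "DE", "AC", "NA")) {
      next
    } else if (grepl("^[0-9]+\\s", ln)) {
      fields <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[2:5]))
      if (length(fields) < 5L || anyNA(vals)) {
        abort(paste0("non-numeric count row at line ", i,
                     if (!is.null(cur_id)) paste0(" (record '", cur_id, "')")))
      }
      cur_rows[[length(cur_rows) + 1L]] <- vals
    }
  }
  if (!terminated) {
    abort(paste0("truncated record: '", cur_id, "' lacks a '//' terminator"))
  }
  matrices
}

#' Write motif count matrices in TRANSFAC format
#'
#' @param matrices list of `motif_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(matrices, path) {
  out <- character(0)
  for (m in matrices) {
    rows <- vapply(seq_len(m$width), function(i) {
      paste(c(sprintf("%02d", i), format(m$counts[i, ], trim = TRUE)),
            collapse = "\t")
    }, character(1))
    out <- c(out,
             paste("ID", m$matrix_id),
             paste("BF", m$gene_id),
             "P0\tA\tC\tG\tT",
             rows, "XX", "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a directed network from an edge list
#'
#' Supports a TSV dialect (header with at least `source` and `target`
#' columns — `tf`/`target` also accepted — plus optional `tier`, `p_value`)
#' and the Cytoscape SIF dialect (`source relation target`, whitespace
#' separated, no header). Duplicate (source, target) pairs are collapsed to
#' the minimum p-value with a logged count. Node flags are resolved against
#' an optional genome; without one, every edge source is flagged as a TF.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"sif"`.
#' @param genome optional `genome_table`.
#' @param strict error on edges referencing genes absent from the genome
#'   (default auto-creates the node).
#' @param name network label (defaults to the file name).
#' @return A `reg_network`.
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif"), genome = NULL,
                           strict = FALSE, name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(name)) name <- basename(path)
  if (dialect == "sif") {
    fields <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
    fields <- fields[vapply(fields, length, integer(1)) >= 3L]
    edges <- tibble(tf = vapply(fields, `[[`, character(1), 1L),
                    target = vapply(fields, `[[`, character(1), 3L),
                    tier = NA_character_, p_value = NA_real_)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(tab) <- tolower(names(tab))
    src <- intersect(c("source", "tf", "tf_id"), names(tab))[1]
    dst <- intersect(c("target", "target_id"), names(tab))[1]
    if (is.na(src) || is.na(dst)) {
      abort("edge-list TSV needs source and target columns")
    }
    edges <- tibble(tf = as.character(tab[[src]]),
                    target = as.character(tab[[dst]]),
                    tier = if ("tier" %in% names(tab)) tab$tier else NA_character_,
                    p_value = if ("p_value" %in% names(tab)) tab$p_value else NA_real_)
  }
  n_dup <- nrow(edges) - nrow(distinct(edges, .data$tf, .data$target))
  if (n_dup > 0L) {
    inform(paste0(n_dup, " duplicate edge(s) collapsed"))
    edges <- edges |>
      group_by(.data$tf, .data$target) |>
      slice(which.min(ifelse(is.na(.data$p_value), Inf, .data$p_value))) |>
      ungroup()
  }
  if (!is.null(genome)) {
    dangling <- setdiff(unique(c(edges$tf, edges$target)), genome$locus_tag)
    if (strict && length(dangling) > 0L) {
      abort(paste0("edge references gene(s) absent from genome: ",
                   paste(head(dangling, 5), collapse = ", ")))
    }
    nodes <- genome |>
      filter(.data$locus_tag %in% c(edges$tf, edges$target)) |>
      select(gene = "locus_tag", "is_tf", "is_sigma")
    if (length(dangling) > 0L) {
      nodes <- bind_rows(nodes, tibble(gene = dangling,
                                       is_tf = dangling %in% edges$tf,
                                       is_sigma = FALSE))
    }
    # sources must be regulators for the network to validate
    nodes$is_tf <- nodes$is_tf | (nodes$gene %in% edges$tf & !nodes$is_sigma)
    reg_network(edges, nodes = nodes, name = name)
  } else {
    reg_network(edges, name = name)
  }
}

#' Write a network as an edge-list TSV
#'
#' Columns: `source`, `target`, `tier`, `p_value` (6 significant digits).
#'
#' @param net a `reg_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  tab <- tibble(source = net$edges$tf, target = net$edges$target,
                tier = net$edges$tier,
                p_value = signif(net$edges$p_value, 6))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write a network in Cytoscape SIF format
#'
#' One `source<TAB>regulates<TAB>target` line per edge.
#'
#' @param net a `reg_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  writeLines(paste(net$edges$tf, "regulates", net$edges$target, sep = "\t"),
             path)
  invisible(path)
}

#' Read a genome annotation TSV
#'
#' Header columns: `locus_tag`, `replicon`, `ordinal`, `strand`, `is_tf`,
#' `is_sigma`, and optionally `cog`, `product`.
#'
#' @param path input TSV.
#' @return A validated `genome_table`.
#' @export
read_genome_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_genome(tab)
}

#' Read a scan-hit TSV
#'
#' Columns `tf_id`, `target_id`, `p_value`; thresholds written as `1e-06` or
#' `1E-6` are both accepted (numeric parsing is locale-independent).
#'
#' @param path input TSV.
#' @return Scan-hit tibble.
#' @export
read_scan_hits <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           tf_id = readr::col_character(),
                           target_id = readr::col_character(),
                           p_value = readr::col_double()))
  scan_hits(tab$tf_id, tab$target_id, tab$p_value)
}
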