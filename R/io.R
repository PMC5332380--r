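# Readers and writers for the pipeline's plain-text formats: count and
# condition TSVs, differential tables, GMT gene sets, pathway edge lists,
# KGML pathway graphs, GraphML networks.

#' Read a count matrix with its condition map
#'
#' @param counts_path TSV with genes in rows (first column `gene`) and a
#'   header row of sample identifiers.
#' @param conditions_path Two-column TSV `sample`, `condition`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, conditions_path) {
  tab <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  cond <- read.delim(conditions_path, stringsAsFactors = FALSE)
  count_matrix(m, stats::setNames(cond$condition, cond$sample))
}

#' Write a count matrix and its condition map
#'
#' @param counts A [count_matrix()].
#' @param counts_path,conditions_path Output TSV paths.
#' @export
write_counts <- function(counts, counts_path, conditions_path) {
  tab <- data.frame(gene = rownames(counts$values), counts$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(counts$conditions),
                         condition = unname(counts$conditions)),
              conditions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read / write a differential-expression table
#'
#' TSV with columns `gene`, `log2fc`, `pvalue`, `fdr`.
#'
#' @param path File path.
#' @param contrast Optional contrast label to attach on read.
#' @return Data frame (read) or the path, invisibly (write).
#' @export
read_differential_table <- function(path, contrast = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- test_differential(NULL, contrast = contrast %||% "precomputed",
                           precomputed = tab)
  out
}

#' @rdname read_differential_table
#' @param table Differential table to write.
#' @export
write_differential_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read pathway graphs from an edge-list TSV
#'
#' Three columns: `pathway_id`, `gene_a`, `gene_b`.
#'
#' @param path TSV path.
#' @return Named list of two-column data frames.
#' @export
read_pathway_edges <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway_id", "gene_a", "gene_b") %in% names(tab)))
  split(tab[, c("gene_a", "gene_b")], tab$pathway_id)
}

#' Write pathway graphs to an edge-list TSV
#'
#' @param graphs Named list of two-column data frames.
#' @param path Output path.
#' @export
write_pathway_edges <- function(graphs, path) {
  rows <- lapply(names(graphs), function(id) {
    e <- graphs[[id]]
    if (is.null(e) || nrow(e) == 0) return(NULL)
    data.frame(pathway_id = id, gene_a = e[[1]], gene_b = e[[2]],
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Parse a KGML pathway file into genes and edges
#'
#' Maps KGML `entry` elements of type `gene` to gene identifiers (the
#' space-separated `name` attribute may carry several ids per entry) and
#' `relation` elements to undirected gene-gene edges. Non-gene entries
#' (compounds, maps, orthologs) are dropped.
#'
#' @param path KGML (KEGG pathway XML) file path.
#' @return List with `genes` (character) and `edges` (data frame
#'   `gene_a`, `gene_b`).
#' @export
read_kgml <- function(path) {
  doc <- xml2::read_xml(path)
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  ids <- xml2::xml_attr(entries, "id")
  names_attr <- xml2::xml_attr(entries, "name")
  entry_genes <- stats::setNames(strsplit(names_attr, " +"), ids)
  genes <- sort(unique(unlist(entry_genes)))

  rels <- xml2::xml_find_all(doc, ".//relation")
  e1 <- xml2::xml_attr(rels, "entry1")
  e2 <- xml2::xml_attr(rels, "entry2")
  edge_rows <- list()
  for (i in seq_along(e1)) {
    g1 <- entry_genes[[e1[i]]]
    g2 <- entry_genes[[e2[i]]]
    if (is.null(g1) || is.null(g2)) next  # relation touches a non-gene entry
    grid <- expand.grid(gene_a = g1, gene_b = g2, stringsAsFactors = FALSE)
    edge_rows[[length(edge_rows) + 1]] <- grid
  }
  edges <- if (length(edge_rows) > 0) {
    ed <- do.call(rbind, edge_rows)
    ed <- ed[ed$gene_a != ed$gene_b, , drop = FALSE]
    lo <- pmin(ed$gene_a, ed$gene_b)
    hi <- pmax(ed$gene_a, ed$gene_b)
    unique(data.frame(gene_a = lo, gene_b = hi, stringsAsFactors = FALSE))
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               stringsAsFactors = FALSE)
  }
  list(genes = genes, edges = edges)
}

#' Export a network as GraphML
#'
#' @param graph igraph graph.
#' @param path Output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network
#'
#' @param path GraphML path.
#' @return igraph graph.
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Export network edges as TSV
#'
#' Writes `gene_a`, `gene_b` and any edge attributes (e.g. `r`, `pvalue`,
#' `qvalue` for a co-expression network).
#'
#' @param graph igraph graph.
#' @param path Output path.
#' @export
write_edge_tsv <- function(graph, path) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  names(ed)[1:2] <- c("gene_a", "gene_b")
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
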