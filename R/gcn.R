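# Gene co-expression network: pairwise Pearson correlation across all
# samples of all conditions, Student asymptotic p-values, BH-FDR edge
# filtering.

#' Pairwise Pearson correlations
#'
#' Computes the Pearson correlation for every unordered pair of the given
#' genes across all samples (conditions pooled). Pairs involving a
#' zero-variance gene have undefined correlation and are skipped with a
#' message.
#'
#' @param expr Numeric expression matrix (genes x samples), e.g. TPM.
#' @param genes Genes to correlate; default all rows.
#' @return Data frame `gene_a`, `gene_b` (with `gene_a < gene_b`), `r`;
#'   attribute `n_samples` carries the sample count.
#' @export
pairwise_correlation <- function(expr, genes = rownames(expr)) {
  if (ncol(expr) < 3) stop("at least 3 samples are required", call. = FALSE)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    stop(sprintf("genes absent from expression table: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  genes <- sort(unique(genes))
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    message(sprintf("skipping %d zero-variance gene(s): %s",
                    sum(flat), paste(head(genes[flat], 5), collapse = ", ")))
    x <- x[!flat, , drop = FALSE]
  }
  k <- nrow(x)
  if (k < 2) {
    return(structure(data.frame(gene_a = character(0), gene_b = character(0),
                                r = numeric(0), stringsAsFactors = FALSE),
                     n_samples = ncol(expr)))
  }
  cm <- cor(t(x))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(gene_a = rownames(cm)[idx[, 1]],
                    gene_b = rownames(cm)[idx[, 2]],
                    r = cm[idx], stringsAsFactors = FALSE)
  attr(out, "n_samples") <- ncol(expr)
  out
}

#' Student asymptotic p-value for a Pearson correlation
#'
#' Two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. `|r| = 1` is clipped to p = 0.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Number of samples (>= 3).
#' @return Numeric vector of p-values.
#' @export
correlation_pvalue <- function(r, n) {
  check_number(n, "n", lower = 3, integerish = TRUE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("|r| must not exceed 1", call. = FALSE)
  }
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  tstat <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * pt(-abs(tstat), df = n - 2)
  p
}

#' Build the co-expression network from tested pairs
#'
#' Adjusts p-values jointly over all tested pairs with the
#' Benjamini-Hochberg step-up procedure and keeps edges with
#' `q < fdr_max` (strict). Genes whose every pair fails the filter remain
#' as isolated nodes.
#'
#' @param pairs Data frame from [pairwise_correlation()], with an added
#'   `pvalue` column (see [correlation_pvalue()]); if absent, p-values are
#'   computed from `r` and `n_samples`.
#' @param n_samples Sample count behind the correlations; defaults to the
#'   `n_samples` attribute of `pairs`.
#' @param fdr_max Edge FDR threshold (default 0.05).
#' @param nodes Optional character vector of node names to retain even if
#'   isolated; defaults to all genes appearing in `pairs`.
#' @return An undirected [igraph][igraph::igraph-package] graph with edge
#'   attributes `r`, `pvalue`, `qvalue`, `weight` (`|r|`, used by
#'   weighted centrality) and graph attributes `n_samples_used`,
#'   `fdr_max`.
#' @export
build_gcn <- function(pairs, n_samples = attr(pairs, "n_samples"),
                      fdr_max = 0.05, nodes = NULL) {
  check_number(fdr_max, "fdr_max", lower = 0, upper = 1)
  if (is.null(pairs$pvalue)) {
    pairs$pvalue <- correlation_pvalue(pairs$r, n_samples)
  }
  if (any(pairs$pvalue < 0 | pairs$pvalue > 1)) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  pairs$qvalue <- p.adjust(pairs$pvalue, method = "BH")
  if (is.null(nodes)) nodes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  keep <- pairs$qvalue < fdr_max
  g <- igraph::graph_from_data_frame(
    pairs[keep, c("gene_a", "gene_b", "r", "pvalue", "qvalue")],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  # absolute correlation as edge weight; igraph centrality picks it up
  g <- igraph::set_edge_attr(g, "weight", value = abs(igraph::E(g)$r))
  g <- igraph::set_graph_attr(g, "n_samples_used", n_samples)
  igraph::set_graph_attr(g, "fdr_max", fdr_max)
}

#' Co-expression network from an expression matrix
#'
#' Convenience wrapper: [pairwise_correlation()] over the given genes,
#' [correlation_pvalue()] on the pooled sample count, then [build_gcn()].
#'
#' @inheritParams pairwise_correlation
#' @inheritParams build_gcn
#' @return See [build_gcn()].
#' @export
coexpression_network <- function(expr, genes = rownames(expr), fdr_max = 0.05) {
  pairs <- pairwise_correlation(expr, genes)
  pairs$pvalue <- correlation_pvalue(pairs$r, attr(pairs, "n_samples"))
  present <- sort(unique(intersect(genes, rownames(expr))))
  build_gcn(pairs, n_samples = attr(pairs, "n_samples"), fdr_max = fdr_max,
            nodes = present)
}
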