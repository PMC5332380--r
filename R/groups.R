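# Pathway over-representation, background-network merge, responsive
# sub-network extraction, and leading-eigenvector functional grouping.

#' Assemble a pathway collection
#'
#' @param sets Named list: pathway id -> character vector of member genes.
#' @param graphs Named list: pathway id -> two-column data frame of
#'   undirected gene-gene edges (`gene_a`, `gene_b`); may be `NULL` for
#'   pathways without topology.
#' @param universe Character vector of all genes considered measurable.
#' @return List of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, graphs = NULL, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  if (!is.null(graphs)) {
    for (id in names(graphs)) {
      e <- graphs[[id]]
      if (is.null(e) || nrow(e) == 0) next
      ends <- unique(c(e[[1]], e[[2]]))
      if (!all(ends %in% sets[[id]])) {
        stop(sprintf("pathway '%s' has edges outside its gene set", id),
             call. = FALSE)
      }
    }
  }
  structure(list(sets = sets, graphs = graphs, universe = unique(universe)),
            class = "pathway_collection")
}

#' Over-representation analysis (hypergeometric test)
#'
#' Upper-tail hypergeometric p-value for the overlap between the query
#' set and each pathway's gene set within the universe. A pathway is
#' enriched when `pvalue < p_max` (strict).
#'
#' @param query Character vector of genes of interest.
#' @param collection A [pathway_collection()].
#' @param p_max Enrichment threshold (default 0.05).
#' @return Data frame `pathway_id`, `size` (in-universe pathway size),
#'   `overlap`, `pvalue`, `enriched`, ordered as in the collection.
#' @export
ora <- function(query, collection, p_max = 0.05) {
  stopifnot(inherits(collection, "pathway_collection"))
  check_number(p_max, "p_max", lower = 0, upper = 1)
  universe <- collection$universe
  query <- intersect(unique(query), universe)
  nq <- length(query)
  res <- lapply(names(collection$sets), function(id) {
    set <- intersect(collection$sets[[id]], universe)
    k <- length(intersect(query, set))
    # P(X >= k) for X ~ Hypergeom(|set| white, |U|-|set| black, nq drawn)
    p <- phyper(k - 1, length(set), length(universe) - length(set), nq,
                lower.tail = FALSE)
    data.frame(pathway_id = id, size = length(set), overlap = k, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$enriched <- out$pvalue < p_max
  out
}

#' Merge enriched pathway graphs into a background network
#'
#' Takes the node and edge union of the enriched pathways' graphs,
#' discards direction, drops self-loops and collapses parallel edges.
#' Vertex attribute `pathways` records which pathways each gene belongs
#' to (semicolon-separated).
#'
#' @param enriched Character vector of pathway ids, or the output of
#'   [ora()] (its `enriched` rows are used).
#' @param collection A [pathway_collection()] supplying the graphs.
#' @return Undirected simple igraph graph.
#' @export
merge_pathways <- function(enriched, collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (is.data.frame(enriched)) enriched <- enriched$pathway_id[enriched$enriched]
  if (length(enriched) == 0) stop("no enriched pathways to merge", call. = FALSE)
  edges <- list()
  nodes <- character(0)
  for (id in enriched) {
    e <- collection$graphs[[id]]
    if (is.null(e)) {
      warning(sprintf("enriched pathway '%s' has no graph; skipped", id),
              call. = FALSE)
      next
    }
    edges[[id]] <- data.frame(gene_a = as.character(e[[1]]),
                              gene_b = as.character(e[[2]]),
                              stringsAsFactors = FALSE)
    nodes <- union(nodes, collection$sets[[id]])
  }
  if (length(edges) == 0) stop("none of the enriched pathways has a graph", call. = FALSE)
  ed <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = sort(nodes)))
  g <- igraph::simplify(g)
  membership <- vapply(igraph::V(g)$name, function(gene) {
    paste(enriched[vapply(enriched,
                          function(id) gene %in% collection$sets[[id]],
                          logical(1))], collapse = ";")
  }, character(1))
  igraph::set_vertex_attr(g, "pathways", value = unname(membership))
}

#' Extract the responsive-gene sub-network
#'
#' Induced subgraph of the background network on the responsive genes:
#' an edge survives iff both endpoints are responsive.
#'
#' @param background Background network from [merge_pathways()].
#' @param responsive Character vector of responsive genes (e.g.
#'   treated-vs-disease DEGs).
#' @return Undirected igraph graph.
#' @export
extract_subnetwork <- function(background, responsive) {
  keep <- intersect(igraph::V(background)$name, responsive)
  if (length(keep) == 0) {
    stop("no responsive genes present in the background network", call. = FALSE)
  }
  igraph::induced_subgraph(background, keep)
}

#' Functional groups by leading-eigenvector modularity
#'
#' Newman's spectral community detection: connected components are
#' processed independently; within a component the (generalized)
#' modularity matrix `B_ij = A_ij - k_i k_j / (2m)` is split by the sign
#' of its leading eigenvector, each split is fine-tuned by
#' Kernighan-Lin-style single-vertex moves (greedy passes, best prefix
#' kept), and the recursion stops when the leading eigenvalue is at most
#' `eps` or the tuned split no longer increases modularity. Exact zero
#' eigenvector entries go to the positive side (the eigenvector's
#' overall sign is fixed so this is deterministic). Isolated nodes form
#' singleton groups.
#'
#' @param subnetwork Undirected igraph graph.
#' @param eps Tolerance on the leading eigenvalue below which a subgraph
#'   is considered indivisible (default 1e-8).
#' @return List of class `functional_groups`: `membership` (data frame
#'   `group_id`, `gene`), `modularity` of the partition, and `groups`
#'   (list of gene vectors).
# Kernighan-Lin fine-tuning of a +/-1 split vector against a
# (generalized) modularity matrix: greedy passes in which every vertex is
# flipped exactly once in order of best immediate gain, keeping the
# prefix of moves with the highest cumulative objective. s'Bs is the
# objective up to a constant factor.
kl_refine <- function(Bg, s, tol = 1e-12) {
  n <- length(s)
  repeat {
    g <- as.numeric(Bg %*% s)
    locked <- rep(FALSE, n)
    flips <- integer(n)
    cum <- numeric(n)
    total <- 0
    for (step in seq_len(n)) {
      # flipping i changes s'Bs by 4*(B_ii - s_i * g_i)
      gain <- 4 * (diag(Bg) - s * g)
      gain[locked] <- -Inf
      i <- which.max(gain)
      total <- total + gain[i]
      s[i] <- -s[i]
      g <- g + 2 * s[i] * Bg[, i]
      locked[i] <- TRUE
      flips[step] <- i
      cum[step] <- total
    }
    best <- which.max(cum)
    if (cum[best] <= tol) {
      # no improving prefix: undo the whole pass
      for (i in flips) s[i] <- -s[i]
      return(s)
    }
    # undo moves after the best prefix and try another pass
    for (i in flips[seq(best + 1, length.out = n - best)]) s[i] <- -s[i]
  }
}

#' @export
detect_groups <- function(subnetwork, eps = 1e-8) {
  n <- igraph::vcount(subnetwork)
  if (n == 0) stop("empty sub-network", call. = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(subnetwork, type = "both"))
  comp <- igraph::components(subnetwork)
  groups <- list()

  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) == 1 || sum(A[members, members]) == 0) {
      groups[[length(groups) + 1]] <- members
      next
    }
    Ac <- A[members, members, drop = FALSE]
    deg <- rowSums(Ac)
    m2 <- sum(deg)  # 2m for this component
    B <- Ac - outer(deg, deg) / m2

    recurse <- function(idx) {
      if (length(idx) == 1) {
        groups[[length(groups) + 1]] <<- members[idx]
        return(invisible())
      }
      Bg <- B[idx, idx, drop = FALSE]
      diag(Bg) <- diag(Bg) - rowSums(B[idx, idx, drop = FALSE])
      es <- eigen(Bg, symmetric = TRUE)
      lambda <- es$values[1]
      if (lambda <= eps) {
        groups[[length(groups) + 1]] <<- members[idx]
        return(invisible())
      }
      v <- es$vectors[, 1]
      nz <- which(abs(v) > 1e-12)
      if (length(nz) > 0 && v[nz[1]] < 0) v <- -v  # fix sign: zeros join "+"
      s <- ifelse(v >= 0, 1, -1)
      s <- kl_refine(Bg, s)
      if (all(s == 1) || all(s == -1)) {
        groups[[length(groups) + 1]] <<- members[idx]
        return(invisible())
      }
      dq <- as.numeric(t(s) %*% Bg %*% s) / (2 * m2)
      if (dq <= 1e-12) {
        groups[[length(groups) + 1]] <<- members[idx]
        return(invisible())
      }
      recurse(idx[s > 0])
      recurse(idx[s < 0])
    }
    recurse(seq_along(members))
  }

  membership <- integer(n)
  for (gi in seq_along(groups)) membership[groups[[gi]]] <- gi
  mod <- igraph::modularity(subnetwork, membership)
  gene_names <- igraph::V(subnetwork)$name
  df <- data.frame(group_id = membership, gene = gene_names,
                   stringsAsFactors = FALSE)
  df <- df[order(df$group_id, df$gene), ]
  rownames(df) <- NULL
  structure(list(
    membership = df,
    modularity = mod,
    groups = lapply(seq_along(groups), function(gi) sort(gene_names[groups[[gi]]]))
  ), class = "functional_groups")
}

#' @export
print.functional_groups <- function(x, ...) {
  cat(sprintf("functional_groups: %d groups over %d genes (Q = %.4f)\n",
              length(x$groups), nrow(x$membership), x$modularity))
  invisible(x)
}
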