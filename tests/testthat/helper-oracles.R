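# Independent oracle implementations used to validate package routines.
# These deliberately use different algorithms / code paths than the
# package (power iteration, exhaustive enumeration, direct formulas).

# PageRank by damped power iteration on an igraph graph; dangling nodes
# redistribute uniformly. Supports optional edge weights.
oracle_pagerank <- function(g, damping = 0.85, weights = NULL, iter = 10000,
                            tol = 1e-15) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, type = "both", attr = if (is.null(weights)) NULL else weights))
  out_strength <- colSums(A)
  dangling <- out_strength == 0
  M <- A
  M[, !dangling] <- sweep(A[, !dangling, drop = FALSE], 2,
                          out_strength[!dangling], "/")
  x <- rep(1 / n, n)
  for (i in seq_len(iter)) {
    x_new <- (1 - damping) / n +
      damping * (M %*% x + sum(x[dangling]) / n)
    x_new <- as.numeric(x_new)
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  stats::setNames(x, igraph::V(g)$name)
}

# Benjamini-Hochberg step-up adjustment from its textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- Inf
  for (i in m:1) {
    run <- min(run, m / i * sorted[i])
    adj[i] <- min(run, 1)
  }
  adj[order(o)]
}

# Hochberg step-up adjustment: adjusted p_(i) = min_{j >= i} (m-j+1) p_(j).
oracle_hochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min((m - seq(i, m) + 1) * sorted[seq(i, m)]))
  }, numeric(1))
  adj[order(o)]
}

# Enrichment score by literal position-by-position recomputation of the
# running sums, no shortcuts.
oracle_es <- function(genes, scores, C) {
  n_genelist <- length(genes)
  n_group <- length(unique(C))
  n_diff <- length(setdiff(C, genes))
  p_hit <- 0
  p_miss <- 0
  best <- -Inf
  for (i in seq_len(n_genelist)) {
    if (genes[i] %in% C) {
      p_hit <- p_hit + scores[i]
    } else {
      p_miss <- p_miss + n_diff / (n_genelist * n_group)
    }
    best <- max(best, p_hit - p_miss)
  }
  best
}

# Exhaustive best-bipartition modularity over all 2-colourings.
oracle_best_bipartition <- function(g) {
  n <- igraph::vcount(g)
  best <- igraph::modularity(g, rep(1, n))
  if (n < 2) return(best)
  for (code in 1:(2^(n - 1) - 1)) {
    side <- as.integer(intToBits(code))[1:n] + 1L
    q <- igraph::modularity(g, side)
    if (q > best) best <- q
  }
  best
}

# Two-sided tail mass of the t distribution by numerical integration.
oracle_t_twosided <- function(tval, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tval), Inf, rel.tol = 1e-13)$value
}

# Hypergeometric upper-tail probability from the factorial formula.
oracle_hyper_upper <- function(k_min, set_size, universe_size, query_size) {
  kk <- k_min:min(set_size, query_size)
  sum(vapply(kk, function(k) {
    choose(set_size, k) * choose(universe_size - set_size, query_size - k) /
      choose(universe_size, query_size)
  }, numeric(1)))
}

# Small deterministic graphs used across tests --------------------------

graph_from_edges <- function(edges, n = NULL, names = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(n) && igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  if (is.null(names)) names <- paste0("g", seq_len(igraph::vcount(g)))
  igraph::set_vertex_attr(g, "name", value = names)
}

random_gnp_named <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = sprintf("g%02d", seq_len(n)))
}

# Priority list literal constructor for hand examples.
make_L <- function(genes, scores) {
  out <- data.frame(gene = genes, score = scores, stringsAsFactors = FALSE)
  attr(out, "n_genelist") <- nrow(out)
  class(out) <- c("priority_list", "data.frame")
  out
}
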