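# PageRank centrality, targeted-attack robustness curves, keystone (hub)
# gene selection.

#' PageRank centrality ranking
#'
#' Stationary scores of the damped random walk on the undirected network
#' (dangling and isolated nodes redistribute uniformly). When the graph
#' carries a `weight` edge attribute (a co-expression network stores
#' `|r|` there) the walk follows edges proportionally to weight;
#' otherwise edges are equally likely. Genes are returned in decreasing
#' score order; exact ties are broken by gene identifier so the ranking
#' is fully deterministic.
#'
#' @param network An igraph graph (e.g. from [build_gcn()]).
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tolerance Convergence tolerance recorded in the output metadata
#'   (the exact algebraic solver is used, so it is not iterated against).
#' @return Data frame `gene`, `score`, `rank` with attributes `damping`
#'   and `tolerance`. Scores sum to 1.
#' @export
pagerank_ranking <- function(network, damping = 0.85, tolerance = 1e-12) {
  check_number(damping, "damping", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (igraph::vcount(network) == 0) stop("network is empty", call. = FALSE)
  pr <- igraph::page_rank(network, damping = damping, algo = "prpack")$vector
  # round away solver noise so exact ties fall back to the identifier
  ord <- order(-signif(pr, 10), names(pr))
  out <- data.frame(gene = names(pr)[ord], score = unname(pr[ord]),
                    rank = seq_along(pr), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "damping") <- damping
  attr(out, "tolerance") <- tolerance
  out
}

lcc_fraction <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  max(igraph::components(g)$csize) / n
}

#' Network degradation under node removal
#'
#' For k = 0..N removes the first k genes of `order` (targeted mode) or k
#' uniformly sampled genes averaged over `random_repeats` draws (random
#' mode) and records the size of the largest connected component as a
#' fraction of the *remaining* node count. At k = N the fraction is 0 by
#' convention.
#'
#' @param network An igraph graph.
#' @param order Removal order (targeted mode must cover all nodes).
#' @param mode `"targeted"` or `"random"`.
#' @param random_repeats Number of random removal orders to average.
#' @param seed Seed for random mode.
#' @return Data frame `k`, `lcc_fraction`, `mode`.
#' @export
attack_curve <- function(network, order = NULL,
                         mode = c("targeted", "random"),
                         random_repeats = 20, seed = 1) {
  mode <- match.arg(mode)
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  one_run <- function(ord) {
    g <- network
    frac <- numeric(n + 1)
    frac[1] <- lcc_fraction(g)
    for (k in seq_len(n)) {
      g <- igraph::delete_vertices(g, ord[k])
      frac[k + 1] <- lcc_fraction(g)
    }
    frac
  }
  if (mode == "targeted") {
    if (is.null(order) || !setequal(order, nodes)) {
      stop("targeted mode requires `order` to cover exactly the network nodes",
           call. = FALSE)
    }
    frac <- one_run(order)
  } else {
    check_number(random_repeats, "random_repeats", lower = 1, integerish = TRUE)
    frac <- with_seed(seed, {
      rowMeans(vapply(seq_len(random_repeats),
                      function(i) one_run(sample(nodes)), numeric(n + 1)))
    })
  }
  data.frame(k = 0:n, lcc_fraction = frac, mode = mode,
             stringsAsFactors = FALSE)
}

#' Select keystone genes from the ranking and attack curve
#'
#' Default rule (`"collapse_threshold"`): the keystone set is the top-k
#' prefix of the ranking for the smallest k whose removal drives the
#' largest-connected-component fraction below `theta`. If the curve never
#' crosses `theta` the rule falls back to the maximum-curvature (elbow)
#' point of the targeted curve with a warning. `rule = "elbow"` uses the
#' elbow directly (k maximizing the discrete second difference of the
#' curve).
#'
#' @param ranking Centrality ranking from [pagerank_ranking()].
#' @param curve Targeted attack curve computed from the same order.
#' @param theta Collapse threshold on the LCC fraction (default 0.10).
#' @param rule `"collapse_threshold"` (default) or `"elbow"`.
#' @return List of class `keystone_set`: `genes` (prefix of the ranking),
#'   `k`, `rule`, `theta`.
#' @export
select_keystones <- function(ranking, curve, theta = 0.10,
                             rule = c("collapse_threshold", "elbow")) {
  rule <- match.arg(rule)
  check_number(theta, "theta", lower = 0, upper = 1)
  stopifnot(all(c("k", "lcc_fraction") %in% names(curve)))
  frac <- curve$lcc_fraction[order(curve$k)]
  used_rule <- rule
  k <- NA_integer_
  if (rule == "collapse_threshold") {
    below <- which(frac < theta)
    if (length(below) > 0) {
      k <- curve$k[order(curve$k)][below[1]]
    } else {
      warning("attack curve never falls below theta; falling back to elbow rule",
              call. = FALSE)
      used_rule <- "elbow_fallback"
    }
  }
  if (is.na(k)) {
    # interior point of maximum discrete curvature
    if (length(frac) < 3) {
      k <- length(frac) - 1L
    } else {
      d2 <- frac[1:(length(frac) - 2)] - 2 * frac[2:(length(frac) - 1)] +
        frac[3:length(frac)]
      k <- which.max(d2)  # curve index k corresponds to d2 position
    }
  }
  structure(list(genes = head(ranking$gene, k), k = as.integer(k),
                 rule = used_rule, theta = theta),
            class = "keystone_set")
}

#' @export
print.keystone_set <- function(x, ...) {
  cat(sprintf("keystone_set: %d genes (rule = %s, theta = %g)\n",
              x$k, x$rule, x$theta))
  invisible(x)
}
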