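# Keystone-gene-based group significance analysis: scaled-PageRank
# priority list, running-sum enrichment score, Monte Carlo null,
# Simes-Hochberg adjustment.

#' Min-max scale centrality scores to [0, 1]
#'
#' `s = (score - min) / (max - min)`. When all scores are equal the range
#' is zero and every scaled score is set to 0 with a warning (declared
#' convention; a constant ranking carries no priority information).
#'
#' @param ranking Data frame from [pagerank_ranking()] or a named numeric
#'   vector of scores.
#' @return Named numeric vector of scaled scores.
#' @export
scale_scores <- function(ranking) {
  if (is.data.frame(ranking)) {
    scores <- stats::setNames(ranking$score, ranking$gene)
  } else {
    scores <- ranking
  }
  if (length(scores) == 0) stop("empty ranking", call. = FALSE)
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    warning("all scores equal; scaled scores set to 0", call. = FALSE)
    return(stats::setNames(rep(0, length(scores)), names(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Build the keystone priority list
#'
#' The priority list L holds the keystone genes that are nodes of the
#' pathway sub-network, ordered by scaled PageRank score descending
#' (ties broken by gene identifier ascending).
#'
#' @param keystones A [select_keystones()] result or character vector.
#' @param subnetwork Sub-network from [extract_subnetwork()], or a
#'   character vector of its gene names.
#' @param scaled Named numeric vector of scaled scores covering the
#'   keystones (see [scale_scores()]).
#' @return Data frame of class `priority_list` with columns `gene`,
#'   `score`, ordered; attribute `n_genelist` is its length.
#' @export
build_priority_list <- function(keystones, subnetwork, scaled) {
  if (inherits(keystones, "keystone_set")) keystones <- keystones$genes
  sub_genes <- if (inherits(subnetwork, "igraph")) {
    igraph::V(subnetwork)$name
  } else {
    subnetwork
  }
  genes <- intersect(keystones, sub_genes)
  if (length(genes) == 0) {
    stop("no keystone genes are present in the sub-network", call. = FALSE)
  }
  miss <- setdiff(genes, names(scaled))
  if (length(miss) > 0) {
    stop(sprintf("scaled scores missing for: %s",
                 paste(head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  s <- scaled[genes]
  ord <- order(-s, genes)
  out <- data.frame(gene = genes[ord], score = unname(s[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_genelist") <- nrow(out)
  class(out) <- c("priority_list", "data.frame")
  out
}

#' Running-sum enrichment score of a functional group
#'
#' Walks down the priority list L. At position i, a gene of group C adds
#' its scaled score to the hit sum P_hit; a gene outside C adds the
#' constant penalty `N_diff / (N_genelist * N_group)` to the miss sum
#' P_miss, where `N_diff = |C \ L|` is the number of group genes missing
#' from the list, `N_genelist = |L|` and `N_group = |C|`. The enrichment
#' score is `max_i (P_hit(i) - P_miss(i))`; it may be negative (a group
#' disjoint from L scores the negative penalty of the first position).
#' When `N_diff = 0` the penalty vanishes and ES equals the sum of the
#' member scores.
#'
#' @param L A [build_priority_list()] result (columns `gene`, `score`).
#' @param C Character vector: the functional group's member genes.
#' @return List of class `enrichment_score`: `es`, `n_diff`, `n_group`,
#'   `running` (the full running-sum vector along L).
#' @export
enrichment_score <- function(L, C) {
  stopifnot(nrow(L) > 0, length(C) > 0)
  C <- unique(C)
  n_genelist <- nrow(L)
  n_group <- length(C)
  hit <- L$gene %in% C
  n_diff <- n_group - sum(hit)
  penalty <- n_diff / (n_genelist * n_group)
  running <- cumsum(ifelse(hit, L$score, -penalty))
  structure(list(es = max(running), n_diff = n_diff, n_group = n_group,
                 running = running),
            class = "enrichment_score")
}

# Fast ES used inside the Monte Carlo loop: the running sum can only
# attain its maximum at a hit position (scores are >= 0 and the penalty
# is constant), or at position 1 when the walk starts with a miss.
es_from_hits <- function(scores, hit_pos, n_genelist, n_group) {
  n_hit <- length(hit_pos)
  n_diff <- n_group - n_hit
  penalty <- n_diff / (n_genelist * n_group)
  if (n_hit == 0) return(-penalty)
  hp <- sort(hit_pos)
  vals <- cumsum(scores[hp]) - penalty * (hp - seq_len(n_hit))
  if (hp[1] > 1) max(-penalty, max(vals)) else max(vals)
}

#' Monte Carlo null distribution of the enrichment score
#'
#' Repeats B times: sample `group_size` genes uniformly without
#' replacement from the background-network nodes to form a random group,
#' and recompute its enrichment score against the same priority list.
#' Background genes absent from L contribute through the `N_diff`
#' penalty, exactly as for observed groups.
#'
#' @param L A [build_priority_list()] result.
#' @param group_size Size of the random groups (`N_C`).
#' @param background Background network (igraph) or character vector of
#'   its gene names.
#' @param B Number of simulations (default 10,000).
#' @param seed Integer seed; identical inputs give identical nulls.
#' @return List of class `null_distribution`: `es_null` (length B),
#'   `B`, `group_size`, `seed`.
#' @export
null_distribution <- function(L, group_size, background, B = 10000, seed = 1) {
  bg <- if (inherits(background, "igraph")) {
    igraph::V(background)$name
  } else {
    unique(background)
  }
  check_number(group_size, "group_size", lower = 1, integerish = TRUE)
  check_number(B, "B", lower = 1, integerish = TRUE)
  if (group_size > length(bg)) {
    stop("group_size exceeds the number of background-network genes",
         call. = FALSE)
  }
  n_genelist <- nrow(L)
  pos_in_L <- match(bg, L$gene)  # NA for background genes outside L
  scores <- L$score
  es_null <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      draw <- sample.int(length(bg), group_size)
      hp <- pos_in_L[draw]
      es_from_hits(scores, hp[!is.na(hp)], n_genelist, group_size)
    }, numeric(1))
  })
  structure(list(es_null = es_null, B = as.integer(B),
                 group_size = as.integer(group_size), seed = as.integer(seed)),
            class = "null_distribution")
}

#' Nominal Monte Carlo p-value
#'
#' `P(C) = #(ES_NULL >= ES_obs) / B`, ties counted. A zero p-value only
#' means the observed ES exceeded every simulated one; the display layer
#' renders it as `"<1/B"` (see [format_nominal_p()]).
#'
#' @param es_obs Observed enrichment score.
#' @param null A [null_distribution()].
#' @return Numeric p-value in `[0, 1]`.
#' @export
nominal_p <- function(es_obs, null) {
  stopifnot(inherits(null, "null_distribution"), length(null$es_null) > 0)
  sum(null$es_null >= es_obs) / null$B
}

#' Simes-Hochberg step-up adjustment
#'
#' For order statistics `p_(1) <= ... <= p_(m)`, the adjusted value of
#' `p_(i)` is `min_{j >= i} (m - j + 1) * p_(j)`, clipped at 1 and mapped
#' back to the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
hochberg_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "hochberg")
}

#' Flag significant functional groups
#'
#' @param results Data frame with an `adjusted_p` column (see
#'   [group_significance()]).
#' @param adjusted_max Significance threshold on the adjusted p-value
#'   (default 0.005, strict).
#' @return `results` with a logical `significant` column.
#' @export
filter_significant <- function(results, adjusted_max = 0.005) {
  check_number(adjusted_max, "adjusted_max", lower = 0, upper = 1)
  stopifnot("adjusted_p" %in% names(results))
  results$significant <- results$adjusted_p < adjusted_max
  results
}

#' Keystone-gene-based group significance analysis
#'
#' Scores every functional group against the keystone priority list and
#' estimates significance: running-sum ES, Monte Carlo nominal p over
#' random same-size groups drawn from the background network (nulls are
#' shared between groups of equal size), Simes-Hochberg adjustment across
#' all groups, and the significance call `adjusted_p < adjusted_max`.
#'
#' @param groups A [detect_groups()] result or a named list of gene
#'   vectors.
#' @param L A [build_priority_list()] result.
#' @param background Background network (igraph) or character vector.
#' @param B Monte Carlo simulations per null (default 10,000).
#' @param seed Integer seed. Each distinct group size uses a sub-seed
#'   derived from it.
#' @param adjusted_max Adjusted-p significance threshold (default 0.005).
#' @return Data frame `group_id`, `es`, `n_group`, `n_diff`, `nominal_p`,
#'   `adjusted_p`, `significant`, ordered by decreasing ES; attribute
#'   `B`.
#' @export
group_significance <- function(groups, L, background, B = 10000, seed = 1,
                               adjusted_max = 0.005) {
  if (inherits(groups, "functional_groups")) {
    sets <- groups$groups
    names(sets) <- sprintf("group_%02d", seq_along(sets))
  } else {
    sets <- groups
    if (is.null(names(sets))) {
      names(sets) <- sprintf("group_%02d", seq_along(sets))
    }
  }
  stopifnot(length(sets) > 0)

  es <- lapply(sets, function(C) enrichment_score(L, C))
  sizes <- vapply(es, function(e) e$n_group, integer(1))
  nulls <- list()
  for (sz in sort(unique(sizes))) {
    nulls[[as.character(sz)]] <-
      null_distribution(L, sz, background, B = B, seed = seed + sz)
  }
  nom <- vapply(seq_along(sets), function(i) {
    nominal_p(es[[i]]$es, nulls[[as.character(sizes[i])]])
  }, numeric(1))

  out <- data.frame(
    group_id = names(sets),
    es = vapply(es, function(e) e$es, numeric(1)),
    n_group = sizes,
    n_diff = vapply(es, function(e) e$n_diff, integer(1)),
    nominal_p = nom,
    adjusted_p = hochberg_adjust(nom),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- filter_significant(out, adjusted_max)
  out <- out[order(-out$es, out$group_id), ]
  rownames(out) <- NULL
  attr(out, "B") <- as.integer(B)
  out
}
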