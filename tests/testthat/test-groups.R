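toy_collection <- function() {
  sets <- list(
    pwA = c("a", "b", "c", "d", "e"),
    pwB = c("d", "e", "f", "g", "h"),
    pwC = c("x", "y", "z")
  )
  graphs <- list(
    pwA = data.frame(gene_a = c("a", "b", "c", "d"),
                     gene_b = c("b", "c", "d", "e")),
    pwB = data.frame(gene_a = c("d", "f", "g"),
                     gene_b = c("e", "g", "h")),
    pwC = data.frame(gene_a = c("x", "y"), gene_b = c("y", "z"))
  )
  pathway_collection(sets, graphs,
                     universe = c(letters[1:8], "x", "y", "z",
                                  sprintf("u%02d", 1:9)))
}

test_that("ORA p-values follow the hypergeometric tail", {
  coll <- toy_collection()
  # query identical to pwC against a 20-gene universe
  res <- ora(c("x", "y", "z"), coll)
  expect_equal(res$pvalue[res$pathway_id == "pwC"], min(res$pvalue))
  expect_true(res$enriched[res$pathway_id == "pwC"])
  # disjoint query: upper tail at overlap 0 includes 0, so p = 1
  res2 <- ora(sprintf("u%02d", 1:5), coll)
  expect_equal(res2$pvalue[res2$pathway_id == "pwA"], 1)

  # hand case: universe 20, pathway 5, query 6, overlap 4
  sets <- list(pw = letters[1:5])
  coll20 <- pathway_collection(sets, NULL, universe = letters[1:20])
  query <- c(letters[1:4], "r", "s")
  res3 <- ora(query, coll20)
  expect_equal(res3$pvalue, oracle_hyper_upper(4, 5, 20, 6), tolerance = 1e-12)
  expect_error(pathway_collection(sets, NULL, character(0)), "universe")
})

test_that("background merge takes the simple undirected union", {
  coll <- toy_collection()
  g1 <- merge_pathways("pwA", coll)
  expect_equal(igraph::vcount(g1), 5)
  expect_equal(igraph::ecount(g1), 4)

  # pwA and pwC share no genes: sizes add
  g2 <- merge_pathways(c("pwA", "pwC"), coll)
  expect_equal(igraph::vcount(g2), 8)
  expect_equal(igraph::ecount(g2), 6)

  # pwA and pwB overlap in genes d, e and share the edge d-e:
  # nodes a..h = 8; edges {ab, bc, cd, de} + {de, fg, gh} collapse to 6
  g3 <- merge_pathways(c("pwA", "pwB"), coll)
  expect_equal(igraph::vcount(g3), 8)
  expect_equal(igraph::ecount(g3), 6)
  expect_true(igraph::is_simple(g3))
  d_path <- igraph::V(g3)$pathways[igraph::V(g3)$name == "d"]
  expect_equal(d_path, "pwA;pwB")
})

test_that("merging warns and skips pathways without graphs", {
  sets <- list(p1 = c("a", "b"), p2 = c("c", "d"))
  graphs <- list(p1 = data.frame(gene_a = "a", gene_b = "b"))
  coll <- pathway_collection(sets, graphs, universe = letters[1:6])
  expect_warning(g <- merge_pathways(c("p1", "p2"), coll), "no graph")
  expect_equal(igraph::vcount(g), 2)
})

test_that("sub-network extraction filters edges on both endpoints", {
  coll <- toy_collection()
  bg <- merge_pathways(c("pwA", "pwB"), coll)
  expect_equal(igraph::ecount(extract_subnetwork(bg, letters[1:8])),
               igraph::ecount(bg))
  iso <- extract_subnetwork(bg, c("a", "c", "h"))
  expect_equal(igraph::ecount(iso), 0)
  expect_equal(igraph::vcount(iso), 3)
  # brute-force both-endpoints filter on a toy case
  responsive <- c("a", "b", "d", "e", "g")
  sub <- extract_subnetwork(bg, responsive)
  full <- igraph::as_edgelist(bg)
  manual <- full[full[, 1] %in% responsive & full[, 2] %in% responsive, ,
                 drop = FALSE]
  got <- igraph::as_edgelist(sub)
  expect_equal(apply(got, 1, function(x) paste(sort(x), collapse = "-")),
               apply(manual, 1, function(x) paste(sort(x), collapse = "-")),
               ignore_attr = TRUE)
  expect_error(extract_subnetwork(bg, c("nope")), "no responsive genes")
})

test_that("two disjoint triangles form exactly two groups", {
  g <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3),
                              c(4, 5), c(5, 6), c(4, 6)), n = 6)
  grp <- detect_groups(g)
  expect_length(grp$groups, 2)
  expect_setequal(grp$groups[[1]], c("g1", "g2", "g3"))
  expect_setequal(grp$groups[[2]], c("g4", "g5", "g6"))
})

test_that("an indivisible graph stays one group; isolates become singletons", {
  k2 <- graph_from_edges(rbind(c(1, 2)), n = 2)
  expect_length(detect_groups(k2)$groups, 1)
  with_iso <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), n = 5)
  grp <- detect_groups(with_iso)
  sizes <- sort(vapply(grp$groups, length, integer(1)))
  expect_equal(sizes, c(1, 1, 3))
})

test_that("the partition attains the exhaustive bipartition optimum on a bridge graph", {
  # two 5-cliques joined by one bridge edge
  cl <- function(off) t(combn(off + 1:5, 2))
  g <- graph_from_edges(rbind(cl(0), cl(5), c(1, 6)), n = 10)
  grp <- detect_groups(g)
  expect_length(grp$groups, 2)
  expect_setequal(grp$groups[[1]], sprintf("g%d", 1:5))
  expect_equal(grp$modularity, oracle_best_bipartition(g), tolerance = 1e-12)
  # agrees with an independent implementation of the same method
  ig <- igraph::cluster_leading_eigen(g)
  expect_equal(grp$modularity, igraph::modularity(ig), tolerance = 1e-12)
})

test_that("groups partition the nodes and never fall below trivial modularity", {
  set.seed(6)
  for (i in 1:5) {
    g <- random_gnp_named(12, 0.25)
    grp <- detect_groups(g)
    expect_setequal(grp$membership$gene, igraph::V(g)$name)
    expect_equal(anyDuplicated(grp$membership$gene), 0)
    expect_gte(grp$modularity, 0)
  }
})

test_that("group detection is invariant to relabeling up to renumbering", {
  set.seed(10)
  g <- random_gnp_named(10, 0.35)
  grp1 <- detect_groups(g)
  perm <- sample(10)
  grp2 <- detect_groups(igraph::permute(g, perm))
  part <- function(grp) {
    canon <- lapply(grp$groups, sort)
    canon[order(vapply(canon, paste, character(1), collapse = "|"))]
  }
  expect_equal(part(grp1), part(grp2))
})
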