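spec_L <- function() {
  make_L(c("a", "b", "c", "d", "e"), c(1.0, 0.8, 0.5, 0.2, 0.0))
}

test_that("score scaling is the min-max affine map", {
  expect_equal(unname(scale_scores(c(a = 2, b = 4, c = 6))), c(0, 0.5, 1))
  expect_warning(s1 <- scale_scores(c(a = 3)), "equal")
  expect_equal(unname(s1), 0)
  set.seed(14)
  x <- stats::setNames(runif(100), sprintf("g%03d", 1:100))
  expect_equal(scale_scores(x), (x - min(x)) / (max(x) - min(x)),
               tolerance = 1e-15)
  expect_error(scale_scores(numeric(0)), "empty")
})

test_that("the priority list is the ordered keystone/sub-network intersection", {
  scaled <- c(k1 = 0.9, k2 = 0.3, k3 = 0.9, k4 = 0.1, k5 = 1.0, k6 = 0.0)
  sub <- c("k1", "k3", "k5", "k6", "other")
  L <- build_priority_list(paste0("k", 1:6), sub, scaled)
  expect_equal(L$gene, c("k5", "k1", "k3", "k6"))  # tie k1/k3 by identifier
  expect_equal(L$score, c(1.0, 0.9, 0.9, 0.0))
  expect_equal(attr(L, "n_genelist"), 4)
  expect_error(build_priority_list(c("k1", "k2"), c("x", "y"), scaled),
               "no keystone")
})

test_that("enrichment score reproduces hand-walked running sums", {
  L <- spec_L()
  # zero-penalty case: all members in L, ES is the member score sum
  es1 <- enrichment_score(L, c("a", "b"))
  expect_equal(es1$es, 1.8, tolerance = 1e-12)
  expect_equal(es1$n_diff, 0)
  # fully disjoint group: constant penalty 2/(5*2), maximum at position 1
  es2 <- enrichment_score(L, c("x", "y"))
  expect_equal(es2$running, c(-0.2, -0.4, -0.6, -0.8, -1.0),
               tolerance = 1e-12)
  expect_equal(es2$es, -0.2, tolerance = 1e-12)
  # mixed group with one missing member, penalty 1/15
  es3 <- enrichment_score(L, c("b", "d", "z"))
  expect_equal(es3$running,
               c(-1 / 15, 0.8 - 1 / 15, 0.8 - 2 / 15, 1.0 - 2 / 15, 1.0 - 3 / 15),
               tolerance = 1e-12)
  expect_equal(es3$es, 0.8667, tolerance = 1e-4)
  expect_equal(es3$n_diff, 1)
  expect_equal(es3$n_group, 3)
})

test_that("enrichment score equals exhaustive recomputation on random cases", {
  set.seed(19)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    genes <- sprintf("g%02d", sample(50, n))
    L <- make_L(genes, sort(runif(n), decreasing = TRUE))
    C <- sample(sprintf("g%02d", 1:50), sample(1:8, 1))
    expect_equal(enrichment_score(L, C)$es, oracle_es(L$gene, L$score, C),
                 tolerance = 1e-12)
  }
})

test_that("the fast null-path ES equals the reference walk", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    L <- make_L(sprintf("g%02d", 1:n), sort(runif(n), decreasing = TRUE))
    bg <- sprintf("g%02d", 1:(n + 10))
    size <- sample(1:6, 1)
    C <- sample(bg, size)
    hitpos <- match(intersect(C, L$gene), L$gene)
    fast <- kgsa:::es_from_hits(L$score, hitpos, n, size)
    expect_equal(fast, enrichment_score(L, C)$es, tolerance = 1e-12)
  }
})

test_that("adding a stronger top gene to both list and group never lowers ES", {
  set.seed(29)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    scores <- sort(runif(n, 0, 0.9), decreasing = TRUE)
    L <- make_L(sprintf("g%02d", 1:n), scores)
    C <- sample(L$gene, sample(1:n, 1))
    base <- enrichment_score(L, C)$es
    L2 <- make_L(c("top", L$gene), c(1, scores))
    up <- enrichment_score(L2, c("top", C))$es
    expect_gte(up + 1e-12, base)
  }
})

test_that("null distributions are reproducible and respect degenerate scores", {
  L <- spec_L()
  n1 <- null_distribution(L, 2, letters[1:6], B = 500, seed = 42)
  n2 <- null_distribution(L, 2, letters[1:6], B = 500, seed = 42)
  expect_identical(n1$es_null, n2$es_null)
  expect_length(n1$es_null, 500)
  expect_error(null_distribution(L, 10, letters[1:6], B = 10),
               "group_size exceeds")
  # constant scores: every same-size draw from within L scores identically
  Lc <- make_L(letters[1:4], rep(0, 4))
  nc <- null_distribution(Lc, 2, letters[1:4], B = 50, seed = 1)
  expect_equal(length(unique(nc$es_null)), 1)
})

test_that("nominal p counts ties and is monotone in the observed score", {
  null <- structure(list(es_null = c(1, 2, 3, 4), B = 4L, group_size = 2L,
                         seed = 1L), class = "null_distribution")
  expect_equal(nominal_p(2, null), 3 / 4)
  expect_equal(nominal_p(0.5, null), 1)
  expect_equal(nominal_p(5, null), 0)
  obs <- seq(0, 5, by = 0.5)
  ps <- vapply(obs, nominal_p, numeric(1), null = null)
  expect_true(all(diff(ps) <= 0))
})

test_that("zero nominal p renders as a bound at the Monte Carlo resolution", {
  expect_equal(format_nominal_p(0, 10000), "<0.0001")
  expect_equal(format_nominal_p(c(0.0002, 0), 10000), c("0.0002", "<0.0001"))
})

test_that("Hochberg adjustment matches the min-over-suffix definition", {
  expect_equal(hochberg_adjust(0.03), 0.03)
  set.seed(31)
  for (i in 1:20) {
    p <- round(runif(sample(2:15, 1)), 3)
    adj <- hochberg_adjust(p)
    expect_equal(adj, oracle_hochberg(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(hochberg_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("significance flags use a strict adjusted-p threshold", {
  res <- data.frame(group_id = c("a", "b", "c"),
                    adjusted_p = c(0.0020, 0.005, 0.0049))
  out <- filter_significant(res)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE))
  set.seed(37)
  r2 <- data.frame(adjusted_p = runif(50))
  expect_equal(filter_significant(r2, 0.3)$significant, r2$adjusted_p < 0.3)
})

test_that("group significance ranks a top-concentrated group first", {
  set.seed(41)
  L <- make_L(sprintf("g%02d", 1:30), seq(1, 0, length.out = 30))
  background <- sprintf("g%02d", 1:60)
  groups <- list(top = sprintf("g%02d", 1:5),
                 spread = sprintf("g%02d", c(5, 12, 19, 26, 55)),
                 out = sprintf("g%02d", 41:45))
  res <- group_significance(groups, L, background, B = 2000, seed = 3)
  expect_equal(res$group_id[1], "top")
  expect_equal(res$n_diff[res$group_id == "out"], 5L)
  expect_true(res$nominal_p[res$group_id == "top"] <
                res$nominal_p[res$group_id == "out"])
  expect_true(all(res$adjusted_p >= res$nominal_p))
  expect_true(all(res$adjusted_p <= 1))
  # same-size groups share the same null: identical ES implies identical p
  res2 <- group_significance(groups, L, background, B = 2000, seed = 3)
  expect_identical(res$nominal_p, res2$nominal_p)
})
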