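make_toy_counts <- function(values) {
  conds <- rep(c("control", "disease", "treated"), each = 2)
  m <- matrix(values, nrow = length(values) / 6, ncol = 6, byrow = TRUE)
  rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- paste(conds, 1:2, sep = "_")
  count_matrix(m, stats::setNames(conds, colnames(m)))
}

test_that("count_matrix validates its invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  cond <- c(s1 = "control", s2 = "disease", s3 = "treated")
  expect_s3_class(count_matrix(m, cond), "count_matrix")
  expect_error(count_matrix(m - 2, cond), "nonnegative")
  expect_error(count_matrix(m, cond[1:2]), "mapped")
  expect_error(count_matrix(m, c(s1 = "a", s2 = "a", s3 = "b")),
               "three conditions")
  m2 <- m
  rownames(m2) <- c("a", "a")
  expect_error(count_matrix(m2, cond), "duplicate")
})

test_that("TPM normalization gives per-million shares", {
  m <- matrix(c(1, 1, 1, 1, 90, 0, 10, 0, 5, 5, 80, 10), ncol = 3,
              dimnames = list(sprintf("g%d", 1:4), c("s1", "s2", "s3")))
  tpm <- normalize_tpm(m)
  expect_equal(tpm[, "s1"], c(g1 = 250000, g2 = 250000, g3 = 250000,
                              g4 = 250000))
  expect_equal(unname(tpm[c(1, 3), "s2"]), c(900000, 100000))
  expect_equal(unname(colSums(tpm)), rep(1e6, 3), tolerance = 1e-6)
})

test_that("TPM normalization is idempotent and errors on all-zero samples", {
  m <- matrix(c(3, 7, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(normalize_tpm(m), "empty")
  good <- m[, 1, drop = FALSE]
  expect_equal(normalize_tpm(normalize_tpm(good)), normalize_tpm(good))
})

test_that("differential test handles flat genes and sample permutations", {
  # column totals are equal so a constant raw gene stays constant in TPM
  cm <- make_toy_counts(c(5, 5, 5, 5, 5, 5,
                          10, 12, 50, 55, 11, 9,
                          100, 98, 60, 55, 99, 101))
  tab <- test_differential(cm, c("disease", "control"))
  expect_equal(tab$log2fc[tab$gene == "g1"], 0, tolerance = 1e-9)
  # permuting samples within conditions changes nothing
  perm <- c(2, 1, 4, 3, 6, 5)
  cm2 <- count_matrix(cm$values[, perm], cm$conditions[perm])
  tab2 <- test_differential(cm2, c("disease", "control"))
  expect_equal(tab$log2fc, tab2$log2fc)
  expect_equal(tab$pvalue, tab2$pvalue)
  expect_error(test_differential(cm, c("disease", "placebo")), "absent")
})

test_that("an all-zero gene gets log2fc 0 and p 1", {
  cm <- make_toy_counts(c(0, 0, 0, 0, 0, 0,
                          10, 12, 50, 55, 11, 9))
  tab <- test_differential(cm, c("disease", "control"))
  expect_equal(tab$log2fc[tab$gene == "g1"], 0)
  expect_equal(tab$pvalue[tab$gene == "g1"], 1)
})

test_that("precomputed differential tables are ingested verbatim", {
  pre <- data.frame(gene = c("a", "b"), log2fc = c(1.2, -0.3),
                    pvalue = c(0.001, 0.5), fdr = c(0.01, 0.6))
  tab <- test_differential(NULL, c("disease", "control"), precomputed = pre)
  expect_equal(tab$log2fc, pre$log2fc)
  expect_equal(attr(tab, "contrast"), "disease_vs_control")
  bad <- pre
  bad$pvalue[1] <- 1.5
  expect_error(test_differential(NULL, c("a", "b"), precomputed = bad),
               "\\[0, 1\\]")
})

test_that("DEG thresholds are strict and match a brute-force filter", {
  tab <- data.frame(
    gene = sprintf("g%d", 1:6),
    log2fc = c(1.0, 0.58, -0.59, 0.6, -2, 0.2),
    pvalue = rep(0.01, 6),
    fdr = c(0.05, 0.05, 0.09, 0.10, 0.099, 0.01)
  )
  degs <- call_degs(tab)
  manual <- tab$gene[tab$fdr < 0.10 & abs(tab$log2fc) > 0.58]
  expect_setequal(degs$gene, manual)
  expect_false("g2" %in% degs$gene)  # log2fc exactly at threshold
  expect_false("g4" %in% degs$gene)  # fdr exactly at threshold
  expect_equal(degs$direction[degs$gene == "g1"], "up")
  expect_equal(degs$direction[degs$gene == "g5"], "down")
})

test_that("DEG calling is monotone in both thresholds", {
  set.seed(1)
  tab <- data.frame(gene = sprintf("g%d", 1:50),
                    log2fc = rnorm(50), pvalue = runif(50), fdr = runif(50))
  base <- call_degs(tab, fdr_max = 0.2, abs_log2fc_min = 0.5)
  looser_fdr <- call_degs(tab, fdr_max = 0.4, abs_log2fc_min = 0.5)
  looser_fc <- call_degs(tab, fdr_max = 0.2, abs_log2fc_min = 0.2)
  expect_true(all(base$gene %in% looser_fdr$gene))
  expect_true(all(base$gene %in% looser_fc$gene))
})

test_that("reverse regulation keeps opposite-sign overlaps with correct labels", {
  dis <- data.frame(gene = c("a", "b", "c", "d"),
                    direction = c("up", "down", "up", "up"),
                    log2fc = c(2, -2, 1, 1), fdr = rep(0.01, 4))
  trt <- data.frame(gene = c("a", "b", "c", "e"),
                    direction = c("down", "up", "up", "down"),
                    log2fc = c(-2, 2, 1, -1), fdr = rep(0.01, 4))
  rev <- reverse_regulated(dis, trt)
  expect_setequal(rev$gene, c("a", "b"))
  expect_equal(rev$direction[rev$gene == "a"], "inversely_down")
  expect_equal(rev$direction[rev$gene == "b"], "inversely_up")
  # flipping both sign conventions swaps the labels
  flip <- function(x) {
    x$direction <- ifelse(x$direction == "up", "down", "up")
    x$log2fc <- -x$log2fc
    x
  }
  rev2 <- reverse_regulated(flip(dis), flip(trt))
  expect_equal(rev2$direction[rev2$gene == "a"], "inversely_up")
  expect_equal(rev2$direction[rev2$gene == "b"], "inversely_down")
})

test_that("planted restored genes are recovered as the reverse-regulated set", {
  cfg <- simulation_config(n_genes = 1000, n_perturbed = 80,
                           effect_log2fc = 2, restored_fraction = 0.5,
                           replicates_per_condition = 10,
                           block_sizes = integer(0), seed = 21)
  sim <- simulate_counts(cfg)
  degs_d <- call_degs(test_differential(sim$counts, c("disease", "control")))
  degs_t <- call_degs(test_differential(sim$counts, c("treated", "disease")))
  rev <- reverse_regulated(degs_d, degs_t)
  restored <- sim$truth$restored_genes
  sensitivity <- mean(restored %in% rev$gene)
  expect_gte(sensitivity, 0.9)
  # estimated fold changes concentrate near the planted effect
  de <- test_differential(sim$counts, c("disease", "control"))
  pg <- sim$truth$perturbed_genes
  est <- de$log2fc[match(pg$gene, de$gene)]
  est <- ifelse(pg$direction == "up", est, -est)
  expect_gte(mean(abs(est - 2) <= 0.3), 0.9)
})
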