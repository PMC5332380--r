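# Synthetic three-condition RNA count data with planted structure.
#
# The generator emulates a tag-based cardiac transcriptome profile:
# negative-binomial counts (gamma-Poisson), log-normal baseline means,
# three conditions (control, disease, treated) with a planted set of
# disease-perturbed genes, a subset of which is restored to baseline by
# treatment, latent-factor co-expression blocks, and uneven library sizes.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study design the pipeline targets: a profile of
#' 10,515 mRNAs over 3 conditions x 3 replicates (9 animals), several
#' hundred disease-perturbed genes of which a majority is reversed by
#' treatment, and a pathway collection of 15 gene sets containing one
#' planted group concentrated at the top of the centrality ranking.
#'
#' @param n_genes Number of genes.
#' @param replicates_per_condition Replicates in each of the three conditions.
#' @param baseline_mean_log Mean of the log-normal baseline expression
#'   (natural-log scale).
#' @param baseline_sd_log Standard deviation of the log-normal baseline.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param n_perturbed Number of genes shifted in the disease condition.
#' @param effect_log2fc Disease shift in log2 units; perturbed genes have
#'   their mean multiplied by `2^effect_log2fc` (sign drawn per gene).
#' @param restored_fraction Fraction of perturbed genes whose treated-condition
#'   mean returns to baseline, in `[0, 1]`.
#' @param block_sizes Integer vector of co-expression block sizes.
#' @param block_correlation Target pairwise correlation within a block, in
#'   `[0, 1]`, induced by a shared latent factor on the log-mean scale.
#' @param block_factor_sd Log-scale standard deviation of the block latent
#'   factor; sets how strongly block genes fluctuate together relative to
#'   the count noise.
#' @param biological_sd_log Per-sample biological noise on the log-mean scale
#'   for genes outside blocks.
#' @param n_pathways Number of pathway gene sets to simulate.
#' @param pathway_size_range Length-2 integer vector, min and max pathway size.
#' @param planted_group_size Size of the planted top-ranked group (0 disables).
#' @param library_size_spread Library-size factors are drawn uniformly in
#'   `[1 - spread, 1 + spread]`; default 0.2 so TPM normalization is
#'   non-trivial.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @seealso [simulate_counts()], [simulate_pathways()]
#' @export
simulation_config <- function(n_genes = 10515,
                              replicates_per_condition = 3,
                              baseline_mean_log = log(200),
                              baseline_sd_log = 1,
                              dispersion = 0.02,
                              n_perturbed = 800,
                              effect_log2fc = 2,
                              restored_fraction = 0.6,
                              block_sizes = rep(50L, 8),
                              block_correlation = 0.8,
                              block_factor_sd = 0.5,
                              biological_sd_log = 0.05,
                              n_pathways = 15,
                              pathway_size_range = c(10, 40),
                              planted_group_size = 10,
                              library_size_spread = 0.2,
                              seed = 1) {
  check_number(n_genes, "n_genes", lower = 1, integerish = TRUE)
  check_number(replicates_per_condition, "replicates_per_condition",
               lower = 1, integerish = TRUE)
  check_number(baseline_mean_log, "baseline_mean_log")
  check_number(baseline_sd_log, "baseline_sd_log", lower = 0)
  check_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_number(n_perturbed, "n_perturbed", lower = 0, upper = n_genes,
               integerish = TRUE)
  check_number(effect_log2fc, "effect_log2fc")
  check_number(restored_fraction, "restored_fraction", lower = 0, upper = 1)
  if (length(block_sizes) > 0) {
    for (b in block_sizes) check_number(b, "block_sizes", lower = 1, integerish = TRUE)
    if (sum(block_sizes) > n_genes) {
      stop("configuration error: sum(block_sizes) exceeds n_genes", call. = FALSE)
    }
  }
  check_number(block_correlation, "block_correlation", lower = 0, upper = 1)
  check_number(block_factor_sd, "block_factor_sd", lower = 0)
  check_number(biological_sd_log, "biological_sd_log", lower = 0)
  check_number(n_pathways, "n_pathways", lower = 1, integerish = TRUE)
  if (length(pathway_size_range) != 2L) {
    stop("configuration error: `pathway_size_range` must have length 2", call. = FALSE)
  }
  check_number(pathway_size_range[1], "pathway_size_range[1]", lower = 2,
               integerish = TRUE)
  check_number(pathway_size_range[2], "pathway_size_range[2]",
               lower = pathway_size_range[1], integerish = TRUE)
  check_number(planted_group_size, "planted_group_size", lower = 0,
               integerish = TRUE)
  check_number(library_size_spread, "library_size_spread", lower = 0,
               upper = 0.99)
  check_number(seed, "seed", integerish = TRUE)

  structure(list(
    n_genes = as.integer(n_genes),
    replicates_per_condition = as.integer(replicates_per_condition),
    baseline_mean_log = baseline_mean_log,
    baseline_sd_log = baseline_sd_log,
    dispersion = dispersion,
    n_perturbed = as.integer(n_perturbed),
    effect_log2fc = effect_log2fc,
    restored_fraction = restored_fraction,
    block_sizes = as.integer(block_sizes),
    block_correlation = block_correlation,
    block_factor_sd = block_factor_sd,
    biological_sd_log = biological_sd_log,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    planted_group_size = as.integer(planted_group_size),
    library_size_spread = library_size_spread,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a three-condition count matrix with ground truth
#'
#' Draws negative-binomial counts for conditions control, disease and
#' treated. Perturbed genes have their disease-condition mean multiplied
#' by `2^effect_log2fc`; restored genes return to the baseline mean under
#' treatment while the remaining perturbed genes keep the disease shift.
#' Genes assigned to a block share a latent log-scale factor so their
#' expression is correlated across samples.
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (perturbed genes with directions, restored genes, block membership).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    reps <- config$replicates_per_condition
    conds <- c("control", "disease", "treated")
    genes <- sprintf("g%05d", seq_len(n))
    samples <- paste(rep(conds, each = reps), seq_len(reps), sep = "_")
    condition <- rep(conds, each = reps)

    base_log <- rnorm(n, config$baseline_mean_log, config$baseline_sd_log)

    perturbed <- sort(sample(genes, config$n_perturbed))
    direction <- sample(c(1, -1), config$n_perturbed, replace = TRUE)
    names(direction) <- perturbed
    n_restored <- round(config$restored_fraction * config$n_perturbed)
    restored <- sort(sample(perturbed, n_restored))

    # log2 offsets per gene x condition
    shift <- rep(0, n)
    names(shift) <- genes
    shift[perturbed] <- direction * config$effect_log2fc
    offset_disease <- shift
    offset_treated <- shift
    offset_treated[restored] <- 0

    block <- rep(NA_integer_, n)
    names(block) <- genes
    if (length(config$block_sizes) > 0 && sum(config$block_sizes) > 0) {
      in_blocks <- sample(genes, sum(config$block_sizes))
      block[in_blocks] <- rep(seq_along(config$block_sizes),
                              times = config$block_sizes)
    }

    n_samp <- length(samples)
    rho <- config$block_correlation
    noise <- config$biological_sd_log * matrix(rnorm(n * n_samp), n, n_samp)
    if (any(!is.na(block))) {
      # block genes get a dedicated latent factor in place of independent
      # biological noise so their shared fluctuation survives count noise
      z <- matrix(rnorm(length(config$block_sizes) * n_samp),
                  length(config$block_sizes), n_samp)
      idx <- which(!is.na(block))
      e <- matrix(rnorm(length(idx) * n_samp), length(idx), n_samp)
      noise[idx, ] <- config$block_factor_sd *
        (sqrt(rho) * z[block[idx], , drop = FALSE] + sqrt(1 - rho) * e)
    }

    log_mu <- base_log + noise
    cond_offset <- cbind(matrix(0, n, reps),
                         matrix(offset_disease * log(2), n, reps),
                         matrix(offset_treated * log(2), n, reps))
    log_mu <- log_mu + cond_offset

    lib <- runif(n_samp, 1 - config$library_size_spread,
                 1 + config$library_size_spread)
    mu <- exp(log_mu) %*% diag(lib)

    counts <- matrix(rnbinom(n * n_samp, mu = mu, size = 1 / config$dispersion),
                     n, n_samp, dimnames = list(genes, samples))

    truth <- list(
      perturbed_genes = data.frame(gene = perturbed,
                                   direction = ifelse(direction > 0, "up", "down"),
                                   stringsAsFactors = FALSE),
      restored_genes = restored,
      block_membership = block
    )
    list(counts = count_matrix(counts, stats::setNames(condition, samples)),
         truth = truth)
  })
}

#' Simulate pathway gene sets and pathway graphs
#'
#' Generates `n_pathways` gene sets with sizes drawn from
#' `pathway_size_range` and, for each, a connected undirected graph on its
#' members (random spanning tree plus extra edges). One pathway is the
#' planted group: its members are the top `planted_group_size` genes of
#' `ranking_hint`, so downstream it should concentrate at the top of the
#' keystone priority list. The other pathways mix genes from
#' `ranking_hint` and the remaining universe so that pathway membership
#' overlaps the responsive gene set.
#'
#' @param config A [simulation_config()] object.
#' @param ranking_hint Ordered character vector of genes, most important
#'   first (e.g. the planted restored genes).
#' @param universe Character vector of all gene identifiers pathways may
#'   draw from; defaults to `ranking_hint`.
#' @param hint_fraction Fraction of each non-planted pathway drawn from
#'   `ranking_hint` (default 0.5).
#' @return A list with `pathway_sets` (named list of character vectors),
#'   `pathway_graphs` (named list of two-column data frames) and
#'   `planted_group` (character vector, empty when disabled).
#' @export
simulate_pathways <- function(config, ranking_hint, universe = ranking_hint,
                              hint_fraction = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (length(ranking_hint) == 0) {
    stop("`ranking_hint` must be nonempty", call. = FALSE)
  }
  if (config$planted_group_size > length(ranking_hint)) {
    stop("configuration error: planted_group_size exceeds length of ranking_hint",
         call. = FALSE)
  }
  if (!all(ranking_hint %in% universe)) universe <- union(universe, ranking_hint)

  with_seed(config$seed + 1L, {
    sizes <- sample(seq(config$pathway_size_range[1],
                        config$pathway_size_range[2]),
                    config$n_pathways, replace = TRUE)
    ids <- sprintf("pw%02d", seq_len(config$n_pathways))
    sets <- vector("list", config$n_pathways)
    names(sets) <- ids

    planted <- character(0)
    if (config$planted_group_size > 0) {
      planted <- head(ranking_hint, config$planted_group_size)
      sets[[1]] <- planted
      sizes[1] <- length(planted)
    }
    start <- if (length(planted) > 0) 2L else 1L
    for (i in seq(start, config$n_pathways)) {
      n_hint <- min(round(hint_fraction * sizes[i]), length(ranking_hint))
      from_hint <- sample(ranking_hint, n_hint)
      pool <- setdiff(universe, from_hint)
      sets[[i]] <- sort(c(from_hint, sample(pool, sizes[i] - n_hint)))
    }

    graphs <- lapply(sets, random_connected_edges)
    list(pathway_sets = sets, pathway_graphs = graphs, planted_group = planted)
  })
}

#' Ordered gene hint for pathway planting
#'
#' Ranks the ground-truth restored genes by total expression (descending),
#' followed by the remaining perturbed genes, likewise ordered. Highly
#' expressed restored genes are the ones most reliably recovered as
#' reverse-regulated hub genes downstream, so the head of this list is
#' where a planted group should concentrate.
#'
#' @param counts A [count_matrix()] from [simulate_counts()].
#' @param truth Matching ground-truth list.
#' @return Character vector of genes, most promising first.
#' @export
simulation_hint <- function(counts, truth) {
  expr_order <- function(g) g[order(-rowSums(counts$values[g, , drop = FALSE]), g)]
  c(expr_order(truth$restored_genes),
    expr_order(setdiff(truth$perturbed_genes$gene, truth$restored_genes)))
}

# Random spanning tree over `genes` plus ~2|genes| extra edges, simple.
random_connected_edges <- function(genes) {
  k <- length(genes)
  if (k < 2) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  ord <- sample(genes)
  a <- ord[vapply(seq(2, k), function(i) sample.int(i - 1, 1), 1L)]
  b <- ord[seq(2, k)]
  extra <- 2L * k
  if (extra > 0) {
    ea <- sample(genes, extra, replace = TRUE)
    eb <- sample(genes, extra, replace = TRUE)
    keep <- ea != eb
    a <- c(a, ea[keep])
    b <- c(b, eb[keep])
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi))
  data.frame(gene_a = lo[keep], gene_b = hi[keep], stringsAsFactors = FALSE)
}
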