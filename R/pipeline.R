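# End-to-end orchestration: synthetic or file-based inputs through
# differential expression, co-expression network, keystone selection,
# functional grouping and group significance, with a reproducibility
# manifest.

#' Pipeline configuration
#'
#' All stage parameters with their defaults. Input paths may be `NULL`,
#' in which case the synthetic generator supplies counts, condition map,
#' pathway sets and pathway graphs.
#'
#' @param counts_path,conditions_path Count matrix and condition-map TSVs
#'   (`NULL` = simulate).
#' @param gmt_path,pathway_edges_path Pathway gene sets (GMT) and pathway
#'   graphs (edge-list TSV); `NULL` = simulate.
#' @param de_disease_path,de_treatment_path Optional precomputed
#'   differential tables for the disease-vs-control and
#'   treated-vs-disease contrasts.
#' @param sim A [simulation_config()] used when inputs are simulated.
#' @param deg_fdr_max,deg_abs_log2fc_min DEG thresholds (0.10, 0.58).
#' @param edge_fdr_max Co-expression edge FDR threshold (0.05).
#' @param damping PageRank damping factor (0.85).
#' @param attack_theta Collapse threshold for keystone selection (0.10).
#' @param attack_rule `"collapse_threshold"` or `"elbow"`.
#' @param ora_p_max Pathway enrichment threshold (0.05).
#' @param permutations Monte Carlo simulations B (10,000).
#' @param alpha_adjusted Adjusted-p significance threshold (0.005).
#' @param seed Integer master seed.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, conditions_path = NULL,
                            gmt_path = NULL, pathway_edges_path = NULL,
                            de_disease_path = NULL, de_treatment_path = NULL,
                            sim = simulation_config(),
                            deg_fdr_max = 0.10, deg_abs_log2fc_min = 0.58,
                            edge_fdr_max = 0.05,
                            damping = 0.85,
                            attack_theta = 0.10,
                            attack_rule = "collapse_threshold",
                            ora_p_max = 0.05,
                            permutations = 10000,
                            alpha_adjusted = 0.005,
                            seed = 1,
                            out_dir = NULL) {
  for (p in c(counts_path, conditions_path, gmt_path, pathway_edges_path,
              de_disease_path, de_treatment_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("input file does not exist: %s", p), call. = FALSE)
    }
  }
  check_number(deg_fdr_max, "deg_fdr_max", lower = 0, upper = 1)
  check_number(deg_abs_log2fc_min, "deg_abs_log2fc_min", lower = 0)
  check_number(edge_fdr_max, "edge_fdr_max", lower = 0, upper = 1)
  check_number(damping, "damping", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(attack_theta, "attack_theta", lower = 0, upper = 1)
  check_number(ora_p_max, "ora_p_max", lower = 0, upper = 1)
  check_number(permutations, "permutations", lower = 1, integerish = TRUE)
  check_number(alpha_adjusted, "alpha_adjusted", lower = 0, upper = 1)
  check_number(seed, "seed", integerish = TRUE)
  cfg <- list(counts_path = counts_path, conditions_path = conditions_path,
              gmt_path = gmt_path, pathway_edges_path = pathway_edges_path,
              de_disease_path = de_disease_path,
              de_treatment_path = de_treatment_path,
              sim = sim,
              deg_fdr_max = deg_fdr_max,
              deg_abs_log2fc_min = deg_abs_log2fc_min,
              edge_fdr_max = edge_fdr_max, damping = damping,
              attack_theta = attack_theta, attack_rule = attack_rule,
              ora_p_max = ora_p_max, permutations = as.integer(permutations),
              alpha_adjusted = alpha_adjusted, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; keys under `sim:`
#' are passed to [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  args <- y
  args$sim <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, args)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (simulated or from files),
#' differential expression for the disease-vs-control and
#' treated-vs-disease contrasts, DEG calling, the reverse-regulated gene
#' set, the co-expression network, PageRank ranking, targeted attack and
#' keystone selection, pathway over-representation, background-network
#' merge, responsive sub-network extraction, leading-eigenvector
#' functional grouping, and keystone-gene-based group significance. When
#' `out_dir` is set, every stage artifact is written (TSV/GMT/GraphML)
#' together with a JSON manifest of all parameters, seeds and stage
#' cardinalities; two runs with the same configuration produce identical
#' tables.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `de_disease`,
#'   `de_treatment`, `degs_disease`, `degs_treatment`, `reverse_set`,
#'   `gcn`, `ranking`, `attack`, `keystones`, `ora`, `background`,
#'   `subnetwork`, `groups`, `priority_list`, `significance`, `truth`
#'   (when simulated) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package = "kgsa",
                   version = as.character(utils::packageVersion("kgsa")),
                   parameters = config[!(names(config) %in%
                                           c("sim", "out_dir"))],
                   sim = if (is.null(config$counts_path)) unclass(config$sim),
                   counts = NULL)

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (is.null(config$counts_path)) {
    sim <- simulate_counts(config$sim)
    counts <- sim$counts
    truth <- sim$truth
    stage_msg("syndata", "simulated %d genes x %d samples",
              nrow(counts$values), ncol(counts$values))
  } else {
    counts <- read_counts(config$counts_path, config$conditions_path)
    stage_msg("input", "read %d genes x %d samples",
              nrow(counts$values), ncol(counts$values))
  }
  genes_all <- rownames(counts$values)

  # --- differential expression -------------------------------------------
  de_d <- if (is.null(config$de_disease_path)) {
    test_differential(counts, c("disease", "control"))
  } else {
    read_differential_table(config$de_disease_path, c("disease", "control"))
  }
  de_t <- if (is.null(config$de_treatment_path)) {
    test_differential(counts, c("treated", "disease"))
  } else {
    read_differential_table(config$de_treatment_path, c("treated", "disease"))
  }
  degs_d <- call_degs(de_d, config$deg_fdr_max, config$deg_abs_log2fc_min)
  degs_t <- call_degs(de_t, config$deg_fdr_max, config$deg_abs_log2fc_min)
  rev_set <- reverse_regulated(degs_d, degs_t)
  stage_msg("diffexpr",
            "%d disease DEGs, %d treatment-responsive DEGs, %d reverse-regulated",
            nrow(degs_d), nrow(degs_t), nrow(rev_set))
  if (nrow(rev_set) < 3) {
    stop("pipeline error [diffexpr]: fewer than 3 reverse-regulated genes",
         call. = FALSE)
  }

  # --- pathways -----------------------------------------------------------
  if (is.null(config$gmt_path)) {
    hint <- simulation_hint(counts, truth)
    pw <- simulate_pathways(config$sim, hint, universe = genes_all)
    truth$planted_group <- pw$planted_group
    truth$pathway_sets <- pw$pathway_sets
    collection <- pathway_collection(pw$pathway_sets, pw$pathway_graphs,
                                     universe = genes_all)
  } else {
    sets <- read_gmt(config$gmt_path)
    graphs <- if (!is.null(config$pathway_edges_path)) {
      read_pathway_edges(config$pathway_edges_path)
    }
    collection <- pathway_collection(sets, graphs, universe = genes_all)
  }

  # --- co-expression network and keystones --------------------------------
  tpm <- normalize_tpm(counts)
  gcn <- coexpression_network(tpm, rev_set$gene, fdr_max = config$edge_fdr_max)
  stage_msg("gcn", "%d nodes, %d edges (FDR < %g)",
            igraph::vcount(gcn), igraph::ecount(gcn), config$edge_fdr_max)
  ranking <- pagerank_ranking(gcn, damping = config$damping)
  attack <- attack_curve(gcn, ranking$gene, mode = "targeted")
  keystones <- select_keystones(ranking, attack, theta = config$attack_theta,
                                rule = config$attack_rule)
  stage_msg("keystone", "%d keystone genes (rule = %s)",
            keystones$k, keystones$rule)

  # --- functional groups ---------------------------------------------------
  enr <- ora(degs_t$gene, collection, p_max = config$ora_p_max)
  stage_msg("groups", "%d of %d pathways enriched (P < %g)",
            sum(enr$enriched), nrow(enr), config$ora_p_max)
  if (sum(enr$enriched) == 0) {
    stop("pipeline error [groups]: no enriched pathways", call. = FALSE)
  }
  background <- merge_pathways(enr, collection)
  subnet <- extract_subnetwork(background, degs_t$gene)
  groups <- detect_groups(subnet)
  stage_msg("groups",
            "background %d nodes / %d edges; sub-network %d nodes; %d groups (Q = %.3f)",
            igraph::vcount(background), igraph::ecount(background),
            igraph::vcount(subnet), length(groups$groups), groups$modularity)

  # --- significance --------------------------------------------------------
  scaled <- scale_scores(ranking)
  L <- build_priority_list(keystones, subnet, scaled)
  res <- group_significance(groups, L, background, B = config$permutations,
                            seed = config$seed,
                            adjusted_max = config$alpha_adjusted)
  stage_msg("significance", "%d of %d groups significant (adjusted P < %g)",
            sum(res$significant), nrow(res), config$alpha_adjusted)

  manifest$counts <- list(
    genes = length(genes_all), samples = ncol(counts$values),
    degs_disease = nrow(degs_d), degs_treatment = nrow(degs_t),
    reverse_regulated = nrow(rev_set),
    gcn_nodes = igraph::vcount(gcn), gcn_edges = igraph::ecount(gcn),
    keystones = keystones$k, enriched_pathways = sum(enr$enriched),
    subnetwork_nodes = igraph::vcount(subnet),
    functional_groups = length(groups$groups),
    priority_list = nrow(L),
    significant_groups = sum(res$significant)
  )

  out <- structure(list(
    counts = counts, de_disease = de_d, de_treatment = de_t,
    degs_disease = degs_d, degs_treatment = degs_t, reverse_set = rev_set,
    gcn = gcn, ranking = ranking, attack = attack, keystones = keystones,
    ora = enr, background = background, subnetwork = subnet, groups = groups,
    priority_list = L, significance = res, truth = truth,
    manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_result(out, config)
  out
}

# Writes every stage artifact plus the manifest into config$out_dir.
write_pipeline_result <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_counts(result$counts, p("counts.tsv"), p("conditions.tsv"))
  write_differential_table(result$de_disease, p("de_disease_vs_control.tsv"))
  write_differential_table(result$de_treatment, p("de_treated_vs_disease.tsv"))
  write.table(result$reverse_set, p("reverse_regulated.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_graphml(result$gcn, p("gcn.graphml"))
  write_edge_tsv(result$gcn, p("gcn_edges.tsv"))
  write.table(result$ranking, p("pagerank.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$attack, p("attack_curve.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(result$keystones$genes, p("keystone_genes.txt"))
  write.table(result$ora, p("pathway_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_graphml(result$background, p("background.graphml"))
  write_graphml(result$subnetwork, p("subnetwork.graphml"))
  write.table(result$groups$membership, p("functional_groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(result$priority_list), p("priority_list.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- result$significance
  sig$nominal_p_display <- format_nominal_p(sig$nominal_p, attr(sig, "B"))
  write.table(sig, p("group_significance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(result$truth)) {
    jsonlite::write_json(
      list(perturbed_genes = result$truth$perturbed_genes,
           restored_genes = result$truth$restored_genes,
           planted_group = result$truth$planted_group),
      p("ground_truth.json"), auto_unbox = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(config$out_dir)
}

#' Percent change between two group means
#'
#' `(comparison - reference) / reference * 100`; the sign gives the
#' direction (negative = decrease relative to the reference). Decrease
#' magnitudes quoted in text are `abs()` of this value with the earlier
#' condition as reference (e.g. treated vs disease uses the disease-model
#' mean as reference).
#'
#' @param reference_mean Reference group mean (nonzero).
#' @param comparison_mean Comparison group mean.
#' @return Signed percent change.
#' @export
percent_change <- function(reference_mean, comparison_mean) {
  if (any(!is.finite(reference_mean)) || any(reference_mean == 0)) {
    stop("reference mean must be finite and nonzero", call. = FALSE)
  }
  (comparison_mean - reference_mean) / reference_mean * 100
}
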