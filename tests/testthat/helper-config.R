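# A reduced study design used by the pipeline-level tests: same structure
# as the default (three conditions x three replicates, planted reversal,
# blocks, one planted pathway group) at a fraction of the gene count.
small_sim_config <- function(seed = 1) {
  simulation_config(n_genes = 800, n_perturbed = 150, restored_fraction = 0.6,
                    block_sizes = c(25, 25), n_pathways = 8,
                    pathway_size_range = c(6, 15), planted_group_size = 6,
                    seed = seed)
}

small_pipeline_config <- function(seed = 1, ...) {
  pipeline_config(sim = small_sim_config(seed), permutations = 500,
                  seed = seed, ...)
}
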