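# kgsa — keystone-gene group significance analysis

`kgsa` analyses how a treatment reshapes a disease transcriptome at the
network level. It targets the common three-arm design of pharmacology
studies — control (sham), disease model, and treated animals profiled by
RNA counting — and answers the question: *which functional gene groups
does the treatment act on, and how strongly?*

The pipeline:

1. **Differential expression.** Counts are TPM-normalized; genes are
   tested per contrast (disease vs control, treated vs disease) and
   called differentially expressed at `FDR < 0.10` and
   `|log2FC| > 0.58`. The DE step is pluggable: precomputed tables
   (e.g. from DESeq2) are ingested verbatim, and a built-in
   Welch-on-log-TPM test keeps the pipeline self-contained.
2. **Reverse-regulated genes.** Genes differentially expressed in *both*
   contrasts with *opposite* signs — the treatment pushes them back
   toward the control state.
3. **Co-expression network (GCN).** Pairwise Pearson correlation over
   all samples, Student asymptotic p-values, Benjamini–Hochberg
   adjustment over all pairs; edges kept at `q < 0.05`.
4. **Keystone genes.** PageRank centrality (damping 0.85, `|r|` edge
   weights) ranks the genes; a targeted attack curve (largest connected
   component fraction vs number of top-ranked genes removed) determines
   how many top genes are "keystone" hubs — by default the smallest
   removal that drives the LCC fraction below θ = 0.10.
5. **Functional groups.** Pathways enriched in the responsive genes
   (hypergeometric `P < 0.05`) are merged into a background network; the
   responsive sub-network is partitioned by Newman's leading-eigenvector
   modularity method with Kernighan–Lin fine-tuning.
6. **Group significance.** The package's core statistic. Keystone genes
   in the sub-network form a priority list *L* ordered by min–max scaled
   PageRank score *s*. Walking down *L*, a group *C* accumulates

   - hits: `P_hit(C, i) = Σ_{g_j ∈ C, j ≤ i} s_j`
   - misses: `P_miss(C, i) = Σ_{g_j ∉ C, j ≤ i} N_diff / (N_genelist · N_group)`

   with `N_diff = |C \ L|`, `N_genelist = |L|`, `N_group = |C|`, and
   `ES(C) = max_i [P_hit − P_miss]`. Significance is estimated from a
   Monte Carlo null — 10,000 random same-size gene groups drawn from the
   background network, `P(C) = #(ES_NULL ≥ ES)/10,000` — adjusted across
   groups by the Simes–Hochberg step-up procedure, with significance
   called at adjusted `P < 0.005`.

A seeded synthetic-data generator (negative-binomial counts, planted
disease perturbation partially reversed by treatment, latent
co-expression blocks, pathway collections with one planted top-ranked
group) makes every stage testable without external data.

## Worked example

```r
library(kgsa)

res <- run_pipeline(pipeline_config(seed = 1))
#> [syndata] simulated 10515 genes x 9 samples
#> [diffexpr] 632 disease DEGs, 295 treatment-responsive DEGs, 258 reverse-regulated
#> [gcn] 258 nodes, 33153 edges (FDR < 0.05)
#> [keystone] 258 keystone genes (rule = collapse_threshold)
#> [groups] 11 of 15 pathways enriched (P < 0.05)
#> [groups] background 246 nodes / 673 edges; sub-network 55 nodes; 30 groups (Q = 0.695)
#> [significance] 1 of 30 groups significant (adjusted P < 0.005)

head(res$significance, 3)
#>   group_id       es n_group n_diff nominal_p adjusted_p significant
#> 1 group_13 4.157643       5      0    0.0001     0.0030        TRUE
#> 2 group_07 2.697210       4      1    0.0017     0.0493       FALSE
#> 3 group_08 2.438454       4      0    0.0051     0.1173       FALSE
```

Reading the output: of 10,515 simulated genes, 258 are reverse-regulated
by the treatment; all of them are co-expression hubs in this strongly
condition-driven design. The sub-network of enriched-pathway genes
partitions into 30 groups, and the group most concentrated at the top of
the keystone priority list (ES 4.16, none of its 5 members missing from
the list, 4 of them planted by the generator) survives the Hochberg
adjustment at adjusted P < 0.005.

Percent changes for reported group means use the earlier condition as
reference:

```r
lipids <- read.delim(system.file("extdata", "plasma_lipids.tsv", package = "kgsa"),
                     row.names = 1)
percent_change(lipids["sham", "TG"], lipids["model", "TG"])
#> [1] 306.25
percent_change(lipids["model", "TG"], lipids["treated", "TG"])
#> [1] -46.15385
```

A shell entry point with per-stage subcommands is installed at
`system.file("scripts", "kgsa.R", package = "kgsa")`:

```sh
Rscript kgsa.R run-all --config config.yaml --out-dir results/
Rscript kgsa.R report --results-dir results/
```

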