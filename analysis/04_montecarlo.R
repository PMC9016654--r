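#!/usr/bin/env Rscript
# Stage 4 — Monte-Carlo label-permutation validation at the full design.
#
# The case labels are permuted over the pooled 4,745 samples (cohort
# sizes preserved); each pathway's case carrier count is compared with
# its permutation null, all pathways sharing one permutation stream.
# Empirical p uses the +1 correction.

suppressMessages(library(pathburden))
ANALYSIS_SEED <- 20260930L
dir.create("results", showWarnings = FALSE)
spiked <- sprintf("PW%04d", 1:5)

sim <- simulate_cohorts(simulation_config(
  seed = ANALYSIS_SEED, cohorts = default_cohorts(),
  n_genes = 4000, n_pathways = 200, genes_per_pathway = 20,
  spikes = stats::setNames(rep(8, 5), spiked)))
mc <- mc_pathway_test(sim$pathway_matrix, sim$manifest,
                      n_perm = 10000, seed = ANALYSIS_SEED)

mc_ranked <- mc[order(mc$p_empirical, mc$pathway_id), ]
write.table(mc_ranked, "results/04_mc_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Monte-Carlo validation, 10,000 permutations, 39 pseudo-cases drawn",
    "from 4,745 pooled samples.\nTop 10 pathways by empirical p:\n")
print(head(mc_ranked, 10), row.names = FALSE)
cat("\nSpiked pathways among MC top 10:",
    sum(spiked %in% head(mc_ranked$pathway_id, 10)), "of 5\n")
cat("Table: results/04_mc_results.tsv\n")
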