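#!/usr/bin/env Rscript
# Stage 3 — per-cohort Fisher burden enrichment at the full design.
#
# Regenerates the full-design simulation deterministically (same seed as
# stage 1), collapses carriers to pathway level and tests case
# enrichment against each of the 9 comparison cohorts with the one-sided
# exact test; BH FDR within each comparison's 200-pathway family.

suppressMessages(library(pathburden))
ANALYSIS_SEED <- 20260930L
dir.create("results", showWarnings = FALSE)
spiked <- sprintf("PW%04d", 1:5)

sim <- simulate_cohorts(simulation_config(
  seed = ANALYSIS_SEED, cohorts = default_cohorts(),
  n_genes = 4000, n_pathways = 200, genes_per_pathway = 20,
  spikes = stats::setNames(rep(8, 5), spiked)))
fe <- fisher_enrichment(sim$pathway_matrix, sim$manifest)

sig <- aggregate(q_fdr ~ comparison, fe, function(q) sum(q <= 0.05))
names(sig)[2] <- "pathways_q_le_0.05"
sig$cohort_size <- sim$manifest$sizes[sig$comparison]
write.table(sig, "results/03_significant_by_cohort.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- do.call(rbind, lapply(split(fe, fe$comparison), head, 5))
write.table(top, "results/03_fisher_top5_per_cohort.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Pathways at q <= 0.05 per comparison cohort:\n")
print(sig, row.names = FALSE)
spiked_rank <- sapply(split(fe, fe$comparison), function(df)
  mean(match(spiked, df$pathway_id)))
cat("\nMean rank of the 5 spiked pathways within each cohort's ordering:\n")
print(round(spiked_rank, 1))
cat("\nNote how the 24-sample cohort lacks the power to push any pathway",
    "past family-wide FDR,\nwhile the ~585-sample cohorts rank the spiked",
    "pathways at the top.\n")
cat("Tables: results/03_significant_by_cohort.tsv,",
    "results/03_fisher_top5_per_cohort.tsv\n")
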