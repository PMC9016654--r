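#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study.
#
# Two datasets are generated, both pure functions of ANALYSIS_SEED:
#
#  * the full-design cohort at matrix level: 39 cases vs a 24-sample
#    comparison cohort and 8 reference cohorts totalling 4,682 samples,
#    4,000 genes in 200 disjoint 20-gene pathways, 5 pathways spiked at
#    case relative risk 8 (used by stages 3-5);
#  * a scaled cohort (39 cases, 24 + 8 x 30 comparisons, 400 genes, 40
#    pathways) emitted as annotated VCF + GMT + manifest + truth table
#    under scratch/analysis/data/, exercising the file-based path
#    (used by stage 2).
#
# Emitting VCF text for the full design (~10^5 variant rows x 4,745
# genotype columns) would serve no analytical purpose; the matrix level
# carries the identical statistical structure.

suppressMessages(library(pathburden))
ANALYSIS_SEED <- 20260930L
dir.create("results", showWarnings = FALSE)
data_dir <- "scratch/analysis/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

spiked <- sprintf("PW%04d", 1:5)
full <- simulate_cohorts(simulation_config(
  seed = ANALYSIS_SEED, cohorts = default_cohorts(),
  n_genes = 4000, n_pathways = 200, genes_per_pathway = 20,
  spikes = stats::setNames(rep(8, 5), spiked)))

scaled_design <- data.frame(
  cohort_id = c("CASE", "PEDCOV", paste0("REF", 1:8)),
  n_samples = c(39L, 24L, rep(30L, 8)),
  is_case = c(TRUE, rep(FALSE, 9)))
scaled <- simulate_cohorts(simulation_config(
  seed = ANALYSIS_SEED + 1L, cohorts = scaled_design,
  n_genes = 400, n_pathways = 40, genes_per_pathway = 10,
  spikes = stats::setNames(rep(8, 3), sprintf("PW%04d", 1:3)),
  emit = c("vcf", "gmt", "manifest")), dir = data_dir)

summary <- data.frame(
  dataset = c("full", "scaled"),
  samples = c(sum(full$manifest$sizes), sum(scaled$manifest$sizes)),
  cohorts = c(length(full$manifest$cohorts),
              length(scaled$manifest$cohorts)),
  genes = c(4000L, 400L),
  pathways = c(200L, 40L),
  spiked = c(paste(full$truth$spiked, collapse = ","),
             paste(scaled$truth$spiked, collapse = ",")),
  qualifying_variants = c(sum(full$carrier_gene),
                          sum(scaled$truth$variants$qualifying)),
  decoy_variants = c(NA_integer_, sum(!scaled$truth$variants$qualifying)))
write.table(summary, "results/01_simulation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Full design:", sum(full$manifest$sizes), "samples,",
    sum(full$carrier_gene), "carrier-gene events;",
    "case pathway-carrier counts for spiked pathways:\n")
print(full$truth$pathway_counts_by_cohort["CASE", spiked])
cat("Scaled fixture written under", data_dir, "with",
    nrow(scaled$truth$variants), "variant records (",
    sum(scaled$truth$variants$qualifying), "qualifying ).\n")
cat("Summary table: results/01_simulation_summary.tsv\n")
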