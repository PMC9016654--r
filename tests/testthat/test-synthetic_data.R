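small_design <- function() {
  data.frame(cohort_id = c("CASE", "C1", "C2"),
             n_samples = c(8L, 12L, 12L),
             is_case = c(TRUE, FALSE, FALSE))
}

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(cohorts = data.frame(
    cohort_id = "A", n_samples = 5L, is_case = FALSE)), "case")
  expect_error(simulation_config(n_genes = 0), "> 0")
  expect_error(simulation_config(spikes = c(PW9999 = 2), n_pathways = 10),
               "pathway ids")
  expect_error(simulation_config(spikes = c(PW0001 = 0.5)), ">= 1")
  expect_error(simulation_config(decoy_fraction = 1), "decoy_fraction")
  expect_error(simulation_config(emit = "parquet"), "unknown emit")
})

test_that("the same seed reproduces byte-identical fixture files", {
  cfg <- simulation_config(seed = 404, cohorts = small_design(),
                           n_genes = 60, n_pathways = 8,
                           genes_per_pathway = 5,
                           spikes = c(PW0002 = 4),
                           emit = c("vcf", "gmt", "manifest"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_cohorts(cfg, dir = d1)
  s2 <- simulate_cohorts(cfg, dir = d2)
  for (f in c("cohort.vcf", "pathways.gmt", "manifest.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_identical(s1$truth$gene_rates, s2$truth$gene_rates)
})

test_that("emitted qualifying and decoy variants honour the qualification rules by construction", {
  sim <- simulate_cohorts(simulation_config(
    seed = 8, cohorts = small_design(), n_genes = 80, n_pathways = 10,
    genes_per_pathway = 6, emit = c("vcf", "manifest")),
    dir = withr::local_tempdir())
  v <- sim$truth$variants
  expect_gt(sum(v$qualifying), 0)
  expect_gt(sum(!v$qualifying), 0)
  # the truth labels agree with an independent application of the rules
  keep <- oracle_qualify_keep(as.list(v$consequence), v$pop_ac)
  expect_equal(keep, v$qualifying)
  # boundary values are pinned: one qualifying at AC=10, one decoy at AC=11
  expect_true(any(v$pop_ac == 10L & v$qualifying))
  expect_true(any(v$pop_ac == 11L & !v$qualifying))
  # every carrier-gene event of the matrix is materialized
  ev <- which(sim$carrier_gene, arr.ind = TRUE)
  truth_pairs <- paste(v$carrier[v$qualifying], v$gene[v$qualifying])
  mat_pairs <- paste(rownames(sim$carrier_gene)[ev[, 1]],
                     colnames(sim$carrier_gene)[ev[, 2]])
  expect_setequal(truth_pairs, mat_pairs)
})

test_that("round trip: read_vcf + qualify_variants recovers exactly the truth records", {
  sim <- simulate_cohorts(simulation_config(
    seed = 15, cohorts = small_design(), n_genes = 100, n_pathways = 10,
    genes_per_pathway = 6, emit = c("vcf", "gmt", "manifest")),
    dir = withr::local_tempdir())
  v <- read_vcf(sim$paths$vcf)
  expect_equal(nrow(v), nrow(sim$truth$variants))
  expect_equal(attr(v, "n_parse_failures"), 0L)
  q <- qualify_variants(v)
  truth_q <- sim$truth$variants[sim$truth$variants$qualifying, ]
  got <- paste(q$pos, vapply(q$genes, `[`, "", 1),
               vapply(q$carriers, `[`, "", 1))
  want <- paste(truth_q$pos, truth_q$gene, truth_q$carrier)
  expect_setequal(got, want)                    # decoys: 100% rejected
  # and the rebuilt carrier matrix reproduces per-gene truth counts
  man <- read_manifest(sim$paths$manifest)
  cm <- build_carrier_matrix(q, man)
  for (g in colnames(cm))
    expect_equal(sum(cm[, g]), sum(sim$carrier_gene[, g]), label = g)
})

test_that("control carrier frequencies track the drawn gene rates", {
  co <- data.frame(cohort_id = c("CASE", "CTRL"),
                   n_samples = c(5L, 2000L), is_case = c(TRUE, FALSE))
  sim <- simulate_cohorts(simulation_config(
    seed = 99, cohorts = co, n_genes = 300, n_pathways = 5,
    genes_per_pathway = 10))
  ctrl <- sim$carrier_gene[comparison_samples(sim$manifest), ]
  freq <- colSums(ctrl) / nrow(ctrl)
  r <- sim$truth$gene_rates
  se <- sqrt(r * (1 - r) / nrow(ctrl))
  within <- abs(freq - r) <= 3 * se + 1e-9
  expect_gte(mean(within), 0.95)
})

test_that("spikes raise case rates only, cap at 1 and warn on saturation", {
  co <- data.frame(cohort_id = c("CASE", "CTRL"),
                   n_samples = c(50L, 50L), is_case = c(TRUE, FALSE))
  cfg <- simulation_config(seed = 2, cohorts = co, n_genes = 30,
                           n_pathways = 3, genes_per_pathway = 10,
                           baseline_shape1 = 5, baseline_shape2 = 5,
                           spikes = c(PW0001 = 8))
  expect_warning(sim <- simulate_cohorts(cfg), "saturated")
  expect_true(all(sim$truth$case_rates <= 1))
  spiked_genes <- sim$truth$pathways$PW0001
  other <- setdiff(names(sim$truth$gene_rates), spiked_genes)
  expect_equal(sim$truth$case_rates[other], sim$truth$gene_rates[other])
  expect_true(all(sim$truth$case_rates[spiked_genes] >=
                    sim$truth$gene_rates[spiked_genes]))
})

test_that("a null design lists no enriched pathway in its truth table", {
  sim <- simulate_cohorts(simulation_config(
    seed = 5, cohorts = small_design(), n_genes = 50, n_pathways = 6,
    genes_per_pathway = 5))
  expect_equal(sim$truth$spiked, character(0))
  expect_identical(sim$truth$case_rates, sim$truth$gene_rates)
})
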