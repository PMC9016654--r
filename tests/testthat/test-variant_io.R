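test_that("header-only VCF yields an empty record set with zero failures", {
  p <- write_vcf_fixture(snpeff_header(c("S1", "S2")), character(0))
  v <- read_vcf(p)
  expect_equal(nrow(v), 0L)
  expect_equal(attr(v, "n_parse_failures"), 0L)
})

test_that("multi-allelic sites split per alt with matched annotation, AC and carriers", {
  body <- paste(c("1", "200", ".", "G", "C,A", "50", "PASS",
                  paste0("ANN=C|missense_variant|MODERATE|G2|g2|transcript|t2,",
                         "A|frameshift_variant|HIGH|G2|g2|transcript|t2;",
                         "gnomAD_AC=3,11;gnomAD_AN=280000"),
                  "GT", "1/2", "0/1", "0/2"), collapse = "\t")
  p <- write_vcf_fixture(snpeff_header(c("S1", "S2", "S3")), body)
  v <- read_vcf(p)
  expect_equal(nrow(v), 2L)
  expect_equal(v$chrom, c("1", "1"))
  expect_equal(v$pos, c(200L, 200L))
  expect_equal(v$ref, c("G", "G"))
  expect_equal(v$alt, c("C", "A"))
  expect_equal(v$consequences[[1]], "missense_variant")
  expect_equal(v$consequences[[2]], "frameshift_variant")
  expect_equal(v$pop_ac, c(3L, 11L))
  expect_equal(v$pop_an, c(280000L, 280000L))
  # S1 is 1/2 (both alts), S2 0/1 (alt 1), S3 0/2 (alt 2)
  expect_setequal(v$carriers[[1]], c("S1", "S2"))
  expect_setequal(v$carriers[[2]], c("S1", "S3"))
  # splitting preserves the multiset of (chrom,pos,ref,alt,sample) tuples
  tuples <- unlist(lapply(seq_len(nrow(v)), function(i)
    paste(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], v$carriers[[i]])))
  expect_setequal(tuples, c("1 200 G C S1", "1 200 G C S2",
                            "1 200 G A S1", "1 200 G A S3"))
})

test_that("genotype conventions: het, hom, phased and haploid all mark a carrier once", {
  body <- paste(c("1", "100", ".", "A", "T", "50", "PASS",
                  "ANN=T|stop_gained|HIGH|G1|g1|transcript|t1;gnomAD_AC=0",
                  "GT", "0/1", "1/1", "1|0", "1", "0/0", "./."),
                collapse = "\t")
  p <- write_vcf_fixture(snpeff_header(paste0("S", 1:6)), body)
  v <- read_vcf(p)
  expect_setequal(v$carriers[[1]], c("S1", "S2", "S3", "S4"))
})

test_that("VEP CSQ dialect parses symbols and per-allele consequences", {
  body <- paste(c("2", "500", ".", "T", "G", "50", "PASS",
                  "CSQ=G|splice_donor_variant&intron_variant|HIGH|TP53|ENSG1;gnomAD_AC=4",
                  "GT", "0/1"), collapse = "\t")
  p <- write_vcf_fixture(vep_header("S1"), body)
  v <- read_vcf(p)           # auto-detects CSQ
  expect_equal(attr(v, "dialect"), "vep_csq")
  expect_equal(v$genes[[1]], "TP53")
  expect_setequal(v$consequences[[1]],
                  c("splice_donor_variant", "intron_variant"))
  expect_equal(v$pop_ac, 4L)
  expect_true(is.na(v$pop_an))
})

test_that("auto-detection failure names both dialects; parse failures are tallied", {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"))
  p <- write_vcf_fixture(hdr, paste(c("1", "1", ".", "A", "T", "5", "PASS",
                                      ".", "GT", "0/1"), collapse = "\t"))
  expect_error(read_vcf(p), "CSQ.*ANN|ANN.*CSQ")
  expect_error(read_vcf(tempfile()), "not found")

  # record lacking the ANN key under a forced dialect: skipped + counted
  body <- c(paste(c("1", "100", ".", "A", "T", "5", "PASS", "gnomAD_AC=1",
                    "GT", "0/1"), collapse = "\t"),
            paste(c("1", "200", ".", "A", "T", "5", "PASS",
                    "ANN=T|stop_gained|HIGH|G1|g1|transcript|t1",
                    "GT", "0/1"), collapse = "\t"))
  p2 <- write_vcf_fixture(snpeff_header("S1"), body)
  v <- read_vcf(p2, dialect = "snpeff_ann")
  expect_equal(nrow(v), 1L)
  expect_equal(attr(v, "n_parse_failures"), 1L)
})

test_that("parsing is order-stable across repeated reads", {
  sim <- simulate_cohorts(simulation_config(
    seed = 11, cohorts = data.frame(cohort_id = c("A", "B"),
                                    n_samples = c(5L, 5L),
                                    is_case = c(TRUE, FALSE)),
    n_genes = 40, n_pathways = 5, genes_per_pathway = 4,
    emit = c("vcf", "manifest")), dir = withr::local_tempdir())
  v1 <- read_vcf(sim$paths$vcf)
  v2 <- read_vcf(sim$paths$vcf)
  expect_identical(v1, v2)
  # record count equals the generator's truth log
  expect_equal(nrow(v1), nrow(sim$truth$variants))
})

test_that("manifest reading validates duplicates, case flag and cohort count", {
  m <- make_manifest(c(CASE = 2L, CTRL = 2L))
  p <- write_manifest_tsv(m)
  got <- read_manifest(p)
  expect_s3_class(got, "sample_manifest")
  expect_equal(length(got$cohorts), 2L)
  expect_equal(got$case_cohort, "CASE")

  writeLines(c("sample_id\tcohort_id\tis_case",
               "S1\tA\t1", "S1\tA\t1", "S2\tB\t0"), p2 <- tempfile())
  expect_error(read_manifest(p2), "duplicate")
  writeLines(c("sample_id\tcohort_id\tis_case", "S1\tA\t1", "S2\tA\t1"),
             p3 <- tempfile())
  expect_error(read_manifest(p3), "2 cohorts")
  expect_error(sample_manifest(c(S1 = "A", S2 = "B"), "C"), "not present")
})

test_that("the study-scale manifest design is accepted and sizes add up", {
  sizes <- c(CASE = 39L, PEDCOV = 24L,
             stats::setNames(c(586L, 586L, rep(585L, 6)), paste0("REF", 1:8)))
  m <- make_manifest(sizes)
  expect_equal(sum(m$sizes), 39L + 24L + 4682L)
  expect_equal(length(m$cohorts), 10L)     # case + 9 comparison cohorts
  expect_equal(sum(m$sizes[setdiff(m$cohorts, c("CASE", "PEDCOV"))]), 4682L)
  expect_equal(sum(m$sizes), length(m$assignments))
})
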