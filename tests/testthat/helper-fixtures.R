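# fixture builders: tiny hand-written VCFs and manifests, constructed in
# code at test time

snpeff_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele | Annotation | Annotation_Impact | ",
           "Gene_Name | Gene_ID | Feature_Type | Feature_ID'\">"),
    "##INFO=<ID=gnomAD_AC,Number=A,Type=Integer,Description=\"gnomAD AC\">",
    "##INFO=<ID=gnomAD_AN,Number=1,Type=Integer,Description=\"gnomAD AN\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vep_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations from Ensembl VEP. Format: ",
           "Allele|Consequence|IMPACT|SYMBOL|Gene\">"),
    "##INFO=<ID=gnomAD_AC,Number=A,Type=Integer,Description=\"gnomAD AC\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_vcf_fixture <- function(header, body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(header, body), path)
  path
}

make_manifest <- function(sizes, case = names(sizes)[1]) {
  assignments <- stats::setNames(
    rep(names(sizes), sizes),
    unlist(lapply(names(sizes), function(co)
      sprintf("%s_%03d", co, seq_len(sizes[[co]])))))
  sample_manifest(assignments, case)
}

write_manifest_tsv <- function(manifest, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(sample_id = names(manifest$assignments),
                   cohort_id = unname(manifest$assignments),
                   is_case = as.integer(manifest$assignments ==
                                          manifest$case_cohort))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal annotated_variants data frame built in code (no file round trip)
make_variants <- function(consequences, pop_ac, genes = NULL,
                          carriers = NULL) {
  n <- length(consequences)
  if (is.null(genes)) genes <- as.list(sprintf("G%03d", seq_len(n)))
  if (is.null(carriers)) carriers <- rep(list(character(0)), n)
  data.frame(chrom = rep("1", n), pos = seq_len(n) * 10L,
             ref = rep("C", n), alt = rep("T", n),
             genes = I(genes), consequences = I(consequences),
             pop_ac = as.integer(pop_ac),
             pop_an = rep(NA_integer_, n),
             pop_af = rep(NA_real_, n), carriers = I(carriers),
             stringsAsFactors = FALSE)
}
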