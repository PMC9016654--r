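#' Configuration for the synthetic multi-cohort generator
#'
#' Describes a case-control exome study at the level the burden analysis
#' consumes: per-gene qualifying-carrier probabilities drawn from a Beta
#' distribution, a pathway collection over the genes, and optional
#' "spiked" pathways whose member-gene carrier rates are multiplied in
#' case samples only. The default cohort design mirrors a study with one
#' 39-sample case cohort, a 24-sample acute-disease comparison cohort and
#' 8 heterogeneous comparison cohorts totalling 4,682 exomes.
#'
#' @param seed integer master seed; everything downstream is a pure
#'   function of it.
#' @param cohorts data frame with columns \code{cohort_id},
#'   \code{n_samples}, \code{is_case} (exactly one TRUE).
#' @param n_genes number of genes.
#' @param baseline_shape1,baseline_shape2 Beta(alpha, beta) parameters
#'   for per-gene qualifying-carrier probability (defaults 0.5 and 200,
#'   mean 0.0025 — a realistic rare-LoF carrier rate).
#' @param n_pathways number of pathways.
#' @param genes_per_pathway integer scalar or length-\code{n_pathways}
#'   vector; members are sampled without replacement per pathway.
#' @param spikes named numeric vector, pathway id to case relative risk
#'   (all >= 1); member-gene rates are multiplied by the relative risk
#'   for case samples, capped at 1.
#' @param variants_per_event qualifying variants materialized per
#'   carrier-gene event when a VCF is emitted (default 1).
#' @param decoy_fraction fraction of emitted variants that must NOT
#'   qualify (wrong class, or allele count above the rarity bound);
#'   default 0.5 so every round trip exercises the rejection paths.
#' @param emit subset of \code{c("matrix","vcf","gmt","manifest")};
#'   \code{"matrix"} is always produced in memory.
#' @return A validated \code{"simulation_config"} object.
#' @export
simulation_config <- function(seed = 1L,
                              cohorts = default_cohorts(),
                              n_genes = 4000L,
                              baseline_shape1 = 0.5,
                              baseline_shape2 = 200,
                              n_pathways = 200L,
                              genes_per_pathway = 20L,
                              spikes = NULL,
                              variants_per_event = 1L,
                              decoy_fraction = 0.5,
                              emit = "matrix") {
  stopifnot(is.data.frame(cohorts),
            all(c("cohort_id", "n_samples", "is_case") %in% names(cohorts)))
  if (sum(cohorts$is_case) != 1L) stop("exactly one cohort must be the case")
  if (any(cohorts$n_samples <= 0)) stop("cohort sizes must be > 0")
  if (n_genes <= 0 || n_pathways <= 0) stop("sizes must be > 0")
  gpp <- rep_len(as.integer(genes_per_pathway), n_pathways)
  if (any(gpp <= 0) || any(gpp > n_genes))
    stop("genes_per_pathway must be in 1..n_genes")
  pw_ids <- sprintf("PW%04d", seq_len(n_pathways))
  if (!is.null(spikes)) {
    if (is.null(names(spikes)) || !all(names(spikes) %in% pw_ids))
      stop("spike names must be pathway ids of the collection")
    if (any(spikes < 1)) stop("spike relative risks must be >= 1")
  }
  if (decoy_fraction < 0 || decoy_fraction >= 1)
    stop("decoy_fraction must be in [0, 1)")
  bad <- setdiff(emit, c("matrix", "vcf", "gmt", "manifest"))
  if (length(bad)) stop("unknown emit format(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 n_genes = as.integer(n_genes),
                 baseline_shape1 = baseline_shape1,
                 baseline_shape2 = baseline_shape2,
                 n_pathways = as.integer(n_pathways),
                 genes_per_pathway = gpp,
                 spikes = spikes,
                 variants_per_event = as.integer(variants_per_event),
                 decoy_fraction = decoy_fraction,
                 emit = unique(c("matrix", emit))),
            class = "simulation_config")
}

#' Default study design: one case cohort vs 9 comparison cohorts
#'
#' 39 cases, one 24-sample comparison cohort and 8 comparison cohorts
#' totalling 4,682 samples.
#'
#' @return Data frame with columns \code{cohort_id}, \code{n_samples},
#'   \code{is_case}.
#' @export
default_cohorts <- function() {
  data.frame(
    cohort_id = c("CASE", "PEDCOV", paste0("REF", 1:8)),
    n_samples = c(39L, 24L, 586L, 586L, rep(585L, 6)),
    is_case = c(TRUE, rep(FALSE, 9)),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-cohort rare-variant study
#'
#' Draws per-gene carrier probabilities once from the configured Beta
#' distribution, applies pathway spikes to case samples (rates capped at
#' 1, saturations counted and warned about), samples carrier indicators
#' independently per sample and gene, and — when file formats are
#' requested — materializes every carrier-gene event as qualifying
#' variant record(s) in an annotated VCF, together with decoy variants
#' guaranteed not to qualify (non-qualifying consequence class, or
#' population allele count above the rarity bound; the first frequency
#' decoy sits exactly at count 11 and the first qualifying variant at
#' count 10 to pin the boundary). The run is a pure function of the
#' seed: identical seeds give byte-identical files.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param dir output directory for emitted files (created if needed);
#'   required when \code{config$emit} requests files.
#' @return List with \code{carrier_gene} (gene-level
#'   \code{carrier_matrix}), \code{manifest}, \code{collection},
#'   \code{truth} (gene rates, pathway membership, spiked ids, realized
#'   per-cohort pathway carrier counts, emitted variant table,
#'   saturation count) and \code{paths} (named emitted file paths).
#' @export
simulate_cohorts <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  wants_files <- length(setdiff(config$emit, "matrix")) > 0
  if (wants_files && is.null(dir))
    stop("emit formats ", paste(setdiff(config$emit, "matrix"), collapse = ","),
         " need an output directory")
  set.seed(config$seed)

  co <- config$cohorts
  sample_ids <- unlist(lapply(seq_len(nrow(co)), function(i)
    sprintf("%s_S%04d", co$cohort_id[i], seq_len(co$n_samples[i]))))
  assignments <- stats::setNames(
    rep(co$cohort_id, co$n_samples), sample_ids)
  manifest <- sample_manifest(assignments, co$cohort_id[co$is_case])
  is_case_sample <- assignments == manifest$case_cohort
  N <- length(sample_ids)

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  rates <- stats::rbeta(config$n_genes, config$baseline_shape1,
                        config$baseline_shape2)
  names(rates) <- genes

  pw_ids <- sprintf("PW%04d", seq_len(config$n_pathways))
  gpp <- config$genes_per_pathway
  if (sum(gpp) <= config$n_genes) {
    # disjoint memberships: spiked pathways then leak no signal into
    # unspiked ones, keeping them true nulls for power testing
    pool <- sample(genes, sum(gpp))
    members <- split(pool, rep.int(seq_along(gpp), gpp))
  } else {
    members <- lapply(gpp, function(k) sample(genes, k))
  }
  names(members) <- pw_ids
  collection <- gene_set_collection(
    members, name = stats::setNames(paste("synthetic pathway", pw_ids), pw_ids),
    source = stats::setNames(rep("synthetic", length(pw_ids)), pw_ids))

  # case rates: spiked pathways multiply member-gene rates (max RR when a
  # gene sits in several spiked pathways), capped at 1
  case_rates <- rates
  n_sat <- 0L
  if (!is.null(config$spikes)) {
    rr_gene <- stats::setNames(rep(1, config$n_genes), genes)
    for (pw in names(config$spikes))
      rr_gene[members[[pw]]] <- pmax(rr_gene[members[[pw]]],
                                     config$spikes[[pw]])
    raw <- rates * rr_gene
    n_sat <- sum(raw > 1)
    if (n_sat > 0)
      warning(n_sat, " gene rate(s) saturated at 1 under spiking")
    case_rates <- stats::setNames(pmin(1, raw), genes)
  }

  # carrier indicators, case rows then the rest, gene-major draws
  prob <- matrix(rep(rates, each = N), nrow = N)
  if (any(is_case_sample) && !is.null(config$spikes))
    prob[is_case_sample, ] <- matrix(rep(case_rates, each = sum(is_case_sample)),
                                     nrow = sum(is_case_sample))
  M <- matrix(stats::rbinom(N * config$n_genes, 1L, prob) == 1L,
              nrow = N, dimnames = list(sample_ids, genes))
  carrier_gene <- as_carrier_matrix(M, level = "gene")

  pw_mat <- collapse_to_pathways(carrier_gene, collection)
  counts_by_cohort <- do.call(rbind, lapply(manifest$cohorts, function(cid)
    colSums(pw_mat[assignments == cid, , drop = FALSE])))
  rownames(counts_by_cohort) <- manifest$cohorts

  variants <- NULL
  paths <- list()
  if ("vcf" %in% config$emit)
    variants <- .materialize_variants(M, config)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if ("vcf" %in% config$emit) {
    paths$vcf <- file.path(dir, "cohort.vcf")
    .write_synthetic_vcf(variants, sample_ids, paths$vcf)
  }
  if ("gmt" %in% config$emit) {
    paths$gmt <- file.path(dir, "pathways.gmt")
    writeLines(vapply(pw_ids, function(id)
      paste(c(id, collection$name[[id]], members[[id]]), collapse = "\t"), ""),
      paths$gmt)
  }
  if ("manifest" %in% config$emit) {
    paths$manifest <- file.path(dir, "manifest.tsv")
    utils::write.table(
      data.frame(sample_id = sample_ids, cohort_id = unname(assignments),
                 is_case = ifelse(is_case_sample, "1", "0")),
      paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  truth <- list(gene_rates = rates, case_rates = case_rates,
                pathways = members,
                spiked = if (is.null(config$spikes)) character(0)
                         else names(config$spikes),
                spike_rr = config$spikes,
                pathway_counts_by_cohort = counts_by_cohort,
                variants = variants,
                n_saturated = n_sat,
                seed = config$seed)
  if (!is.null(dir) && wants_files) {
    paths$truth <- file.path(dir, "truth.json")
    .write_truth_json(truth, paths$truth)
  }
  list(carrier_gene = carrier_gene, pathway_matrix = pw_mat,
       manifest = manifest, collection = collection,
       truth = truth, paths = paths)
}

.qualifying_terms <- c("stop_gained", "start_lost", "frameshift_variant",
                       "splice_acceptor_variant", "splice_donor_variant")

# one row per emitted variant; qualifying rows realize the carrier-gene
# events of M, decoy rows must be rejected by class or by frequency
.materialize_variants <- function(M, config) {
  ev <- which(M, arr.ind = TRUE)
  sample_ids <- rownames(M); genes <- colnames(M)
  n_ev <- nrow(ev)
  rows <- list()
  if (n_ev > 0) {
    n_q <- n_ev * config$variants_per_event
    cons <- sample(.qualifying_terms, n_q, replace = TRUE)
    ac <- sample(0:10, n_q, replace = TRUE)
    ac[1] <- 10L  # pin the inclusive rarity boundary
    ev_idx <- rep(seq_len(n_ev), each = config$variants_per_event)
    rows$qual <- data.frame(
      gene = genes[ev[ev_idx, 2]],
      carrier = sample_ids[ev[ev_idx, 1]],
      consequence = cons, pop_ac = ac,
      qualifying = TRUE, stringsAsFactors = FALSE)
  }
  n_qual <- if (is.null(rows$qual)) 0L else nrow(rows$qual)
  n_decoy <- if (config$decoy_fraction > 0)
    max(2L, round(config$decoy_fraction / (1 - config$decoy_fraction) * n_qual))
  else 0L
  if (n_decoy > 0) {
    # alternate class decoys (rare but non-qualifying consequence) and
    # frequency decoys (qualifying consequence, AC above the bound)
    kind <- rep_len(c("class", "freq"), n_decoy)
    cons <- ifelse(kind == "class",
                   sample(c("missense_variant", "synonymous_variant",
                            "splice_region_variant", "intron_variant"),
                          n_decoy, replace = TRUE),
                   sample(.qualifying_terms, n_decoy, replace = TRUE))
    ac <- ifelse(kind == "class",
                 sample(0:10, n_decoy, replace = TRUE),
                 sample(11:100, n_decoy, replace = TRUE))
    ac[which(kind == "freq")[1]] <- 11L  # pin the just-too-common boundary
    rows$decoy <- data.frame(
      gene = sample(genes, n_decoy, replace = TRUE),
      carrier = sample(sample_ids, n_decoy, replace = TRUE),
      consequence = cons, pop_ac = as.integer(ac),
      qualifying = FALSE, stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, rows)
  if (is.null(v) || nrow(v) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), carrier = character(0),
                      consequence = character(0), pop_ac = integer(0),
                      qualifying = logical(0)))
  n <- nrow(v)
  fs <- v$consequence == "frameshift_variant"
  v$chrom <- "1"
  v$pos <- seq_len(n) * 100L
  v$ref <- ifelse(fs, "CA", "C")
  v$alt <- "T"
  v$alt[fs] <- "C"
  rownames(v) <- NULL
  v[, c("chrom", "pos", "ref", "alt", "gene", "carrier", "consequence",
        "pop_ac", "qualifying")]
}

.write_synthetic_vcf <- function(variants, sample_ids, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele | Annotation | Annotation_Impact | ",
           "Gene_Name | Gene_ID | Feature_Type | Feature_ID'\">"),
    "##INFO=<ID=gnomAD_AC,Number=A,Type=Integer,Description=\"gnomAD allele count\">",
    "##INFO=<ID=gnomAD_AN,Number=1,Type=Integer,Description=\"gnomAD allele number\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  body <- character(nrow(variants))
  if (nrow(variants) > 0) {
    ord <- order(variants$pos)
    variants <- variants[ord, ]
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      impact <- if (v$qualifying) "HIGH" else "MODERATE"
      info <- sprintf("ANN=%s|%s|%s|%s|%s|transcript|t1;gnomAD_AC=%d;gnomAD_AN=280000",
                      v$alt, v$consequence, impact, v$gene,
                      tolower(v$gene), v$pop_ac)
      gts <- ifelse(sample_ids == v$carrier, "0/1", "0/0")
      body[i] <- paste(c(v$chrom, v$pos, ".", v$ref, v$alt, "50", "PASS",
                         info, "GT", gts), collapse = "\t")
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

.write_truth_json <- function(truth, path) {
  out <- list(
    seed = truth$seed,
    gene_rates = as.list(truth$gene_rates),
    pathways = truth$pathways,
    spiked = truth$spiked,
    spike_rr = if (is.null(truth$spike_rr)) NULL else as.list(truth$spike_rr),
    pathway_counts_by_cohort =
      as.data.frame(t(truth$pathway_counts_by_cohort)),
    n_saturated = truth$n_saturated,
    n_qualifying_variants = if (is.null(truth$variants)) 0L
                            else sum(truth$variants$qualifying),
    variants = truth$variants)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = FALSE)
  invisible(path)
}
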