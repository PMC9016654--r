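#' Load and validate a pipeline run configuration
#'
#' The configuration is a YAML file with keys: \code{vcf} (path or list
#' of paths), \code{gmt} (path or list; optionally a named list tag:
#' path, where the tag becomes the collection source), \code{manifest}
#' (path), \code{case_cohort} (optional), \code{output_dir}, and
#' optional blocks \code{qualification} (\code{max_pop_allele_count},
#' \code{reference_chromosomes}, \code{treat_missing_as_rare},
#' \code{qualifying_classes}), \code{genesets}
#' (\code{min_genes}, \code{max_genes}), \code{enrichment}
#' (\code{alternative}, \code{fdr_method}, \code{alpha}), \code{mc}
#' (\code{n_perm}, \code{seed}, \code{statistic}), \code{consensus}
#' (\code{rule}, \code{k}), \code{io} (\code{dialect}, \code{ac_key},
#' \code{an_key}, \code{af_key}).
#'
#' @param path YAML file path, or an already-parsed list.
#' @return A validated \code{"run_config"} list with defaults filled in.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    case_cohort = NULL,
    qualification = list(max_pop_allele_count = 10L,
                         reference_chromosomes = 280000L,
                         treat_missing_as_rare = TRUE,
                         qualifying_classes = c("stop_gain", "start_loss",
                                                "frameshift",
                                                "canonical_splice")),
    genesets = list(min_genes = 2, max_genes = 2000),
    enrichment = list(alternative = "greater", fdr_method = "BH",
                      alpha = 0.05),
    mc = list(n_perm = 10000L, seed = 1L, statistic = "carrier_count"),
    consensus = list(rule = "all_groups", k = NULL),
    io = list(dialect = "auto", ac_key = "gnomAD_AC", an_key = "gnomAD_AN",
              af_key = "gnomAD_AF"))
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      cfg[[k]] <- utils::modifyList(defaults[[k]], cfg[[k]])
  }
  for (k in c("vcf", "gmt", "manifest", "output_dir"))
    if (is.null(cfg[[k]])) stop("run config is missing required key: ", k)
  for (p in unlist(c(cfg$vcf, cfg$gmt, cfg$manifest)))
    if (!file.exists(p)) stop("configured input does not exist: ", p)
  a <- cfg$enrichment$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1) stop("alpha must be in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full burden-enrichment pipeline
#'
#' Executes read -> qualify -> gene carrier matrix -> pathway collapse
#' -> per-comparison Fisher with FDR -> Monte-Carlo test vs the pooled
#' comparisons -> consensus report, and writes TSV reports plus a
#' machine-readable JSON run manifest (package version, seed, config
#' hash, per-stage counts) into the configured output directory.
#' Identical configuration and inputs give identical outputs for any
#' worker count.
#'
#' @param config a \code{run_config}, a YAML path, or a plain list
#'   accepted by \code{\link{load_run_config}}.
#' @param workers worker processes for the Monte-Carlo stage.
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, a list with \code{qualified}, \code{fisher},
#'   \code{mc}, \code{consensus}, \code{counts} and \code{paths}.
#' @export
run_pipeline <- function(config, workers = 1L, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- load_run_config(config)
  log <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] %s", stage, paste0(...)))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- read_manifest(config$manifest,
                            case_cohort = config$case_cohort)
  log("manifest", length(manifest$assignments), " samples in ",
      length(manifest$cohorts), " cohorts; case = ", manifest$case_cohort)

  io <- config$io
  vcfs <- lapply(unlist(config$vcf), read_vcf, dialect = io$dialect,
                 ac_key = io$ac_key, an_key = io$an_key, af_key = io$af_key)
  variants <- do.call(rbind, vcfs)
  n_fail <- sum(vapply(vcfs, attr, 0L, "n_parse_failures"))
  log("read", nrow(variants), " variant records (",
      n_fail, " parse failures)")

  rule <- do.call(qualification_rule, list(
    qualifying_classes = config$qualification$qualifying_classes,
    max_pop_allele_count = config$qualification$max_pop_allele_count,
    reference_chromosomes = config$qualification$reference_chromosomes,
    treat_missing_as_rare = config$qualification$treat_missing_as_rare))
  qualified <- qualify_variants(variants, rule)
  counts <- list(variants_in = nrow(variants) + n_fail,
                 parse_failures = n_fail,
                 qualified = nrow(qualified),
                 rejected_by_class = attr(qualified, "n_rejected_class"),
                 rejected_by_frequency =
                   attr(qualified, "n_rejected_frequency"))
  log("qualify", counts$qualified, " qualifying of ", nrow(variants),
      " parsed (", counts$rejected_by_class, " wrong class, ",
      counts$rejected_by_frequency, " too common)")

  gmts <- config$gmt
  tags <- if (!is.null(names(gmts)) && any(nzchar(names(gmts))))
    names(gmts) else rep("other", length(gmts))
  colls <- lapply(seq_along(gmts), function(i)
    read_gmt(gmts[[i]], source = tags[i],
             size_bounds = c(config$genesets$min_genes,
                             config$genesets$max_genes)))
  collection <- if (length(colls) > 1L) do.call(merge_collections, colls)
                else colls[[1]]
  log("genesets", length(collection), " pathways retained (",
      collection$n_skipped_lines, " malformed lines, ",
      collection$n_dropped_size, " outside size bounds)")

  gene_m <- build_carrier_matrix(qualified, manifest)
  pw_m <- collapse_to_pathways(gene_m, collection)
  counts$genes <- ncol(gene_m)
  counts$pathways_tested <- ncol(pw_m)
  log("collapse", ncol(gene_m), " genes -> ", ncol(pw_m), " pathways (",
      length(attr(pw_m, "empty_pathways")), " with no represented gene)")

  fisher <- fisher_enrichment(pw_m, manifest,
                              alternative = config$enrichment$alternative,
                              fdr_method = config$enrichment$fdr_method)
  log("fisher", nrow(fisher), " tests over ",
      length(unique(fisher$comparison)), " comparison cohorts")

  mc <- mc_pathway_test(pw_m, manifest,
                        n_perm = config$mc$n_perm, seed = config$mc$seed,
                        statistic = config$mc$statistic, workers = workers)
  log("mc", config$mc$n_perm, " label permutations vs pooled comparisons, ",
      "seed ", config$mc$seed)

  consensus <- consensus_rank(fisher, mc,
                              rule = config$consensus$rule,
                              k = config$consensus$k,
                              alpha = config$enrichment$alpha)
  log("consensus", sum(consensus$flagged), " pathway(s) flagged at alpha = ",
      config$enrichment$alpha)

  paths <- list(
    qualified = file.path(config$output_dir, "qualified_variants.tsv"),
    fisher = file.path(config$output_dir, "fisher_enrichment.tsv"),
    mc = file.path(config$output_dir, "mc_results.tsv"),
    consensus = file.path(config$output_dir, "consensus.tsv"),
    run_manifest = file.path(config$output_dir, "run_manifest.json"))
  write_qualified_tsv(qualified, paths$qualified)
  .write_tsv(fisher, paths$fisher)
  .write_tsv(mc, paths$mc)
  .write_tsv(consensus, paths$consensus)
  .write_run_manifest(config, counts, paths$run_manifest)

  invisible(list(qualified = qualified, fisher = fisher, mc = mc,
                 consensus = consensus, counts = counts, paths = paths))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run manifest: versions, seed, config hash, stage counts; no timestamp,
# so reruns of an identical configuration are byte-identical
.write_run_manifest <- function(config, counts, path) {
  cfg_plain <- unclass(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg_plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  hash <- unname(tools::md5sum(tmp))
  jsonlite::write_json(
    list(package = "pathburden",
         version = as.character(utils::packageVersion("pathburden")),
         seed = config$mc$seed,
         config_md5 = hash,
         config = cfg_plain,
         stage_counts = counts,
         null_model = paste("Monte-Carlo: case labels permuted over the",
                            "pooled cohort, cohort sizes preserved")),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
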