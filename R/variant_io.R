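#' Read an annotated VCF into normalized per-allele variant records
#'
#' Parses a VCF 4.x file (plain or bgzipped) whose INFO field carries
#' functional annotations in either the VEP \code{CSQ=} or SnpEff
#' \code{ANN=} dialect, and returns one record per (site, alternate
#' allele) with the gene symbols, consequence terms, population allele
#' counts and carrier samples attached.
#'
#' Multi-allelic sites are split into one record per alternate allele;
#' per-allele annotation entries and \code{Number=A} INFO values are
#' matched to the correct allele. A sample is a carrier of an allele if
#' its genotype contains that allele index at least once (\code{0/1},
#' \code{1/1}, \code{1|0} and haploid \code{1} all count once;
#' \code{0/0} and \code{./.} do not).
#'
#' @param path path to the VCF file.
#' @param dialect annotation dialect: \code{"auto"} (detect from the
#'   header), \code{"vep_csq"} or \code{"snpeff_ann"}.
#' @param ac_key,an_key,af_key INFO keys for the population (gnomAD)
#'   allele count, allele number and allele frequency. The frequency is
#'   only consulted downstream when the count is absent.
#' @return A data frame of class \code{"annotated_variants"} with one
#'   row per alternate allele and columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{genes} (list), \code{consequences}
#'   (list), \code{pop_ac}, \code{pop_an}, \code{pop_af},
#'   \code{carriers} (list). Attributes: \code{n_parse_failures} (records
#'   skipped for unparseable annotation), \code{dialect} (the dialect
#'   used), \code{samples} (sample columns seen in the file).
#' @export
read_vcf <- function(path, dialect = c("auto", "vep_csq", "snpeff_ann"),
                     ac_key = "gnomAD_AC", an_key = "gnomAD_AN",
                     af_key = "gnomAD_AF") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta

  has_csq <- any(grepl("^##INFO=<ID=CSQ[,>]", meta))
  has_ann <- any(grepl("^##INFO=<ID=ANN[,>]", meta))
  if (dialect == "auto") {
    if (has_csq) dialect <- "vep_csq"
    else if (has_ann) dialect <- "snpeff_ann"
    else stop("cannot auto-detect annotation dialect: header defines ",
              "neither INFO/CSQ (VEP) nor INFO/ANN (SnpEff)")
  }
  ann_key <- if (dialect == "vep_csq") "CSQ" else "ANN"
  fields <- .ann_field_names(meta, ann_key)
  idx <- .ann_field_indices(fields, dialect)

  fix <- vcf@fix
  gt <- vcf@gt
  samples <- if (!is.null(gt) && ncol(gt) > 1) colnames(gt)[-1] else character(0)

  rows <- list()
  n_fail <- 0L
  if (nrow(fix) > 0) {
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      info <- .parse_info(fix[i, "INFO"])
      ann_raw <- info[[ann_key]]
      entries <- if (is.null(ann_raw)) list() else
        lapply(strsplit(ann_raw, ",", fixed = TRUE)[[1]],
               function(e) strsplit(e, "|", fixed = TRUE)[[1]])
      # a record is unparseable if annotation is absent or every entry is
      # too short to hold the consequence field
      min_len <- max(idx$allele, idx$consequence, idx$gene)
      ok_entries <- entries[vapply(entries, length, 1L) >= min_len]
      if (length(ok_entries) == 0L) {
        n_fail <- n_fail + length(alts)
        next
      }
      acs <- .split_number_a(info[[ac_key]], length(alts))
      afs <- .split_number_a(info[[af_key]], length(alts))
      an <- suppressWarnings(as.integer(info[[an_key]]))
      if (length(an) == 0L) an <- NA_integer_
      gts <- if (length(samples)) .extract_gt(gt[i, , drop = TRUE]) else character(0)
      for (k in seq_along(alts)) {
        ent <- .match_entries(ok_entries, idx$allele,
                              fix[i, "REF"], alts[k], length(alts))
        genes <- unique(vapply(ent, `[`, "", idx$gene))
        genes <- genes[!is.na(genes) & nzchar(genes)]
        cons <- unique(unlist(lapply(ent, function(e)
          strsplit(e[idx$consequence], "&", fixed = TRUE)[[1]])))
        cons <- cons[!is.na(cons) & nzchar(cons)]
        carriers <- samples[.is_carrier(gts, k)]
        rows[[length(rows) + 1L]] <- list(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[k],
          genes = genes, consequences = cons,
          pop_ac = acs[k], pop_an = an, pop_af = afs[k],
          carriers = carriers)
      }
    }
  }
  out <- .variants_df(rows)
  attr(out, "n_parse_failures") <- n_fail
  attr(out, "dialect") <- dialect
  attr(out, "samples") <- samples
  class(out) <- c("annotated_variants", class(out))
  out
}

.variants_df <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genes = I(list()), consequences = I(list()),
                      pop_ac = integer(0), pop_an = integer(0),
                      pop_af = numeric(0), carriers = I(list()),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 1L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    genes = I(lapply(rows, `[[`, "genes")),
    consequences = I(lapply(rows, `[[`, "consequences")),
    pop_ac = as.integer(round(vapply(rows, `[[`, NA_real_, "pop_ac"))),
    pop_an = vapply(rows, `[[`, NA_integer_, "pop_an"),
    pop_af = vapply(rows, `[[`, NA_real_, "pop_af"),
    carriers = I(lapply(rows, `[[`, "carriers")),
    stringsAsFactors = FALSE)
}

# field names from the header Description line, e.g.
#   CSQ: "Consequence annotations from Ensembl VEP. Format: Allele|Consequence|SYMBOL"
#   ANN: "Functional annotations: 'Allele | Annotation | ... | Gene_Name | ...'"
.ann_field_names <- function(meta, key) {
  line <- grep(paste0("^##INFO=<ID=", key, "[,>]"), meta, value = TRUE)
  if (length(line) == 0L)
    stop("VCF header has no INFO/", key, " definition")
  desc <- sub(".*Description=\"(.*)\".*", "\\1", line[1])
  fmt <- if (grepl("Format:", desc)) sub(".*Format:\\s*", "", desc)
         else if (grepl("'", desc)) sub(".*?'(.*)'.*", "\\1", desc)
         else desc
  trimws(strsplit(fmt, "|", fixed = TRUE)[[1]])
}

.ann_field_indices <- function(fields, dialect) {
  find <- function(cands) {
    for (nm in cands) {
      j <- match(nm, fields)
      if (!is.na(j)) return(j)
    }
    NA_integer_
  }
  if (dialect == "vep_csq") {
    out <- list(allele = find("Allele"),
                consequence = find("Consequence"),
                gene = find(c("SYMBOL", "Gene")))
  } else {
    out <- list(allele = find("Allele"),
                consequence = find(c("Annotation", "Effect")),
                gene = find(c("Gene_Name", "Gene_ID")))
  }
  if (is.na(out$consequence) || is.na(out$gene))
    stop("cannot locate consequence/gene fields in the ", dialect,
         " annotation header (fields seen: ", paste(fields, collapse = "|"), ")")
  if (is.na(out$allele)) out$allele <- 1L
  out
}

.parse_info <- function(info) {
  if (is.na(info) || info == ".") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) >= 2) x[2] else TRUE)
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

.split_number_a <- function(x, n_alt) {
  if (is.null(x)) return(rep(NA_real_, n_alt))
  v <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
  if (length(v) == n_alt) v else rep(v[1], n_alt)
}

# GT subfield per sample, honouring per-row FORMAT ordering
.extract_gt <- function(gt_row) {
  fmt <- strsplit(gt_row[[1]], ":", fixed = TRUE)[[1]]
  gi <- match("GT", fmt)
  vals <- gt_row[-1]
  vapply(vals, function(v) {
    if (is.na(v)) return(NA_character_)
    f <- strsplit(v, ":", fixed = TRUE)[[1]]
    if (is.na(gi) || gi > length(f)) NA_character_ else f[gi]
  }, "", USE.NAMES = FALSE)
}

# TRUE where the genotype string contains allele index k (carrier is
# binary: het, hom and hemizygous all count once)
.is_carrier <- function(gts, k) {
  vapply(gts, function(g) {
    if (is.na(g)) return(FALSE)
    any(strsplit(g, "[/|]")[[1]] == as.character(k))
  }, TRUE, USE.NAMES = FALSE)
}

# match annotation entries to one alt allele; VEP trims shared leading
# bases in the Allele field for indels, so try that form too
.match_entries <- function(entries, allele_idx, ref, alt, n_alt) {
  alleles <- vapply(entries, `[`, "", allele_idx)
  hit <- alleles == alt
  if (!any(hit) && nchar(ref) != nchar(alt) &&
      substr(ref, 1, 1) == substr(alt, 1, 1)) {
    trimmed <- if (nchar(alt) > 1) substr(alt, 2, nchar(alt)) else "-"
    hit <- alleles == trimmed
  }
  if (!any(hit) && n_alt == 1L) hit <- rep(TRUE, length(entries))
  entries[hit]
}

#' Read a sample-to-cohort manifest
#'
#' The manifest is a tab-separated file with header columns
#' \code{sample_id} and \code{cohort_id}, and optionally \code{is_case}
#' (logical or 0/1) flagging the case cohort. The case cohort can
#' alternatively be named via \code{case_cohort}.
#'
#' @param path path to the TSV manifest.
#' @param case_cohort cohort id of the case group; required when the
#'   file has no \code{is_case} column.
#' @return An object of class \code{"sample_manifest"}: a list with
#'   \code{assignments} (named character vector, sample id to cohort id),
#'   \code{case_cohort}, \code{cohorts} and \code{sizes}.
#' @export
read_manifest <- function(path, case_cohort = NULL) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "cohort_id") %in% names(df)))
    stop("manifest must have columns sample_id and cohort_id")
  if (is.null(case_cohort)) {
    if (!"is_case" %in% names(df))
      stop("no case cohort given and manifest has no is_case column")
    flag <- tolower(df$is_case) %in% c("true", "t", "1", "yes")
    cc <- unique(df$cohort_id[flag])
    if (length(cc) != 1L)
      stop("is_case column must flag exactly one cohort (found ",
           length(cc), ")")
    case_cohort <- cc
  }
  sample_manifest(stats::setNames(df$cohort_id, df$sample_id), case_cohort)
}

#' Construct and validate a sample manifest
#'
#' @param assignments named character vector mapping sample id to
#'   cohort id.
#' @param case_cohort the cohort id of the case group.
#' @return A validated \code{"sample_manifest"} object.
#' @export
sample_manifest <- function(assignments, case_cohort) {
  ids <- names(assignments)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("every sample needs an id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample id(s) in manifest: ",
         paste(unique(dup), collapse = ", "))
  cohorts <- unique(unname(assignments))
  if (length(cohorts) < 2L)
    stop("manifest must define at least 2 cohorts (found ",
         length(cohorts), ")")
  if (!case_cohort %in% cohorts)
    stop("case cohort '", case_cohort, "' not present in manifest")
  sizes <- table(factor(assignments, levels = cohorts))
  structure(list(assignments = assignments,
                 case_cohort = case_cohort,
                 cohorts = cohorts,
                 sizes = stats::setNames(as.integer(sizes), cohorts)),
            class = "sample_manifest")
}

#' @method print sample_manifest
#' @export
print.sample_manifest <- function(x, ...) {
  cat("sample_manifest:", length(x$assignments), "samples in",
      length(x$cohorts), "cohorts (case:", x$case_cohort, ")\n")
  for (co in x$cohorts)
    cat(sprintf("  %-12s %5d%s\n", co, x$sizes[[co]],
                if (co == x$case_cohort) "  [case]" else ""))
  invisible(x)
}

#' Comparison (non-case) sample ids of a manifest
#' @param manifest a \code{sample_manifest}.
#' @return character vector of sample ids outside the case cohort.
#' @export
comparison_samples <- function(manifest) {
  names(manifest$assignments)[manifest$assignments != manifest$case_cohort]
}

#' Case sample ids of a manifest
#' @param manifest a \code{sample_manifest}.
#' @return character vector of case-cohort sample ids.
#' @export
case_samples <- function(manifest) {
  names(manifest$assignments)[manifest$assignments == manifest$case_cohort]
}
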