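#' Rule for qualifying rare deleterious variants
#'
#' A qualifying variant must (i) carry a consequence in one of the
#' qualifying classes — stop-gain, start-loss, frameshift indel or
#' canonical splice-site — and (ii) be rare in the population reference:
#' at most \code{max_pop_allele_count} alleles among
#' \code{reference_chromosomes} reference chromosomes (default 10 in
#' 280,000). Variants absent from the reference are treated as rare by
#' default, since private variants are rarer than any finite count.
#'
#' @param qualifying_classes subset of \code{"stop_gain"},
#'   \code{"start_loss"}, \code{"frameshift"}, \code{"canonical_splice"}.
#' @param max_pop_allele_count inclusive upper bound on the population
#'   allele count.
#' @param reference_chromosomes number of reference chromosomes behind
#'   the count; used to convert the bound to a frequency when only an
#'   allele frequency is annotated.
#' @param treat_missing_as_rare logical; is a variant with no population
#'   annotation rare?
#' @return A validated \code{"qualification_rule"} object.
#' @export
qualification_rule <- function(qualifying_classes = c("stop_gain", "start_loss",
                                                      "frameshift",
                                                      "canonical_splice"),
                               max_pop_allele_count = 10L,
                               reference_chromosomes = 280000L,
                               treat_missing_as_rare = TRUE) {
  known <- c("stop_gain", "start_loss", "frameshift", "canonical_splice")
  bad <- setdiff(qualifying_classes, known)
  if (length(bad)) stop("unknown qualifying class(es): ",
                        paste(bad, collapse = ", "))
  if (length(qualifying_classes) == 0L)
    stop("qualifying_classes must be non-empty")
  if (max_pop_allele_count < 0) stop("max_pop_allele_count must be >= 0")
  if (reference_chromosomes <= 0) stop("reference_chromosomes must be > 0")
  structure(list(qualifying_classes = qualifying_classes,
                 max_pop_allele_count = as.integer(max_pop_allele_count),
                 reference_chromosomes = as.integer(reference_chromosomes),
                 treat_missing_as_rare = isTRUE(treat_missing_as_rare)),
            class = "qualification_rule")
}

# Sequence-Ontology term -> class map. splice_region_variant is
# deliberately absent: "canonical" means the two essential splice sites.
.consequence_map <- c(
  stop_gained = "stop_gain",
  start_lost = "start_loss",
  initiator_codon_variant = "start_loss",
  frameshift_variant = "frameshift",
  splice_acceptor_variant = "canonical_splice",
  splice_donor_variant = "canonical_splice")

# when several terms map, the most severe class wins
.class_severity <- c("stop_gain", "frameshift", "canonical_splice",
                     "start_loss")

#' Classify a variant's consequence terms
#'
#' Maps a set of Sequence-Ontology-style consequence terms to a single
#' consequence class. \code{stop_gained} maps to stop-gain;
#' \code{start_lost} and \code{initiator_codon_variant} to start-loss;
#' \code{frameshift_variant} to frameshift; \code{splice_acceptor_variant}
#' and \code{splice_donor_variant} to canonical-splice. All other terms
#' (missense, synonymous, intronic, \code{splice_region_variant}, ...)
#' classify as \code{"other"}. When terms map to several classes the most
#' severe wins, in the fixed order stop_gain > frameshift >
#' canonical_splice > start_loss.
#'
#' @param consequences character vector of consequence terms (one
#'   variant's term set), or a list of such vectors.
#' @return A character scalar (or vector, for list input) in
#'   \code{c("stop_gain","frameshift","canonical_splice","start_loss","other")}.
#' @export
classify_consequence <- function(consequences) {
  if (is.list(consequences))
    return(vapply(consequences, classify_consequence, ""))
  hits <- unique(stats::na.omit(.consequence_map[consequences]))
  if (length(hits) == 0L) return("other")
  .class_severity[min(match(hits, .class_severity))]
}

#' Is a variant rare under a qualification rule?
#'
#' TRUE when the population allele count is at most the rule's bound
#' (inclusive), or the count is missing and the rule treats missing as
#' rare. When only an allele frequency is available the bound is applied
#' as \code{max_pop_allele_count / reference_chromosomes}.
#'
#' @param pop_ac integer vector of population allele counts (NA =
#'   missing).
#' @param rule a \code{\link{qualification_rule}}.
#' @param pop_af optional numeric vector of population allele
#'   frequencies, consulted where \code{pop_ac} is missing.
#' @return Logical vector.
#' @export
is_rare <- function(pop_ac, rule = qualification_rule(), pop_af = NULL) {
  if (any(!is.na(pop_ac) & pop_ac < 0))
    stop("negative population allele count")
  out <- !is.na(pop_ac) & pop_ac <= rule$max_pop_allele_count
  miss <- is.na(pop_ac)
  if (!is.null(pop_af)) {
    max_af <- rule$max_pop_allele_count / rule$reference_chromosomes
    use_af <- miss & !is.na(pop_af)
    out[use_af] <- pop_af[use_af] <= max_af
    miss <- miss & is.na(pop_af)
  }
  out[miss] <- rule$treat_missing_as_rare
  out
}

#' Filter variants to rare deleterious qualifying variants
#'
#' Retains exactly the records whose consequence class is one of the
#' rule's qualifying classes and whose population allele count passes
#' \code{\link{is_rare}}. Input order is preserved and each retained
#' record is labelled with its class.
#'
#' @param variants an \code{annotated_variants} data frame (from
#'   \code{\link{read_vcf}} or built in code with the same columns).
#' @param rule a \code{\link{qualification_rule}}.
#' @return The qualifying subset with an added \code{class} column;
#'   class \code{"qualified_variants"}.
#' @export
qualify_variants <- function(variants, rule = qualification_rule()) {
  cls <- classify_consequence(variants$consequences)
  af <- if ("pop_af" %in% names(variants)) variants$pop_af else NULL
  rare <- is_rare(variants$pop_ac, rule, pop_af = af)
  keep <- cls %in% rule$qualifying_classes & rare
  out <- variants[keep, , drop = FALSE]
  out$class <- cls[keep]
  rownames(out) <- NULL
  attr(out, "n_rejected_class") <- sum(!cls %in% rule$qualifying_classes)
  attr(out, "n_rejected_frequency") <-
    sum(cls %in% rule$qualifying_classes & !rare)
  class(out) <- unique(c("qualified_variants", class(out)))
  out
}

#' Write qualifying variants as a flat TSV
#'
#' One row per (variant, gene): chrom, pos, ref, alt, gene, class,
#' pop_AC and comma-separated carrier sample ids.
#'
#' @param qualified output of \code{\link{qualify_variants}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_qualified_tsv <- function(qualified, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(qualified)), function(i) {
    genes <- qualified$genes[[i]]
    if (length(genes) == 0L) genes <- NA_character_
    data.frame(chrom = qualified$chrom[i], pos = qualified$pos[i],
               ref = qualified$ref[i], alt = qualified$alt[i],
               gene = genes, class = qualified$class[i],
               pop_AC = qualified$pop_ac[i],
               carriers = paste(qualified$carriers[[i]], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       gene = character(0), class = character(0),
                       pop_AC = integer(0), carriers = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
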