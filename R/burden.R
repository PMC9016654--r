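#' Collapse qualifying variants to a gene-level carrier matrix
#'
#' Cell (sample, gene) is TRUE iff the sample carries at least one
#' qualifying variant annotated to that gene; several variants in the
#' same gene still give a single TRUE (carrier status is binary, the
#' standard collapsing-test burden unit). A variant annotated to k genes
#' marks its carriers in all k gene columns.
#'
#' @param qualified a \code{qualified_variants} data frame.
#' @param manifest a \code{\link{sample_manifest}}; every carrier sample
#'   must appear in it.
#' @return Logical matrix, manifest samples x genes (sorted gene
#'   symbols), of class \code{"carrier_matrix"} with attribute
#'   \code{level = "gene"}. With no qualifying variants the full sample
#'   axis is kept and the gene axis is empty.
#' @export
build_carrier_matrix <- function(qualified, manifest) {
  samples <- names(manifest$assignments)
  all_carriers <- unique(unlist(qualified$carriers))
  unknown <- setdiff(all_carriers, samples)
  if (length(unknown))
    stop("carrier sample(s) absent from manifest: ",
         paste(unknown, collapse = ", "))
  genes <- sort(unique(unlist(qualified$genes)))
  m <- matrix(FALSE, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  for (i in seq_len(nrow(qualified))) {
    g <- qualified$genes[[i]]
    s <- qualified$carriers[[i]]
    if (length(g) && length(s)) m[s, g] <- TRUE
  }
  structure(m, level = "gene", class = c("carrier_matrix", "matrix", "array"))
}

#' Collapse a gene-level carrier matrix to pathway level
#'
#' A sample carries a pathway burden iff it carries a qualifying variant
#' in at least one member gene (logical OR over member-gene columns).
#' Member genes with no gene column contribute nothing; pathways with
#' zero represented genes are retained as all-FALSE columns and flagged
#' in the \code{empty_pathways} attribute.
#'
#' @param gene_matrix a gene-level \code{carrier_matrix}.
#' @param collection a \code{\link{gene_set_collection}}.
#' @return Logical matrix samples x pathways of class
#'   \code{"carrier_matrix"}, attribute \code{level = "pathway"} and
#'   \code{empty_pathways} (character vector of unrepresented pathway
#'   ids).
#' @export
collapse_to_pathways <- function(gene_matrix, collection) {
  if (!identical(attr(gene_matrix, "level"), "gene"))
    stop("collapse_to_pathways needs a gene-level carrier matrix")
  ids <- names(collection$sets)
  m <- matrix(FALSE, nrow = nrow(gene_matrix), ncol = length(ids),
              dimnames = list(rownames(gene_matrix), ids))
  empty <- character(0)
  for (j in seq_along(ids)) {
    members <- intersect(collection$sets[[j]], colnames(gene_matrix))
    if (length(members) == 0L) {
      empty <- c(empty, ids[j])
    } else {
      m[, j] <- rowSums(gene_matrix[, members, drop = FALSE]) > 0L
    }
  }
  structure(m, level = "pathway", empty_pathways = empty,
            class = c("carrier_matrix", "matrix", "array"))
}

#' Build a carrier matrix directly from a logical matrix
#'
#' Convenience constructor used by the simulator and by callers that
#' already hold per-sample indicators.
#'
#' @param m logical matrix, samples (rows, named) x features (columns,
#'   named).
#' @param level \code{"gene"} or \code{"pathway"}.
#' @return A \code{carrier_matrix}.
#' @export
as_carrier_matrix <- function(m, level = c("gene", "pathway")) {
  level <- match.arg(level)
  storage.mode(m) <- "logical"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("carrier matrix needs sample row names and feature column names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("carrier matrix axis labels must be unique")
  structure(m, level = level, class = c("carrier_matrix", "matrix", "array"))
}
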