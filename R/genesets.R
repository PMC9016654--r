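#' Read a gene-set collection from a GMT file
#'
#' Standard GMT (MSigDB dialect): one set per line,
#' \code{id<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate member
#' symbols within a set are dropped; sets whose deduplicated size falls
#' outside \code{size_bounds} are dropped and counted; lines with fewer
#' than three fields are skipped and counted.
#'
#' @param path path to the GMT file.
#' @param source collection tag, e.g. \code{"GO"} or \code{"KEGG"}.
#' @param size_bounds length-2 numeric \code{c(min_genes, max_genes)}
#'   applied after deduplication. The default (2, 2000) excludes
#'   singleton sets (which reduce a pathway test to a gene test) and very
#'   large uninformative sets; pass \code{c(1, Inf)} to keep everything.
#' @param alias optional named character vector mapping gene symbols to
#'   replacement symbols, applied before deduplication. Matching is
#'   case-sensitive.
#' @return An object of class \code{"gene_set_collection"}: list with
#'   \code{sets} (named list of member symbol vectors), \code{name},
#'   \code{source} (named character vectors parallel to \code{sets}),
#'   and tallies \code{n_skipped_lines}, \code{n_dropped_size}.
#' @export
read_gmt <- function(path, source = "other", size_bounds = c(2, 2000),
                     alias = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); nms <- character(0)
  n_skip <- 0L; n_drop <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) { n_skip <- n_skip + 1L; next }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!is.null(alias)) {
      hit <- members %in% names(alias)
      members[hit] <- alias[members[hit]]
    }
    members <- unique(members)
    if (length(members) < size_bounds[1] || length(members) > size_bounds[2]) {
      n_drop <- n_drop + 1L; next
    }
    sets[[f[1]]] <- members
    nms[f[1]] <- f[2]
  }
  gene_set_collection(sets, name = nms,
                      source = stats::setNames(rep(source, length(sets)),
                                               names(sets)),
                      n_skipped_lines = n_skip, n_dropped_size = n_drop)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member gene symbols;
#'   pathway ids must be unique, members are deduplicated.
#' @param name,source optional named character vectors (pathway id to
#'   display name / source tag).
#' @param n_skipped_lines,n_dropped_size load tallies.
#' @return A \code{"gene_set_collection"} object.
#' @export
gene_set_collection <- function(sets, name = NULL, source = NULL,
                                n_skipped_lines = 0L, n_dropped_size = 0L) {
  ids <- names(sets)
  if (length(sets) && (is.null(ids) || any(!nzchar(ids))))
    stop("every gene set needs an id")
  if (anyDuplicated(ids))
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(sets, unique)
  if (is.null(name)) name <- stats::setNames(ids, ids)
  if (is.null(source)) source <- stats::setNames(rep("other", length(sets)), ids)
  structure(list(sets = sets, name = name, source = source,
                 n_skipped_lines = as.integer(n_skipped_lines),
                 n_dropped_size = as.integer(n_dropped_size)),
            class = "gene_set_collection")
}

#' Merge gene-set collections
#'
#' @param ... \code{gene_set_collection} objects. Pathway ids must be
#'   disjoint across inputs; a clash is an error.
#' @return The merged \code{gene_set_collection}.
#' @export
merge_collections <- function(...) {
  colls <- list(...)
  ids <- unlist(lapply(colls, function(x) names(x$sets)))
  if (anyDuplicated(ids))
    stop("pathway id clash on merge: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene_set_collection(
    do.call(c, lapply(colls, `[[`, "sets")),
    name = do.call(c, lapply(colls, `[[`, "name")),
    source = do.call(c, lapply(colls, `[[`, "source")),
    n_skipped_lines = sum(vapply(colls, `[[`, 1L, "n_skipped_lines")),
    n_dropped_size = sum(vapply(colls, `[[`, 1L, "n_dropped_size")))
}

#' Reverse index: gene to the sets containing it
#'
#' @param collection a \code{gene_set_collection}.
#' @return Named list, gene symbol to character vector of pathway ids.
#' @export
sets_of_gene <- function(collection) {
  pid <- rep(names(collection$sets),
             vapply(collection$sets, length, 1L))
  split(pid, unlist(collection$sets))
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @method print gene_set_collection
#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- vapply(x$sets, length, 1L)
  cat("gene_set_collection:", length(x$sets), "sets,",
      length(unique(unlist(x$sets))), "distinct genes\n")
  if (length(sz))
    cat("  set sizes: min", min(sz), "median", stats::median(sz),
        "max", max(sz), "\n")
  if (x$n_skipped_lines || x$n_dropped_size)
    cat("  load tallies:", x$n_skipped_lines, "malformed lines skipped,",
        x$n_dropped_size, "sets outside size bounds\n")
  invisible(x)
}
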