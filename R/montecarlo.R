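#' Monte-Carlo case-label permutation test of pathway burden
#'
#' Pools the case cohort with all comparison cohorts and builds an
#' exchangeability null for the pathway statistic (the case carrier
#' count) by repeatedly drawing a uniform random subset of
#' \code{n_case} pseudo-cases without replacement, preserving the cohort
#' sizes exactly. The empirical p-value uses the +1 correction,
#' \code{(n_geq + 1) / (n_perm + 1)}, so it is never exactly zero.
#'
#' All pathways share one pregenerated permutation stream: the null
#' draws are identical across pathways and across worker counts, so the
#' result depends only on \code{(carriers, manifest, n_perm, seed,
#' statistic)}.
#'
#' @param carriers a logical vector over samples (named by sample id),
#'   or a samples x pathways logical matrix (e.g. a pathway-level
#'   \code{carrier_matrix}).
#' @param manifest a \code{\link{sample_manifest}}.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param statistic \code{"carrier_count"} (default; case carrier count,
#'   which under binary carriers induces exactly the hypergeometric
#'   null) or \code{"fisher_p"} (permute the pooled-table one-sided
#'   Fisher p; extreme = smaller).
#' @param workers number of worker processes for splitting pathways;
#'   results are identical for any worker count.
#' @return Data frame with one row per pathway: \code{pathway_id},
#'   \code{observed_stat}, \code{n_perm}, \code{n_geq},
#'   \code{p_empirical}, \code{seed}.
#' @export
mc_pathway_test <- function(carriers, manifest, n_perm = 10000L, seed = 1L,
                            statistic = c("carrier_count", "fisher_p"),
                            workers = 1L) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  C <- .carrier_mat(carriers, manifest)
  N <- nrow(C)
  case_ids <- case_samples(manifest)
  n_case <- length(case_ids)
  if (n_case == 0L || n_case >= N)
    stop("case cohort must be non-empty and smaller than the pooled cohort")

  obs_count <- colSums(C[case_ids, , drop = FALSE])
  n_other <- colSums(C) - obs_count

  set.seed(as.integer(seed))
  perm <- matrix(0L, nrow = n_perm, ncol = n_case)
  for (i in seq_len(n_perm)) perm[i, ] <- sample.int(N, n_case)

  chunks <- .split_cols(ncol(C), workers)
  count_chunk <- function(cols) {
    Ck <- C[, cols, drop = FALSE]
    if (statistic == "carrier_count") {
      ngeq <- integer(length(cols))
      for (i in seq_len(n_perm))
        ngeq <- ngeq + (colSums(Ck[perm[i, ], , drop = FALSE]) >=
                          obs_count[cols])
    } else {
      K <- obs_count[cols] + n_other[cols]
      p_obs <- fisher_exact_p(obs_count[cols], n_case - obs_count[cols],
                              n_other[cols], (N - n_case) - n_other[cols])
      ngeq <- integer(length(cols))
      for (i in seq_len(n_perm)) {
        a <- colSums(Ck[perm[i, ], , drop = FALSE])
        p_perm <- fisher_exact_p(a, n_case - a, K - a, (N - n_case) - (K - a))
        ngeq <- ngeq + (p_perm <= p_obs)
      }
    }
    ngeq
  }
  n_geq <- if (workers > 1L && length(chunks) > 1L) {
    unlist(parallel::mclapply(chunks, count_chunk,
                              mc.cores = workers, mc.set.seed = FALSE))
  } else {
    unlist(lapply(chunks, count_chunk))
  }
  data.frame(pathway_id = colnames(C),
             observed_stat = unname(obs_count),
             n_perm = as.integer(n_perm),
             n_geq = as.integer(unname(n_geq)),
             p_empirical = (unname(n_geq) + 1) / (n_perm + 1),
             seed = as.integer(seed),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact permutation p-value by full enumeration of case labellings
#'
#' Enumerates every possible assignment of the case labels over the
#' pooled cohort and returns the fraction of assignments whose case
#' carrier count is at least the observed one. For a binary carrier
#' statistic this equals the one-sided hypergeometric (pooled-table
#' Fisher) tail exactly; it serves as the small-instance oracle for
#' \code{\link{mc_pathway_test}}.
#'
#' @param carriers logical vector over samples, named by sample id.
#' @param manifest a \code{\link{sample_manifest}}.
#' @return Exact tail probability.
#' @export
exact_permutation_p <- function(carriers, manifest) {
  samples <- names(manifest$assignments)
  if (is.null(names(carriers))) {
    if (length(carriers) != length(samples))
      stop("unnamed carrier vector must match manifest length")
    names(carriers) <- samples
  }
  x <- as.logical(carriers[samples])
  N <- length(x)
  n_case <- length(case_samples(manifest))
  if (choose(N, n_case) > 1e6)
    stop("choose(", N, ", ", n_case, ") exceeds 1e6 assignments; ",
         "use mc_pathway_test instead")
  obs <- sum(x[manifest$assignments[samples] == manifest$case_cohort])
  combos <- utils::combn(N, n_case)
  stats <- colSums(matrix(x[combos], nrow = n_case))
  mean(stats >= obs)
}

.carrier_mat <- function(carriers, manifest) {
  samples <- names(manifest$assignments)
  if (is.matrix(carriers)) {
    if (is.null(rownames(carriers)))
      stop("carrier matrix needs sample row names")
    missing <- setdiff(samples, rownames(carriers))
    if (length(missing))
      stop("manifest sample(s) absent from carrier matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    m <- carriers[samples, , drop = FALSE]
  } else {
    if (is.null(names(carriers))) {
      if (length(carriers) != length(samples))
        stop("unnamed carrier vector must match manifest length")
      names(carriers) <- samples
    }
    m <- matrix(as.logical(carriers[samples]), ncol = 1,
                dimnames = list(samples, "pathway"))
  }
  storage.mode(m) <- "logical"
  m
}

.split_cols <- function(n_col, workers) {
  workers <- max(1L, as.integer(workers))
  if (n_col == 0L) return(list(integer(0)))
  k <- min(workers, n_col)
  if (k == 1L) return(list(seq_len(n_col)))
  unname(split(seq_len(n_col),
               ceiling(seq_len(n_col) / (n_col / k))))
}
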