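#' One-sided (and two-sided) Fisher exact p for 2x2 carrier tables
#'
#' For a table with \code{a} case carriers, \code{b} case non-carriers,
#' \code{c} comparison carriers and \code{d} comparison non-carriers,
#' the one-sided enrichment p-value is the hypergeometric upper tail
#' P(X >= a) conditioned on both margins — the case cohort drawing
#' \code{a + b} samples from \code{a + c} carriers and \code{b + d}
#' non-carriers. Vectorized over tables.
#'
#' @param a,b,c,d non-negative integer vectors (recycled) of 2x2 cell
#'   counts.
#' @param alternative \code{"greater"} (enrichment in cases, default) or
#'   \code{"two_sided"}.
#' @return Numeric vector of exact p-values.
#' @export
fisher_exact_p <- function(a, b, c, d, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  if (alternative == "greater") {
    # P(X >= a) with X ~ Hypergeometric(carriers = a+c, non = b+d, draw = a+b)
    stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  } else {
    vapply(seq_len(n), function(i) {
      stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2,
                                byrow = TRUE))$p.value
    }, 1.0)
  }
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# odds ratio with Haldane-Anscombe 0.5 correction when any cell is zero;
# reporting only — p-values are always exact
.odds_ratio <- function(a, b, c, d) {
  z <- a == 0 | b == 0 | c == 0 | d == 0
  h <- ifelse(z, 0.5, 0)
  ((a + h) * (d + h)) / ((b + h) * (c + h))
}

#' Per-pathway, per-comparison-cohort Fisher enrichment
#'
#' Tests, for every pathway and every comparison cohort, whether case
#' samples are enriched for pathway carriers, using the exact
#' hypergeometric test conditioned on the 2x2 margins. q-values control
#' the FDR across the pathway family within each comparison separately.
#'
#' @param pathway_matrix a pathway-level \code{carrier_matrix} over all
#'   manifest samples.
#' @param manifest a \code{\link{sample_manifest}} with the case cohort
#'   and at least one comparison cohort.
#' @param alternative \code{"greater"} (default) or \code{"two_sided"}.
#' @param fdr_method \code{"BH"} (default), \code{"bonferroni"} or
#'   \code{"none"}.
#' @param pool_comparisons if TRUE, all comparison cohorts are merged
#'   into a single pooled comparison named \code{"pooled"}.
#' @return Data frame with one row per (pathway, comparison): columns
#'   \code{pathway_id}, \code{comparison}, \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{carrier_freq_case}, \code{carrier_freq_comparison},
#'   \code{odds_ratio}, \code{p_fisher}, \code{q_fdr}; sorted by
#'   (comparison, p, pathway_id).
#' @export
fisher_enrichment <- function(pathway_matrix, manifest,
                              alternative = c("greater", "two_sided"),
                              fdr_method = c("BH", "bonferroni", "none"),
                              pool_comparisons = FALSE) {
  alternative <- match.arg(alternative)
  fdr_method <- match.arg(fdr_method)
  samples <- rownames(pathway_matrix)
  if (!setequal(samples, names(manifest$assignments)))
    stop("carrier matrix samples do not match the manifest")
  cohort <- manifest$assignments[samples]
  if (pool_comparisons)
    cohort[cohort != manifest$case_cohort] <- "pooled"
  comparisons <- setdiff(unique(cohort), manifest$case_cohort)
  if (length(comparisons) == 0L) stop("no comparison cohort in manifest")
  if (any(table(cohort) == 0L)) stop("empty cohort")

  case_rows <- cohort == manifest$case_cohort
  n_case <- sum(case_rows)
  case_carriers <- colSums(pathway_matrix[case_rows, , drop = FALSE])
  out <- lapply(comparisons, function(co) {
    rows <- cohort == co
    n_co <- sum(rows)
    cc <- colSums(pathway_matrix[rows, , drop = FALSE])
    a <- case_carriers; b <- n_case - a
    cl <- cc; dl <- n_co - cc
    p <- fisher_exact_p(a, b, cl, dl, alternative)
    data.frame(pathway_id = colnames(pathway_matrix), comparison = co,
               a = a, b = b, c = cl, d = dl,
               carrier_freq_case = a / n_case,
               carrier_freq_comparison = cl / n_co,
               odds_ratio = .odds_ratio(a, b, cl, dl),
               p_fisher = p,
               q_fdr = switch(fdr_method,
                              BH = bh_fdr(p),
                              bonferroni = pmin(1, p * length(p)),
                              none = p),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$comparison, out$p_fisher, out$pathway_id), ]
  rownames(out) <- NULL
  out
}

#' Consensus ranking across comparison cohorts and the Monte-Carlo null
#'
#' A pathway is flagged when it meets the per-group Fisher criterion —
#' \code{q_fdr <= alpha} in all comparison groups
#' (\code{rule = "all_groups"}), or in at least \code{k} of them
#' (\code{rule = "k_of_m"}) — AND its Monte-Carlo permutation p against
#' the pooled comparisons is \code{<= alpha}. Output is ranked by MC p,
#' then the worst (largest) group q, then pathway id as a deterministic
#' tie-break.
#'
#' @param fisher_results output of \code{\link{fisher_enrichment}}.
#' @param mc_results output of \code{\link{mc_pathway_test}}.
#' @param rule \code{"all_groups"} or \code{"k_of_m"}.
#' @param k number of groups required under \code{"k_of_m"}.
#' @param alpha significance level for both criteria (default 0.05).
#' @return Data frame with one row per pathway: \code{pathway_id},
#'   \code{n_groups}, \code{n_groups_sig}, \code{max_q}, \code{mc_p},
#'   \code{fisher_pass}, \code{mc_pass}, \code{flagged}; ranked.
#' @export
consensus_rank <- function(fisher_results, mc_results,
                           rule = c("all_groups", "k_of_m"), k = NULL,
                           alpha = 0.05) {
  rule <- match.arg(rule)
  fu <- sort(unique(fisher_results$pathway_id))
  mu <- sort(unique(mc_results$pathway_id))
  if (!identical(fu, mu))
    stop("Fisher and Monte-Carlo results cover different pathway universes")
  if (rule == "k_of_m" && is.null(k)) stop("rule 'k_of_m' needs k")

  spl <- split(fisher_results, fisher_results$pathway_id)
  agg <- do.call(rbind, lapply(spl, function(df) {
    data.frame(pathway_id = df$pathway_id[1],
               n_groups = nrow(df),
               n_groups_sig = sum(df$q_fdr <= alpha),
               max_q = max(df$q_fdr), stringsAsFactors = FALSE)
  }))
  need <- if (rule == "all_groups") agg$n_groups else pmin(k, agg$n_groups)
  agg$fisher_pass <- agg$n_groups_sig >= need
  mc <- mc_results[match(agg$pathway_id, mc_results$pathway_id), ]
  agg$mc_p <- mc$p_empirical
  agg$mc_pass <- agg$mc_p <= alpha
  agg$flagged <- agg$fisher_pass & agg$mc_pass
  agg <- agg[order(agg$mc_p, agg$max_q, agg$pathway_id), ]
  rownames(agg) <- NULL
  agg
}
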