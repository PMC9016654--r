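# Independent oracles, written directly from the definitions and kept
# free of any package internals.

# one-sided enrichment p for a 2x2 table by explicit hypergeometric
# tail summation: P(X >= a), X = case carriers given both margins
oracle_hyper_tail <- function(a, b, c, d) {
  n <- a + b + c + d
  K <- a + c          # carriers in the pooled cohort
  n_case <- a + b
  lo <- a
  hi <- min(K, n_case)
  if (lo > hi) return(0)
  x <- lo:hi
  sum(exp(lchoose(K, x) + lchoose(n - K, n_case - x) - lchoose(n, n_case)))
}

# vectorized version for exhaustive sweeps
oracle_hyper_tail_vec <- function(a, b, c, d) {
  n <- a + b + c + d
  K <- a + c
  n_case <- a + b
  hi <- pmin(K, n_case)
  L <- pmax(0L, hi - a + 1L)
  idx <- rep.int(seq_along(a), L)
  x <- sequence(L) - 1L + rep.int(a, L)
  terms <- exp(lchoose(K[idx], x) + lchoose(n[idx] - K[idx], n_case[idx] - x) -
                 lchoose(n[idx], n_case[idx]))
  out <- numeric(length(a))
  agg <- rowsum(terms, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} p_(j) * n / j, capped at 1, back in input order
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# direct per-record qualification filter (class map + rarity), written
# independently of the pipeline code
oracle_qualify_keep <- function(consequences, pop_ac, max_ac = 10,
                                missing_rare = TRUE,
                                classes = c("stop_gain", "start_loss",
                                            "frameshift", "canonical_splice")) {
  map <- list(stop_gained = "stop_gain", start_lost = "start_loss",
              initiator_codon_variant = "start_loss",
              frameshift_variant = "frameshift",
              splice_acceptor_variant = "canonical_splice",
              splice_donor_variant = "canonical_splice")
  vapply(seq_along(consequences), function(i) {
    cls <- unique(unlist(map[consequences[[i]]]))
    ok_class <- length(cls) > 0 && any(cls %in% classes)
    ac <- pop_ac[i]
    ok_rare <- if (is.na(ac)) missing_rare else ac <= max_ac
    ok_class && ok_rare
  }, TRUE)
}
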