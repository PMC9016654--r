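test_that("gene-level collapse is a binary carrier indicator", {
  m <- make_manifest(c(CASE = 2L, CTRL = 2L))
  s1 <- names(m$assignments)[1]
  # two qualifying variants in the same gene: still one TRUE cell
  v <- make_variants(list("stop_gained", "frameshift_variant"), c(0L, 0L),
                     genes = list("G1", "G1"),
                     carriers = list(s1, s1))
  q <- qualify_variants(v)
  cm <- build_carrier_matrix(q, m)
  expect_equal(sum(cm), 1L)
  expect_true(cm[s1, "G1"])
  expect_equal(attr(cm, "level"), "gene")

  # a variant annotated to k genes sets k cells
  v2 <- make_variants(list("stop_gained"), 0L,
                      genes = list(c("GA", "GB")), carriers = list(s1))
  cm2 <- build_carrier_matrix(qualify_variants(v2), m)
  expect_equal(sum(cm2), 2L)

  # no qualifying variants: all-false with the full sample axis
  cm3 <- build_carrier_matrix(qualify_variants(make_variants(list(), integer(0))), m)
  expect_equal(dim(cm3), c(4L, 0L))
  expect_equal(rownames(cm3), names(m$assignments))

  # unknown carrier sample is fatal, naming the sample
  v4 <- make_variants(list("stop_gained"), 0L, carriers = list("GHOST"))
  expect_error(build_carrier_matrix(qualify_variants(v4), m), "GHOST")
})

test_that("pathway collapse is the OR over member genes; empty pathways are flagged", {
  m <- make_manifest(c(CASE = 1L, CTRL = 1L))
  s <- names(m$assignments)
  gm <- as_carrier_matrix(matrix(c(FALSE, FALSE, TRUE, FALSE), 2,
                                 dimnames = list(s, c("G1", "G2"))), "gene")
  coll <- gene_set_collection(list(PA = c("G1", "G2"), PB = c("GX", "GY")))
  pm <- collapse_to_pathways(gm, coll)
  expect_true(pm[s[1], "PA"])   # carrier in G2 only -> pathway carrier
  expect_false(any(pm[, "PB"]))
  expect_equal(attr(pm, "empty_pathways"), "PB")
  expect_error(collapse_to_pathways(pm, coll), "gene-level")
})

test_that("pathway collapse equals a brute-force double loop on a random matrix", {
  set.seed(123)
  samples <- sprintf("S%02d", 1:20)
  genes <- sprintf("G%02d", 1:50)
  gm <- as_carrier_matrix(
    matrix(runif(20 * 50) < 0.1, 20, dimnames = list(samples, genes)),
    "gene")
  sets <- lapply(1:15, function(i)
    sample(c(genes, "ABSENT1", "ABSENT2"), sample(2:8, 1)))
  names(sets) <- sprintf("P%02d", 1:15)
  pm <- collapse_to_pathways(gm, gene_set_collection(sets))
  for (s in samples)
    for (p in names(sets)) {
      expected <- FALSE
      for (g in sets[[p]])
        if (g %in% genes && gm[s, g]) expected <- TRUE
      expect_identical(unname(pm[s, p]), expected)
    }
})

test_that("one-sided Fisher p matches hand-derived values and the oracle", {
  # no case carriers: P(X >= 0) = 1
  expect_equal(fisher_exact_p(0, 5, 3, 7), 1.0)
  # 2x2 of all ones: tail mass 5/6 over x in {0,1,2}
  expect_equal(fisher_exact_p(1, 1, 1, 1), 5 / 6, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:200) {
    t <- as.vector(stats::rmultinom(1, sample(4:50, 1), rep(1 / 4, 4)))
    expect_equal(fisher_exact_p(t[1], t[2], t[3], t[4]),
                 oracle_hyper_tail(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
    # and the independent library route
    expect_equal(fisher_exact_p(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE),
                                    alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  expect_equal(fisher_exact_p(3, 1, 1, 5, alternative = "two_sided"),
               stats::fisher.test(matrix(c(3, 1, 1, 5), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_error(fisher_exact_p(-1, 1, 1, 1), "negative")
})

test_that("one-sided p is non-increasing in the case-carrier cell at fixed margins", {
  for (K in 2:6) {
    n_case <- 5; n_ctrl <- 8
    a <- 0:min(K, n_case)
    p <- fisher_exact_p(a, n_case - a, K - a, n_ctrl - (K - a))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("BH q-values match the step-up definition and p.adjust", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.5, 0.5, 0.5)), c(0.5, 0.5, 0.5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("fisher_enrichment conserves cohort margins and is sample-order invariant", {
  set.seed(21)
  m <- make_manifest(c(CASE = 12L, C1 = 15L, C2 = 9L))
  samples <- names(m$assignments)
  pm <- as_carrier_matrix(
    matrix(runif(36 * 6) < 0.25, 36,
           dimnames = list(samples, sprintf("PW%d", 1:6))), "pathway")
  res <- fisher_enrichment(pm, m)
  expect_equal(nrow(res), 12L)   # 6 pathways x 2 comparison cohorts
  expect_true(all(res$a + res$b == 12L))
  for (co in c("C1", "C2"))
    expect_true(all(res$c[res$comparison == co] +
                      res$d[res$comparison == co] == m$sizes[[co]]))
  # q within each comparison family
  for (co in c("C1", "C2")) {
    sub <- res[res$comparison == co, ]
    expect_equal(sub$q_fdr, oracle_bh(sub$p_fisher), tolerance = 1e-12)
  }
  # permuting sample order changes nothing
  perm <- sample(nrow(pm))
  res2 <- fisher_enrichment(as_carrier_matrix(pm[perm, , drop = FALSE],
                                              "pathway"), m)
  expect_equal(res, res2)
  # deterministic sort: (comparison, p, pathway_id)
  expect_false(is.unsorted(order(res$comparison, res$p_fisher,
                                 res$pathway_id)))
  expect_error(fisher_enrichment(pm[1:10, ], m), "match the manifest")
})

test_that("zero-cell odds ratios are finite via the 0.5 correction; p stays exact", {
  m <- make_manifest(c(CASE = 4L, CTRL = 4L))
  pm <- as_carrier_matrix(
    matrix(c(rep(TRUE, 4), rep(FALSE, 4)), 8,
           dimnames = list(names(m$assignments), "PW1")), "pathway")
  res <- fisher_enrichment(pm, m)
  expect_true(is.finite(res$odds_ratio))
  expect_equal(res$p_fisher, oracle_hyper_tail(4, 0, 0, 4), tolerance = 1e-12)
})

test_that("consensus flags require both the per-group and Monte-Carlo criteria", {
  fr <- data.frame(pathway_id = rep(c("PA", "PB", "PC"), each = 2),
                   comparison = rep(c("C1", "C2"), 3),
                   q_fdr = c(0.01, 0.02,    # PA: significant everywhere
                             0.01, 0.02,    # PB: same, but fails MC
                             0.01, 0.50))   # PC: fails one group
  mc <- data.frame(pathway_id = c("PA", "PB", "PC"),
                   p_empirical = c(0.001, 0.30, 0.001))
  cr <- consensus_rank(fr, mc, rule = "all_groups", alpha = 0.05)
  expect_true(cr$flagged[cr$pathway_id == "PA"])
  expect_false(cr$flagged[cr$pathway_id == "PB"])   # fails MC only
  expect_false(cr$flagged[cr$pathway_id == "PC"])
  # k_of_m with k = m reproduces all_groups exactly
  cr2 <- consensus_rank(fr, mc, rule = "k_of_m", k = 2, alpha = 0.05)
  expect_equal(cr$flagged, cr2$flagged)
  # k = 1 admits PC's single significant group
  cr3 <- consensus_rank(fr, mc, rule = "k_of_m", k = 1, alpha = 0.05)
  expect_true(cr3$flagged[cr3$pathway_id == "PC"])
  # ranking: MC p first, then worst q, then id
  expect_equal(cr$pathway_id[1:2], c("PA", "PC"))
  expect_error(consensus_rank(fr[fr$pathway_id != "PA", ], mc),
               "universes")
})
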