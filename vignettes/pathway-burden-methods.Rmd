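---
title: "Rare-variant pathway burden testing with pathburden: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant pathway burden testing with pathburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the method answers

Given one small case cohort (here, children with a post-infectious
hyperinflammatory syndrome) and several larger comparison cohorts of
sequenced exomes/genomes, is the case cohort enriched for carriers of
rare, clearly deleterious variants in particular biological pathways?
Single-gene tests are hopeless at n ≈ 40 for variants with population
frequency below 10 / 280,000; collapsing carriers over pathway gene sets
trades gene-level resolution for power.

The pipeline has four statistical stages, each exposed as a package
function and driven end to end by `run_pipeline()` or the numbered
scripts under `analysis/`.

## 1. Variant qualification

A variant *qualifies* when both hold:

* **Consequence class** — its Sequence-Ontology terms map to one of
  stop-gain (`stop_gained`), start-loss (`start_lost`,
  `initiator_codon_variant`), frameshift (`frameshift_variant`) or
  canonical splice site (`splice_acceptor_variant`,
  `splice_donor_variant`). Missense, synonymous, intronic and
  `splice_region_variant` never qualify: "canonical splicing" is read
  strictly as the two essential splice dinucleotide sites. In-frame
  indels are excluded for the same reason — the class list is
  frameshift indels specifically. When terms map to several classes the
  most severe wins (stop_gain > frameshift > canonical_splice >
  start_loss); the order only affects the reported label, never
  membership in the qualifying set.
* **Population rarity** — gnomAD allele count ≤ 10 (inclusive) against
  a reference of 280,000 chromosomes, i.e. frequency ≤ 3.6 × 10⁻⁵.
  A variant absent from the reference is *rarer* than any observed
  count, so missing annotations count as rare by default
  (`treat_missing_as_rare = TRUE`); when only an allele frequency is
  annotated, the equivalent frequency bound is applied.

No in-silico deleteriousness score is used: the class filter already
restricts to protein-truncating and splice-disrupting alleles, and
score thresholds would add an unstated tunable. No internal-cohort
frequency filter is applied beyond the population one.

## 2. Collapsing to carrier burden

The burden unit is the **binary sample-level carrier indicator**: a
sample either carries ≥ 1 qualifying variant in a gene or it does not;
homozygous, hemizygous and multiply-hit samples count once. Pathway
burden is the OR over member genes. This is standard collapsing-test
practice and matches reporting carrier frequencies per group; a
variant-count statistic would be dominated by the handful of samples
with several qualifying alleles. Pathways with no represented gene are
kept as all-FALSE columns and flagged, so the tested family is stable
across cohorts.

## 3. Per-cohort Fisher enrichment

For pathway *j* and comparison cohort *g*, the 2 × 2 table (a = case
carriers, b = case non-carriers, c = comparison carriers, d =
comparison non-carriers) is tested one-sided for case enrichment with
the exact conditional hypergeometric tail,

  p = P(X ≥ a),  X ~ Hypergeom(a + c carriers, b + d non-carriers, a + b draws),

computed via `phyper` (`fisher_exact_p()`). One-sided "greater" is the
default because the hypothesis is enrichment in cases; a two-sided mode
(via `fisher.test`) exists. Odds ratios get the Haldane–Anscombe 0.5
correction when a cell is zero — for reporting only, never touching the
p-value. FDR is controlled by Benjamini–Hochberg within each
comparison's pathway family (the per-cohort tests answer separate
questions; pooling them into one family would let a large cohort's
signal mask a small one's). `none` and `bonferroni` are available.

## 4. Monte-Carlo label permutation

The validation stage pools the case cohort with **all** comparison
cohorts and asks how extreme the observed case carrier count is when
case labels are assigned at random: each permutation draws n_case
pseudo-cases uniformly without replacement (conditioning on the design
margin), the pathway statistic is recomputed, and

  p = (#\{permutations with statistic ≥ observed\} + 1) / (n_perm + 1).

The +1 correction makes the p-value valid (never 0) at the cost of a
bias of order 1/n_perm. For the binary carrier statistic this null *is*
the hypergeometric null, which gives a sharp cross-check:
`exact_permutation_p()` (full enumeration, small instances) must equal
the pooled-table Fisher tail to 10⁻¹², and the MC estimate must fall
within binomial error of it — both are enforced in the test suite.
An alternative permutation statistic (`statistic = "fisher_p"`) permutes
the pooled-table p itself; with binary carriers it tallies identically.

**Determinism.** All pathways share one permutation stream: the
permutation index matrix is generated once from the seed, then applied
to every pathway column. Results are therefore bitwise-reproducible and
independent of how pathway columns are chunked across workers — the
worker count changes scheduling, never the draws. (A counter-based
per-pathway substream scheme would also work; the shared stream is
simpler and additionally makes pathway p-values comparable under the
same null draws.)

`n_perm` defaults to 10,000: resolution 10⁻⁴, standard error at
p = 0.05 about 0.002. Raise it when tail p-values near a strict
threshold matter.

## 5. Consensus

A pathway is reported when it passes the per-group criterion (q ≤ α in
**all** comparison groups, or ≥ k of m under `k_of_m`) *and* the
Monte-Carlo p vs the pooled comparisons is ≤ α. Ranking is by MC p,
then worst group q, then pathway id — the last purely to make reports
deterministic under ties.

The all-groups rule is deliberately stringent, and one consequence is
worth knowing: a very small comparison cohort bounds what the rule can
ever flag. With 24 comparison samples, even a pathway at 30–45% case
carrier frequency reaches only p ≈ 0.005 against that cohort, which BH
across a 200-pathway family lifts above q = 0.05. In the full-design
synthetic runs the spiked pathways are q < 10⁻⁶ in every ~585-sample
cohort and top the Monte-Carlo ranking, yet the strict rule often flags
none of them because of the 24-sample group alone. The `k_of_m`
relaxation (e.g. 8 of 9) exists for exactly this situation; the
analysis scripts report both.

## The synthetic generator

Real clinical exomes cannot ship with a package, so every stage is
tested against `simulate_cohorts()`, which emulates the statistical
structure the analysis consumes:

* cohort design — default `default_cohorts()`: one 39-sample case
  cohort, one 24-sample comparison cohort, eight comparison cohorts
  totalling 4,682 samples;
* per-gene qualifying-carrier probabilities drawn once from
  Beta(0.5, 200) (mean 0.0025, strongly right-skewed — most genes
  almost never carry a qualifying allele, a few reach percents, which
  matches the shape of rare-LoF carrier rates);
* pathway structure — 200 sets of 20 genes by default. When the
  collection tiles the gene pool, memberships are drawn as a disjoint
  partition: a spiked gene otherwise leaks genuine case enrichment
  into every overlapping "unspiked" pathway, so false-flag rates would
  measure gene sharing rather than test error. Collections larger than
  the gene pool fall back to overlapping sampling;
* spikes — member-gene rates multiplied by a relative risk in case
  samples only, capped at 1 (saturations counted and warned). A single
  multiplicative effect size is the simplest alternative hypothesis
  with a clean interpretation;
* file emission — carrier-gene events materialized as qualifying
  variant records in a VCF 4.2 with SnpEff-style `ANN=` annotations and
  `gnomAD_AC`/`gnomAD_AN` INFO, plus an equal number of decoys that
  must not qualify (rare-but-benign classes, or qualifying classes at
  AC 11–100; the boundary pair AC = 10 / AC = 11 is pinned in every
  fixture), so every round trip exercises both rejection paths; plus
  GMT, manifest TSV and a JSON truth table. Identical seeds give
  byte-identical files.

What it does **not** emulate: linkage disequilibrium, diploid genotype
structure beyond carrier status, site-frequency spectra, relatedness,
ancestry stratification, batch effects between cohorts, or WES/WGS
capture differences. Passing tests therefore demonstrate correctness of
the statistics under exchangeable, independent carriers — not
robustness to population structure, which in real data must be handled
upstream or by stratified designs.

## Numerical and interface choices

* Variant identity is (chrom, pos, ref, alt) after multi-allelic
  splitting; no left-normalization is attempted — inputs are assumed
  normalized by the upstream annotation pipeline.
* Both VEP `CSQ` and SnpEff `ANN` dialects are parsed, with field
  positions taken from the header `Description` line; `auto` picks
  whichever the header defines. Records with unparseable annotation are
  skipped and tallied, never silently dropped.
* gnomAD keys are configurable (`gnomAD_AC`/`gnomAD_AN`, frequency
  fallback) because annotation conventions drift.
* Gene-set size bounds default to (2, 2000): singleton sets collapse
  the pathway test to a gene test, and very large sets are carried by
  their sheer gene count; `c(1, Inf)` restores the raw collection.
* Gene symbols match case-sensitively, with an optional alias map;
  reconciling symbol drift between annotation and GMT releases is the
  user's responsibility.
* Degenerate inputs: a = 0 gives p = 1 by construction; empty cohorts
  are fatal; an all-false pathway has MC p = 1 under any seed.
* Problem sizes in the analysis scripts and validation runs: the full
  design (4,745 samples × 4,000 genes, 200 pathways) is simulated at
  matrix level; the file-based path runs on a scaled cohort (~300
  samples, 400 genes), since a full-design VCF (~10⁵ rows × 4,745
  genotype columns) adds bulk but no statistical content. Monte-Carlo
  validation uses 2,000–10,000 permutations depending on the stage.

## Known limitations

* Carrier-indicator burden ignores allele dosage and multiple hits per
  gene (a variant-count mode exists behind `statistic`/reporting flags
  but is not the default inference path).
* No covariate adjustment, kernel tests or ancestry correction — the
  comparison-cohort consensus is the only defense against cohort-level
  confounding, and it cannot fix shared stratification.
* WGS and WES inputs are consumed as given; no capture harmonization
  is attempted.
* The choice between one- and two-sided testing, and between carrier
  and variant units, is exposed but defaults to one-sided carriers;
  results should be reported with those settings stated.
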