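---
title: "Mining hydroxyproline-rich glycoproteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining hydroxyproline-rich glycoproteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypmine)
```

## The problem

Hydroxyproline-rich glycoproteins (HRGPs) are plant cell-wall proteins in
three families — arabinogalactan proteins (AGPs), extensins (EXTs) and
proline-rich proteins (PRPs). Unlike most gene families they cannot be
collected reliably by BLAST or profile-HMM searches alone, because their
defining features are *compositional* (a strong bias towards proline,
alanine, serine and threonine — the "PAST" residues) and *low-complexity
repeats* (the extensin Ser-Pro~n~ unit, the PRP PPV[X][KC] pentamer,
lysine-rich blocks) rather than conserved domains. `hypmine` implements a
family-specific search over a proteome, plus the downstream
molecular-evolution statistics commonly applied to the resulting gene set:
Nei–Gojobori Ka/Ks, Ks-based duplication dating, duplicate-mode labelling,
expression divergence of paralog pairs, and genomic GC tracks.

## The classifier

Every protein gets a composition profile (counts of P/A/S/T/K; the PAST
fraction (P+A+S+T)/length) and a motif profile (all occurrences of SP3,
SP4, SP5, PPV[X][KC], KKPCPP, and the lysine triplets [X]KK, KKK, K[X]K,
with 0-based half-open coordinates). Ambiguous residues (X, B, Z, U)
count toward length but never toward PAST or K.

The subfamily rules overlap — a protein can satisfy both the EXT and the
EXT-AGP criteria — so the classifier is an ordered, first-match-wins list:

1. **FLA** — fasciclin domain hit (from user-supplied hmmsearch
   `--domtblout`, default accession PF02469, independent E ≤ 1e-5) and
   PAST ≥ 0.10;
2. **EXT-AGP** — PAST ≥ 0.10 and at least one SPn hit;
3. **lysine-rich AGP** — PAST ≥ 0.10 and a lysine-rich region;
4. **AG peptide** — PAST ≥ 0.10 and length ≤ 90 aa;
5. **classical AGP** — PAST ≥ 0.30 and no non-fasciclin ("swapped")
   domain hit; when no domain table is loaded the check cannot run and the
   call carries a `domain-check-skipped` flag instead of silently passing
   or blocking;
6. **SPn-EXT** — at least `min_ext_hits` (default 2) SPn hits of one n;
   the largest n with enough hits names the subfamily;
7. **PRP** — at least one PPV[X][KC] or KKPCPP hit;
8. **NONE** otherwise.

The precedence is forced by the family definitions themselves: proteins
with both SPn motifs and AGP bias are EXT-AGPs (so that rule precedes both
the lysine-rich and extensin rules), and PRPs are the residual Hyp-rich
class that fits neither EXTs nor AGPs, so PRP is last. The order is
nevertheless a `rule_config()` field, logged by the CLI, because other
corpora may warrant a different resolution.

Choices where the literature is loose, all configurable in
`rule_config()`:

* **Thresholds are inclusive** (≥), uniformly, rather than mixing > and ≥.
* **SPn is "exactly n prolines"**: an S followed by four prolines is one
  SP4 hit and no SP3 hit, which keeps the three extensin subfamilies
  disjoint per occurrence; proline runs longer than five after an S count
  as SP5.
* **Extensins need ≥ 2 SPn hits of the same n** by default
  (`ext_same_n = TRUE`); a pooled-n mode exists because descriptions
  differ on whether mixed-n repeats qualify.
* **AG peptides: length ≤ 90** residues (the boundary value is included).
* **The lysine-rich region is operationalized** as ≥ 2 lysine-triplet
  hits starting within a 30-residue window. A single K[X]K occurs by
  chance in most proteins; requiring a cluster reflects what "lysine-rich
  block" means in sequence diagrams of this family. Both numbers are
  configurable and deliberately conservative.
* **PPV[X][KC]**: the fifth position accepts K or C by default; the
  alphabet is a config option because a (K/T) variant also circulates.
* Note that K[X]K, [X]KK and KKK all match inside a KKK run (with X = K);
  hit sets are defined by pattern, not by exclusive partition, and the
  brute-force oracle in the test suite enumerates them the same way.

Signal-peptide and GPI-anchor states are *consumed annotations* (SignalP 4
short format, big-PI text, parsed by documented column/keyword rules);
they are reported in calls and the summary table but never change a
verdict. A gene absent from a table is "not annotated", which is flagged
distinctly from an explicit negative prediction.

`collapse_repetitive()` interprets "repetitive sequences" as exact
amino-acid duplicates, keeps the lexicographically smallest id and reports
every absorbed id; it is optional (a CLI flag) because whether such
duplicates should count in family totals is a corpus-level decision.
`validate_by_homology()` flags calls whose PAST fraction falls in
[0.08, 0.12] as `borderline` — the 10% screening threshold is soft — and
adds `homology-supported` when a user-supplied BLAST table contains a hit
with identity ≥ 30% and E ≤ 1e-5; no call is ever changed.

## Ka/Ks, dating, duplication modes

`ng_kaks()` is the Nei–Gojobori (1986) pathway-counting estimator with
Jukes–Cantor correction. Numerical conventions that matter:

* Per codon position, the synonymous-site fraction is computed over the
  *non-stop* single-base alternatives (a position whose only alternatives
  are stops contributes nothing). This follows the original method; it is
  the main source of small discrepancies against implementations that
  keep stop alternatives in the denominator, and is pinned by an
  independent enumeration oracle in the tests.
* Codons differing at 2–3 positions average Sd/Nd over all minimal
  substitution pathways, excluding pathways through stop codons (all
  pathways are used only if every one is blocked).
* Gap-containing codon columns, ambiguous-base columns and stop-codon
  columns are dropped (the latter with a warning).
* p ≥ 3/4 makes the Jukes–Cantor log undefined: the result is flagged
  `saturated`. Ks = 0 yields `undefined_omega` rather than an infinite
  ratio, so tabular output stays finite.

`divergence_time()` is T = Ks/(2λ) with λ = 9.1 × 10⁻⁹
substitutions/site/year, and flags Ks inside the closed interval
[0.15, 0.3] — the recent whole-genome duplication shared by pear and
apple. `lrt()` implements the site-model likelihood-ratio arithmetic
(2|lnL₇ − lnL₈| against an upper-tail χ² with df = 2 by default); fitting
the site models themselves is out of scope.

`classify_duplication()` labels each positioned gene by priority:
collinear pair ⇒ `wgd_segmental` (the collinearity input does not
distinguish WGD from segmental, so neither do the labels), same-chromosome
homolog at rank distance exactly 1 ⇒ `tandem`, ≤ 10 (configurable) ⇒
`proximal`, any homolog ⇒ `dispersed`, else `singleton`. Gene ranks are a
dense 0-based order per chromosome sorted by start with ties broken by
gene id, so the labels are deterministic.

## Expression divergence

Expression conservation of a gene pair is the sample Pearson correlation
of their RPKM vectors across shared libraries (≥ 3 required); divergence
is 1 − EC, in [0, 2]. Zero-variance vectors give an `undefined` status
rather than NaN. `divergence_distributions()` compares the duplicated-pair
divergences against a null of unordered random pairs drawn uniformly
without replacement from the HRGP id set (seeded; self-pairs excluded),
and optionally against a user-supplied control pair set. The comparison
test is the two-sided Wilcoxon rank-sum (normal approximation): the choice
is ours, since divergence distributions are bounded and skewed, and it is
reported as such.

Heatmap display uses v → log2(v + 1) per cell followed by an affine map
of each row's [min, max] onto [−bound, +bound] (default 3; 4.55 matches a
wider published display range); constant rows map to zero. A clipped
row-z-score mode is offered as an alternative. `ddct()` is the standard
2^−ΔΔCt relative-expression formula.

## GC windows

`gc_windows()` tiles each chromosome with non-overlapping windows from
position 1 (default 10 kb, the usual display resolution; the final
partial window is emitted), computing (G+C)/(A+C+G+T) with N and other
ambiguity codes excluded from numerator and denominator; soft-masked
lowercase counts normally. The base-weighted mean of the window values
therefore reproduces the whole-chromosome GC exactly, which the tests
assert to 1e-12. No "GC-rich" significance threshold is imposed — only
the track is produced.

## The synthetic-data generators

The test suite and acceptance script run entirely on seeded generators
with known truth:

* `generate_proteome()` draws backgrounds from an alphabet *excluding*
  S, P, K, V and C, so no SPn, PPV, KKPCPP or lysine motif can arise by
  chance; planted motifs are the only motifs present and negatives are
  unambiguous. PAST content comes from exact counts of A/T residues.
  Archetype bands keep a margin from every threshold: AG peptides
  60–80 aa at 38–45% PAST; classical AGPs 200–400 aa at 38–45%;
  lysine-rich AGPs and EXT-AGPs at 16–24% PAST with planted KKK clusters
  or SPPP pairs; SPn-EXTs 350–450 aa at ~1% background PAST with three
  planted runs; PRPs at ~2% with two planted PPVAK; FLAs come with a
  matching synthetic fasciclin domain table. This is deliberately *not*
  a realistic proteome: real sequences have natural residue frequencies,
  borderline PAST values, chimeric domains and soft motif boundaries, so
  100% recovery here demonstrates rule correctness, not real-data
  sensitivity or specificity.
* `generate_expression()` draws each pair from a bivariate normal with
  correlation ρ on the log scale and exponentiates (log-normal marginals:
  non-negative and right-skewed like RNA-seq abundances). Pearson
  correlation on the exponentiated scale is attenuated to
  (e^ρ − 1)/(e − 1) for unit log-variance, which the tests use as the
  expected mean EC; mean divergence remains strictly monotone in ρ.
* `generate_cds_pair()` samples a stop-free ancestor (excluding ATG and
  TGG, which admit no synonymous single-base change) and applies exact
  numbers of synonymous and nonsynonymous single-base edits to distinct
  codons, never creating stops — giving pure-Ka and pure-Ks truth cases.

Problem sizes in the checked properties — 100 proteins per archetype plus
400 negatives for recovery, 1,000 random sequences against the
brute-force motif oracle, 200 random codon pairs of ≤ 30 codons against
the Ka/Ks enumeration oracle at 1e-10, and 10,000 expression pairs per ρ
level — were chosen to make the statistical assertions stable at
single-CPU scale.

## Known limitations

* The classifier is rule-faithful, not learned: proteins near the PAST
  thresholds or with unusual motif spacing will follow whichever side of
  the configured boundary they fall on (the `borderline` flag exists for
  exactly this).
* The "no swapped domains" condition for classical AGPs is only
  enforceable when a domain table is supplied.
* NG-method Ka/Ks ignores transition/transversion bias and codon usage;
  saturated pairs (p ≥ 3/4) are flagged, not estimated.
* Duplicate-mode labels inherit whatever the upstream homology and
  collinearity inputs decided; the package classifies, it does not detect
  collinearity.
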