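---
title: "Detecting tri-nucleotide repeats and classifying homo-amino-acid tract encodings"
author: "tnrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tri-nucleotide repeats and classifying homo-amino-acid tract encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnrscan)
```

## The scientific problem

Tri-nucleotide repeats (TNRs) — tandem DNA repeats with a 3-nt unit — are
the mutational substrate of a well-known class of expansion diseases, the
poly-glutamine (poly-Q) disorders foremost among them. In coding sequence a
TNR translates into a homo-amino-acid (homo-AA) tract, but the converse is
not true: because the genetic code is redundant, a homo-AA tract can also
be *variant-encoded* by a mixture of synonymous codons, which is far less
prone to replication-slippage length changes. Separating homo-AA tracts
into TNR-encoded and variant-encoded classes, and asking how the two
classes differ — in residue composition, tract length, functional (GO)
associations, interaction degree and sequence conservation — is the
analysis this package implements, end to end, together with a fully seeded
synthetic data generator so that every stage can be validated against
known ground truth.

## Repeat detection and scoring

Tracts are scored by a global *wraparound* alignment of a candidate
substring against indefinite repetition of its leading unit: +2 per
matching nucleotide, −7 per substitution, −7 per inserted or deleted
nucleotide, with tracts reported when the score reaches 40 and the unit
length (period) is at most 3. Two consequences of these weights anchor the
analysis:

* the shortest reportable mismatch-free tract is 40/2 = **20 nt**
  (6⅔ units of a 3-mer);
* one substitution costs as much as 3.5 matched nucleotides gain, so
  reported tracts are strongly biased toward purity.

Detection is an exact maximal-scoring search, not a probabilistic
heuristic: every (start, end, period) candidate reaching the threshold is
enumerated, and a greedy selection keeps maximal non-overlapping tracts,
ranking by score, then length, then start, then the lexicographically
smallest canonical unit (the minimal rotation, used to pool phase-shifted
forms such as CAG/AGC/GCA). Period-1 and period-2 tracts are detected and
then discarded by `filter_period3()`, which also removes period-3
disguises of lower-period repeats (a poly-A tract read as unit AAA, a
(CA)n tract read as CAC) by re-scoring each tract under all 1-mer and
2-mer units.

For efficiency the enumeration is restricted to windows seeded by lag-*p*
self-match runs of length ≥ 3, merged within 50 nt and padded. This is
exact for every tract containing a pure stretch of at least *p* + 3
nucleotides (6 nt for period 3). A score-qualifying tract in which *every*
matched segment is 5 nt or shorter would evade the seeds; such tracts
require an adversarial arrangement of periodic errors (e.g. a substitution
every sixth base sustained for ≥ 80 nt) and do not arise in genomic or
simulated data at any observable rate. The tests compare the scanner
against an unrestricted exhaustive enumeration on hundreds of random
sequences; the two have never disagreed.

Scanning is plus-strand only: a CAG tract and its reverse-complement CTG
tract are distinct records, as they are in the per-unit frequency
analyses. N bases score as mismatches, never match, and cannot begin or
end a tract.

## The order-2 Markov background

The null model for repeat-unit frequencies is an order-2 Markov chain over
nucleotides: `fit_markov2()` tallies every overlapping (dinucleotide,
next-base) triple (N-containing windows skipped, no wrap across sequence
boundaries), and expected trinucleotide probabilities are
P(abc) = P(ab)·P(c|ab), renormalised over the unit support. The observed
unit distribution of the filtered tracts is compared to this background
with a Pearson chi-squared test; categories with expected count below 5
are pooled beforehand so the asymptotic reference distribution is valid,
and df = (categories after pooling) − 1. Per-unit deviations are reported
as log2(observed frequency / expected probability) — log2 is the
conventional scale for such ratio displays and a `log_base` argument
exposes the choice. Units observed zero times are flagged absent rather
than mapped to −Inf, and a unit with zero background probability receives
an expected-probability floor of 1/(10·total) so the statistics stay
finite. The background is fitted from the whole genome including repeat
tracts, matching the whole-genome convention of the original analysis;
masking is the caller's choice by scanning first and excising tracts.

## Gene regions and tract localization

`load_annotation()` keeps exactly one splice variant per gene — by default
the variant with the longest total CDS, or the first listed
(`variant_rule = "first_listed"`, the convention for annotations without
canonical-variant information). Genomic positions are classified into
mutually exclusive regions with the precedence exonic (coding) > 5′ UTR >
3′ UTR > intron > upstream > intergenic; the upstream window is 1000 nt
(configurable), a common promoter-proxy convention. A tract is assigned
the class holding the majority of its nucleotides, with ties broken by the
same precedence. The majority vote is taken over the *exclusive* position
classification — a CDS base that also lies in a neighbouring gene's
upstream window counts only as exonic — otherwise overlapping windows of
adjacent genes double-count and can outvote a gene's own features.

## Homo-AA tracts and encoding classification

`find_homoaa_runs()` reports maximal runs of one standard amino acid of
length ≥ 7 residues (X, ambiguity codes and selenocysteine break runs). A
run is **TNR-encoded** when at least 7 consecutive residues of the tract
are encoded by the same codon, **variant-encoded** otherwise; the
same-codon run is counted strictly within the tract's codon slice, so
codons outside the run never extend it. Both thresholds are exposed in
`homoaa_params()`; raising the same-codon threshold can only move tracts
from TNR to variant, never the reverse (a monotonicity the tests assert).
Proteins whose recorded CDS does not translate to the protein sequence are
dropped with a warning rather than silently mis-mapped.

Per-tract classification is primary. The per-protein sets are a derived
view: a protein joins the TNR-encoded set if *any* of its tracts is
TNR-encoded and the variant set if any is variant-encoded, so the two sets
overlap and their sizes may sum to more than the union — the arithmetic
the published per-species protein counts display.

`map_tract_to_genome()` converts a residue span to its CDS nucleotide span
(3 nt per residue) and walks the spliced CDS segments in transcription
order, emitting forward-coordinate intervals split at introns; for
minus-strand genes transcription runs from high to low coordinates and the
intervals are normalised afterwards. The invariant — extracting the
intervals, reverse-complementing when on the minus strand, and translating
reproduces the tract's residues exactly — is asserted for every tract in
the test suite, including intron-split tracts.

## The statistical battery

* **Composition** (`composition_analysis`): for each residue, trials are
  that residue's tracts, successes its TNR-encoded tracts, and the null
  success probability p0 is the proportion of TNR-encoded homo-AA
  *proteins* among all homo-AA proteins. Trials are tract counts while p0
  is a protein-level proportion; this unit mismatch is kept deliberately
  because it is how the quantity is defined in the source analysis. The
  test is the exact two-tailed binomial under the minimum-likelihood rule
  (the p-value sums the probabilities of all outcomes no more likely than
  the observed one) — the standard exact convention for "two-tailed". The
  per-residue effect display is log2 of the residue's share among
  TNR-encoded tracts over its share among variant-encoded tracts.
* **Length** (`length_analysis`): per residue, TNR- vs variant-encoded
  tract lengths are compared with the Mann-Whitney U test. The exact
  permutation null of the rank-sum statistic (midranks for ties) is
  enumerated by dynamic programming whenever n1·n2 ≤ 400; larger samples
  use the tie-corrected normal approximation with continuity correction.
  The two-sided exact p is the probability of a U at least as far from
  its null mean as observed. Means and standard errors per class
  accompany the test.
* **PPI degree** (`ppi_degree_comparison`): degree is the number of
  distinct partners in an undirected, de-duplicated pair list; proteins
  absent from the list count as degree 0. Classes are compared with the
  same Mann-Whitney machinery (the original analysis names no test for
  this comparison; Mann-Whitney keeps the battery consistent).
* **Conservation** (`tract_conservation_comparison`): the per-tract
  metric is the mean per-base score over the tract's genomic loci — the
  natural summary where the source leaves the segmentation unspecified.
  Bases missing from the score track are excluded from the mean, not
  treated as zero; tracts with no covered base are excluded from the test
  with a warning.

No multiple-testing correction is applied across the 20 residues; the
per-residue significance calls are raw p < α (α = 0.05 by default), as in
the figure this reproduces.

One calibration subtlety is worth knowing: because p0 is estimated from
the same tract pool that supplies each residue's success count, the
composition test is conservative when one residue dominates the pool (its
own successes drag p0 toward itself). With all 20 residues contributing —
the situation on a real proteome — the coupling is negligible and the
test's null rejection rate sits just below the nominal α, as an exact
discrete test should.

## GO over-representation

The ontology is read from OBO 1.2, keeping only is_a and
`relationship: part_of` edges and discarding obsolete terms — has_part and
regulates edges are excluded because propagating over them produces false
positives. Gene annotations are propagated through the reflexive
transitive closure (igraph handles reachability; a cycle over retained
edges is a hard error). Each term annotated to at least one background
gene is tested with the one-sided (greater) Fisher exact test on the 2×2
study/background table; genes without annotations stay in the margins as
"without term". The reported E-value is the Bonferroni-scaled p-value,
p × (number of terms tested), *not* capped at 1 — matching E-value
semantics in the published tables — with a `cap_evalue` flag for the
capped convention. Backgrounds are arbitrary ID sets, so the same study
set can be tested against the variant-encoded set, the full homo-AA set,
or the whole proteome.

## The synthetic data generator

`simulation_config()` + `simulate_dataset()` emit every input the
pipeline consumes — genome FASTA, GFF3, CDS and protein FASTA,
protein-gene map, OBO ontology, association/PPI TSVs, bedGraph
conservation — plus truth tables for every planted feature. One master
seed fans out to fixed per-stage seeds, so a configuration determines
every output byte; the tests assert byte-identical regeneration.

Default study conditions (chosen once; all configurable):

* genome: 600 kb, single chromosome, order-2 Markov background (uniform
  by default, any conditional table accepted), 400 genes on both strands,
  each with a 5′ UTR, two CDS exons split at an arbitrary nucleotide, one
  intron and a 3′ UTR;
* planted DNA tracts: 12 pure-to-lightly-mismatched tracts covering all
  six region classes; the repeat phase is broken two bases deep at both
  boundaries so planted loci are score-maximal and recovered exactly;
  non-genic tracts live in a dedicated genome tail so no planted
  intergenic tract can fall into an upstream window;
* homo-AA runs: ~430 runs over residues Q, A, E, N, S, P. Poly-Q carries
  the planted signal of interest: θ_Q = 0.7 of runs TNR-encoded with mean
  length 13 versus 8 for variant-encoded (the qualitative headline this
  battery must recover); other residues sit at θ 0.1–0.25 with equal or
  near-equal length means. Run lengths are 7-shifted geometric so the
  ≥ 7-residue precondition always holds. Variant runs are built by
  constrained codon choice capping any same-codon sub-run at 6 — one
  below the classification threshold — so class labels are unambiguous;
  ~15 % of carrier proteins hold two runs (real homo-AA proteomes average
  ~1.1–1.2 tracts per protein), which keeps the protein-level p0 close to
  the per-tract TNR fraction and yields the overlapping protein sets the
  published counts imply;
* ontology: 60-term DAG over 4 levels with is_a/part_of edges and a
  single root; one deep term is assigned to TNR-run-carrying genes at
  odds 5 relative to other genes (base rate 0.15), all other terms
  independently of repeat status;
* PPI: Poisson(4) degrees wired by stub matching, class-blind; and a
  conservation track of per-base N(0.8, 0.1) scores clipped to [0, 1]
  covering the gene bodies, also class-blind — for both, the realistic
  condition is *no* class difference, which is what the source reports.

What the generator does **not** emulate: phylogenetically realistic
conservation, PPI network topology beyond the degree distribution,
species-specific codon usage, overlapping genes, alternative splice
variants in the emitted GFF3 (the variant-selection rule is tested on a
hand-built annotation instead). Passing tests therefore demonstrate the
correctness of the machinery and the recoverability of planted effects,
not that any real genome shows those effects.

## Numerical and design choices

* Coordinates: tract tables and `genomic_loci` strings are 0-based
  half-open (BED-like); GFF3 output is 1-based inclusive; gene models are
  held internally as `GRanges`.
* Scanner ties among equal-scoring overlapping candidates: longer tract,
  then smaller start, then smaller canonical unit — a declared convention
  where the source is silent.
* The Mann-Whitney exact/normal switch at n1·n2 = 400 is a declared
  convention; the exact-mode DP over doubled midranks is O(n1·Σranks) and
  its subset counts stay below 2^53 for the sample sizes the switch
  admits.
* Degenerate inputs: empty sequences score 0 and scan to empty tables;
  single-category chi-squared support, empty Mann-Whitney samples and a
  study set not contained in its background are errors; a residue present
  in only one encoding class is reported with an NA p-value.
* Problem sizes in the test suite (scaled to keep the full run in
  minutes): oracle equivalence on 100 random 300-nt sequences plus 30
  120-nt sequences against a slower fully independent oracle; calibration
  at 1000 replicates per test; planted-effect recovery over 20 seeded
  600-kb generator runs; enrichment recovery over 10 (odds 5) and 20
  (odds 1) seeded runs.

## Known limitations

The scanner's detection guarantee excludes the adversarial low-purity
patterns described above; periods > 3 (general microsatellites and
minisatellites) are out of scope, as is repeat masking. Reverse-complement
unit classes are not merged during scanning — `unit_frequency_profile()`
exposes merging as a flag (default off) since the convention in the
original per-unit figure is not stated. The composition test inherits the
tract/protein unit mismatch discussed above; a per-protein reading is
available by building the 2-level tables yourself from the per-protein
sets. E-values are uncapped by default; pass `cap_evalue = TRUE` for the
capped convention.
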