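# tnrscan

Cross-species analysis of tri-nucleotide repeats (TNRs) and the
homo-amino-acid (homo-AA) tracts they encode.

Tandem DNA repeats with a 3-nt unit are the substrate of the repeat
expansion diseases — Huntington's disease being the canonical coding-region
example — and in coding sequence they translate into homo-AA tracts such as
poly-glutamine. Because the genetic code is redundant, a homo-AA tract need
not be repeat-encoded: synonymous codon mixtures ("variant encoding")
produce the same protein with far lower slippage-driven length
instability. This package implements the full analysis that separates the
two encoding classes and compares them:

* **Repeat scanning** — exact maximal-scoring detection of tandem repeat
  tracts of period ≤ 3 under a wraparound alignment score (+2 per match,
  −7 per mismatch, −7 per indel, reporting threshold 40, so the shortest
  reportable pure tract is 20 nt), with period-1/2 filtering and canonical
  (minimal-rotation) unit reporting.
* **Background comparison** — an order-2 Markov nucleotide background with
  expected trinucleotide frequencies, chi-squared goodness-of-fit of the
  observed unit distribution, and per-unit log2 observed/expected ratios.
* **Localization** — one splice variant per gene from GFF3, mutually
  exclusive region classes (exonic > 5′UTR > 3′UTR > intron > upstream >
  intergenic), majority-overlap tract assignment.
* **Encoding classification** — homo-AA runs of ≥ 7 residues; a tract is
  TNR-encoded iff ≥ 7 consecutive residues use one identical codon;
  codon-level reverse mapping of tracts to genomic loci across introns and
  both strands.
* **Statistics** — exact two-tailed binomial composition test per residue
  (successes = TNR-encoded tracts, null probability = TNR-encoded share of
  homo-AA proteins), Mann-Whitney length comparisons (exact permutation
  null with ties for n1·n2 ≤ 400), interaction-degree and per-base
  conservation comparisons.
* **GO over-representation** — OBO parsing (is_a/part_of only),
  transitive-closure annotation propagation, one-sided Fisher exact tests
  against arbitrary backgrounds, Bonferroni E-values.
* **Synthetic data** — a fully seeded generator for every input (genome,
  gene models, proteome, ontology, interactions, conservation) with truth
  tables, so each stage is testable against known ground truth.

## A worked example

Generate a small synthetic study and run the pipeline end to end:

```r
library(tnrscan)

cfg <- pipeline_config(sim = simulation_config(seed = 11))
report <- run_pipeline(cfg, "tnr_out", quiet = TRUE)
report
```

The default study conditions are a 600-kb genome, 400 genes, 12 planted
DNA tracts across all region classes, and ~430 planted homo-AA runs with
poly-Q planted at θ = 0.7 TNR-encoded and longer when TNR-encoded (mean
13 vs 8 residues). The report prints:

```
== Tandem repeat / homo-AA tract study report ==
seed 11, alpha 0.05

DNA tracts: 189 scanned, 188 after period-3 filtering
region classes:
  exonic     178
  utr5       1
  utr3       1
  intron     2
  upstream   1
  intergenic 5

unit distribution vs background: chi-sq 347.8 (df 29), p 2.52e-56

homo-AA proteins: 158 TNR-encoded + 234 variant-encoded (union 368)

composition: 6/6 residues significant at alpha: A(-1.08) E(-1.05)
             N(-0.92) P(-3.58) Q(+2.29) S(-2.03)
length: 1 residues significant: Q(+0.67)

PPI degree comparison: p = 0.353
conservation comparison: p = 0.0231

top enriched terms (study = TNR-encoded proteins):
  GO:0000060  E=4.8e-11  (71/158 study, 96/368 bg)  synthetic term 60
  ...
```

Reading it: the planted DNA tracts are recovered in their planted region
classes (the other exonic tracts are the DNA footprints of TNR-encoded
homo-AA runs, and one mismatched planted tract is a filtered period-2
call). Glutamine is the only residue over-represented among TNR-encoded
tracts (log2 ratio +2.29, exact binomial p = 5.4e-16) and the only residue
whose TNR-encoded tracts are significantly longer (13.4 vs 8.4 residues,
Mann-Whitney p = 1.7e-07) — the planted signal, recovered. The other
residues' negative composition ratios reflect the protein-level null
proportion exceeding their per-tract rates, a property of the test's
definition discussed in the vignette. PPI degrees and conservation are
generated class-blind, so any flag there is a type-I event (the
conservation p of 0.023 on this seed is one; the calibration tests bound
the rate). The GO term planted at odds 5 in repeat-carrying genes ranks
first by E-value, eleven orders of magnitude clear of the next term.

Individual stages are plain functions: `scan_tnr()`, `filter_period3()`,
`fit_markov2()`, `unit_frequency_profile()`, `load_annotation()`,
`localize_tracts()`, `scan_proteome()`, `build_protein_sets()`,
`composition_analysis()`, `length_analysis()`, `ppi_degree_comparison()`,
`tract_conservation_comparison()`, `parse_obo()`,
`propagate_annotations()`, `fisher_overrepresentation()`. A thin
command-line wrapper with the same stages as subcommands is installed at
`inst/scripts/tnrscan`.

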