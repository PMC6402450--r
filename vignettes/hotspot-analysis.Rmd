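---
title: "Detecting somatic point-mutation hot spots in hypermutated tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic point-mutation hot spots in hypermutated tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

## The problem

Tumors with defective DNA mismatch repair (microsatellite-unstable, MSI)
accumulate an order of magnitude more somatic point mutations than
mismatch-repair-proficient tumors. That burden makes the classical driver
signal — recurrence of a gene across patients — nearly useless on its own:
with hundreds of somatic SNVs per exome, many genes are hit repeatedly by
chance. Positional recurrence is far more specific. Activating oncogenic
mutations concentrate in one or two codons (the classic example being a
valine-to-glutamate change at codon 600 of a kinase mutated in a third of MSI
colorectal tumors), so a cluster of protein-altering mutations in the same or
adjacent codons across patients is a strong selection signal even in a
hypermutated background.

`hotspotr` implements this analysis end to end for a two-stage
discovery/validation cohort design:

1. filter raw per-tumor SNV call sets to high-confidence somatic coding
   territory;
2. annotate each SNV at codon level against canonical-transcript CDS models;
3. cluster non-synonymous and splice-site mutations into hot spots;
4. report per-hot-spot cohort frequencies;
5. test whether the exome-wide hot-spot count exceeds what burden and
   mutational spectrum alone would produce, by a stratified permutation null.

A synthetic-cohort generator produces the full input bundle (reference,
gene models, capture regions, tumor calls with planted hot spots, a control
panel), so the whole path is exercisable and testable without any external
or controlled-access data.

## Filtering model

Calls enter as one row per (sample, variant) with read depth and alt-read
counts. Four pure predicates are applied, in a canonical order only for
reporting purposes (the retained set is order-independent):

* **Quality**: depth ≥ 21 reads and variant allele fraction ≥ 20%, both
  bounds inclusive. The fraction test is computed in integer arithmetic
  (`alt_reads * 10000 >= depth * 2000` at the default), so 6 of 30 reads —
  exactly 20% — is retained without floating-point surprises.
* **Indel removal**: only single-base substitutions in A/C/G/T proceed; the
  analysis targets point mutations, and the indel-rich microsatellite signal
  is a separate problem.
* **Capture restriction**: genome- and exome-derived call sets are unified
  on the intervals targeted by the exome enrichment kit. Regions live as a
  merged `GRanges` (1-based closed) in memory and as BED (0-based half-open)
  on disk; the conversion is pinned by tests (`[100, 200)` on disk covers
  1-based 101..200).
* **Germline exclusion**: a call present in the matched normal is removed,
  as is any call whose control-panel allele frequency is ≥ 5 × 10⁻⁵ (the
  retention rule is a strict `<`, so a variant exactly at the threshold is
  excluded). The panel is treated as opaque tabular input.

Every stage reports removed/remaining counts, and the counts reconcile
exactly with input minus output — an invariant asserted on every synthetic
run in the test suite.

## Consequence annotation

Gene models are canonical transcripts: ordered, non-overlapping CDS
intervals on one strand, total length divisible by 3 (violations are
rejected by name at load). Codon numbering follows translation order, so for
minus-strand genes codon 1 spans the highest genomic coordinates. A coding
SNV is annotated by substituting the strand-oriented alternate base at its
codon offset and translating with the standard genetic code:

* same amino acid → `synonymous` (this includes a stop codon mutating to a
  different stop);
* new stop codon → `nonsense`;
* any other protein change, including stop-loss → `missense`.

Positions in the first or last two *intronic* bases flanking a CDS exon are
`splice_site`. Only CDS exon boundaries are considered (UTR structure is not
modeled), so a single-exon gene has no splice flanks; flanks outside the
gene's outermost CDS ends are plain noncoding. Broad classes follow the
standard three-way scheme: nonsilent (missense, nonsense, splice site),
silent (synonymous), noncoding.

A variant overlapping several gene models is annotated once per model; each
(variant, gene) pair is an independent annotated mutation. Variant
coordinates are 1-based throughout, matching how positions are printed in
cancer-genomics reports.

Separately from the protein-level call, every SNV gets one of 18 mutation
types: `A>C, A>G, A>T, T>A, T>C, T>G` plus the six C/G-source substitutions
split by CpG context. CpG status is decided on the reference plus strand — a
C immediately followed by G, or a G immediately preceded by C — regardless
of gene strand, and an N neighbor means "not at CpG". The strand-symmetric
six-class spectrum (C:G>T:A and friends) is derived from the same labels;
MSI tumors are dominated by C:G>T:A, reflecting deamination of methylated
cytosine.

## Hot-spot definition and clustering

A hot spot is a cluster of qualifying mutations (missense, nonsense or
splice site) located in the same codon, in two adjacent codons, or in the
two intronic bases flanking one exon–intron boundary, carried by at least
two distinct samples. Clustering is the maximal connected component of the
"|Δcodon| ≤ 1" relation within a gene. This makes the rule deterministic and
oracle-checkable, and it naturally merges mixtures of same-codon and
adjacent-codon recurrences (e.g. five distinct substitutions across codons
545–546 become one reported hot spot). A chain across codons k, k+1, k+2
therefore also merges; the reported `codon_min`/`codon_max` span makes this
visible. Splice-flank clusters are keyed by (gene, boundary), so mutations
on both intronic sides of the same boundary count as one hot spot — the
boundary, not the side, is the recurrent element.

The test suite proves the implementation identical to an independent
brute-force oracle (all pairwise links, `igraph` connected components) on
1,000 random inputs, along with monotonicity: adding a mutation never
removes a hot spot, removing one never creates one.

Two-stage detection mirrors the cohort design: hot spots are detected in
the discovery cohort, validation mutations are then assigned to the
detected spans, and clusters reaching the threshold only with validation
data are flagged `validation_emergent`. Gene-level candidate lists drop
genes whose nonsilent mutations occur in fewer than three distinct tumors.
Frequencies are reported per cohort and combined, as percentages rounded
half-up to one decimal (half-up, not banker's rounding: 10 of 36 prints
27.8). Externally computed gene rankings can be joined to the report but
are never computed here.

## The permutation null

The headline statistic asks: does the exome-wide count of hot spots exceed
what this cohort's mutation burden and spectrum would generate by chance?
The null is built by redistribution:

* Mutations keep their sample labels and their 18-way types.
* Each mutation is placed independently and uniformly on a capture site
  eligible for its own type — same plus-strand source base and CpG status.
  The stated procedure is redistribution "to the capture regions";
  conditioning on base and context is this package's design choice, because
  an unconditioned placement would make the 18-type stratification
  pointless and would misrepresent the CpG-concentrated spectrum (CpG sites
  are a small minority of capture bases but carry most C:G>T:A mutations).
  The choice is exposed through the site index rather than hard-coded deep
  in the loop.
* Placement is with replacement: two mutations may land on the same site.
  That collision is exactly the event whose frequency the null measures.
* After each round the hot-spot count is recomputed under the null
  criterion: at least two *non-synonymous mutations* (not two samples) in
  the same or adjacent codons, splice-flank clusters excluded. The observed
  statistic fed to the test uses the identical criterion, for
  comparability; both thresholds and the mutation-vs-sample choice are
  configuration.

With R rounds (default 100,000) and `b_ge`/`b_le` the number of null counts
at or above / at or below the observed, the two-sided empirical p-value is
the add-one form `p = min(1, 2·min(b_ge+1, b_le+1)/(R+1))`. It can never be
zero; an observed count beating every one of 100,000 null counts reports
2/100,001 ≈ 2 × 10⁻⁵.

For speed, the rounds run on a precomputed table mapping every (capture
site, alternate base) to the codon-cluster code of its consequence, so a
round is a stratified draw plus a sort — about 100,000 rounds per minute at
200 mutations on one CPU. The slow route (re-place, re-annotate, re-count)
remains the reference: both consume the RNG identically and the test suite
asserts bit-identical null counts round-for-round. Determinism is part of
the result contract: the seed is recorded and identical seeds give
identical null vectors.

Because the cluster statistic is heavily discrete, the two-sided p-value
under its own null is super-uniform (conservative) rather than exactly
uniform; the calibration test therefore checks that the rejection rate
never exceeds the nominal level across a grid of thresholds, over 500
re-draws at R = 200.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not raw sequencing:

* **Design**: 36 discovery and 93 validation samples by default — the
  two-cohort shape of the motivating study design.
* **Genome**: a random contig carrying non-overlapping genes with 2–4 CDS
  exons on both strands, CDS lengths multiples of 3 around a 900 nt mean;
  capture = CDS ± 2 bp splice flanks plus occasional off-target intergenic
  windows.
* **Spectrum**: background SNVs are drawn per-site conditional on base and
  CpG context with the same site index the permutation uses — generator and
  null share one stratification implementation by construction. Default
  weights put 0.545 on C:G>T:A combined, matching the spectrum reported for
  MSI colorectal tumors.
* **Burden**: per-sample counts are Poisson with the configured target as
  mean (~median). The default of 50 per sample is a deliberate scale-down
  of real exome-wide burdens in the hundreds, proportioned to the
  few-tens-of-kb synthetic capture; burden per captured base, which is what
  drives collision statistics, is the quantity being emulated.
* **Planted hot spots**: a deterministic non-synonymous change at a chosen
  codon, injected into chosen numbers of discovery/validation samples with
  depths and allele fractions that pass the filters.
* **Decoys**: ~10% of the background count per filter class (low depth,
  low fraction, indel, off-target, germline) so every filter stage removes
  something on every run; planted germline variants get panel frequencies
  at or above the threshold, somatic variants stay absent from the panel.
* **Determinism**: all randomness flows from one master seed through named
  substreams; a fixed seed reproduces byte-identical FASTA/GTF/BED/TSV
  outputs.

What the generator does *not* emulate — alignment artifacts, base-quality
error, multi-nucleotide events, copy number, microsatellite indels, gene
length/replication-timing covariates of mutation rate — bounds what the
passing tests show: they validate the statistical machinery and its
contracts, not robustness to upstream calling error on real tumors.

### Problem sizes used in the tests

Test and acceptance scenarios are sized so their statistical claims hold
exactly, as a design property:

* **Recovery**: exact precision = recall = 1.0 across 20 seeds is only a
  meaningful expectation where chance codon collisions are negligible, so
  the recovery scenario uses a sparse background (burden 0.1/sample over 40
  genes ≈ 12,000 codons; expected chance collisions ≈ 7 × 10⁻⁴ per cohort).
  A companion test shows false-positive hot spots appearing as burden
  rises, which is the intended behavior, not a failure mode.
* **Permutation at full scale**: a 36-sample discovery cohort with ~200
  mutations over a ~90 kb capture carrying 10 planted hot spots of 3
  mutations each. The null cluster count is approximately Poisson(1)
  (3m²/2N pair-collision heuristic), so an observed excess of ~10 sits
  beyond the null's 10⁻⁷ tail and every randomized count falls below the
  observed — the regime in which the add-one p-value at R = 100,000 prints
  2 × 10⁻⁵.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(
  seed = 7, n_genes = 8, burden_median = 5,
  hotspots = list(list(gene = "G001", codon = 10,
                       n_discovery = 4, n_validation = 2)))
coh <- generate_cohort(cfg)
res <- run_hotspot_analysis(coh$variants, coh$ref, coh$models, coh$regions,
                            panel = coh$panel, permutation = TRUE,
                            R = 10000, seed = 1)
res$filter_report
res$hotspots[res$hotspots$gene_id == "G001", ]
res$permutation
```

## Numerical and degenerate-input choices

* Percentages round half away from zero at one decimal
  (`round_half_up()`), matching how cohort tables are conventionally
  printed; base R's half-to-even would disagree at exact halves.
* The MAF retention rule is a strict `<`; the depth and fraction rules are
  inclusive `>=`; all three are asserted at their exact boundary values.
* An empty capture set is an error for the site index (the null would be
  undefined) but a valid filter (everything removed).
* A mutation type with zero eligible capture sites aborts the permutation
  with the type named, rather than silently dropping mutations.
* Ties in clustering cannot occur: components of an interval graph on
  integers are unique, which is why the connected-component rule was chosen
  over seed-and-extend alternatives.
* Overlapping gene models route through an auxiliary code table in the
  fast permutation path; the sample-count null criterion is not offered in
  that case (the default mutation-count criterion is unaffected).

## Known limitations

* One canonical transcript per gene; codon numbering is taken from the
  supplied transcript, never inferred, and multi-isoform consequence
  resolution is out of scope.
* Splice-flank modeling uses CDS exon boundaries only; non-coding exon
  flanks are not considered.
* No per-hot-spot significance is computed — the permutation assesses
  exome-wide excess only — and no covariate-matched background (expression,
  replication timing) is attempted.
* The control panel is exact-allele lookup; no proxy matching by position
  or local haplotype.
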