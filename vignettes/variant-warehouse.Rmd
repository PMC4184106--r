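---
title: "The variant warehouse: model, filtering semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The variant warehouse: model, filtering semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varstore)
```

# The data model

A store is a directory holding three layers of the same information:

1. **Per-sample call tables** — one SNP and one indel table per sample, in
   the internal tab-separated layout (`chrom pos ref alt zygosity
   ref_depth alt_depth quality`). These are the ground truth and the only
   place genotype-level detail (depths, qualities) lives.
2. **Summary tables** — one row per *distinct* variant per kind, carrying
   the variant key, the cached carrier count, and the functional
   annotation computed when the variant was first seen.
3. **Carrier link tables** — `(variant, sample, zygosity)` rows, keyed by
   variant. Together with the summary row they answer every cohort-wide
   question without opening per-sample tables.

Variant identity is `(chrom, pos, alt)`. The reference allele is stored
and validated — two imports disagreeing on `ref` at the same key are a
hard error — but does not participate in identity, so multi-allelic sites
become separate records. All coordinates are 1-based inclusive
internally; genePred/refFlat input (0-based half-open) is converted at the
boundary. Indels use the minimal-allele representation with `"-"` for the
empty side; VCF's anchored representation is normalized on entry by
stripping the maximal common prefix, then the maximal common suffix, then
left-aligning the remaining pure insertion/deletion against the allele
string itself. No reference genome is consulted anywhere; this keeps the
package fully self-contained, at the cost that alignment can only use the
context the VCF record itself provides (in practice the repeat context of
the REF allele). The normalization is idempotent and is property-tested
against an exhaustive leftmost-placement search.

Every mutating operation (add sample, batch import, remove sample) stages
its changes on copies and commits only on success, so a failing import
leaves the store byte-identical (verified by the audit dump, a
deterministic sorted rendering of layer 2+3 that serves as the store's
canonical equality surface). A full-scan audit (`audit_check()`)
recomputes the carrier sets from layer 1 and is run in tests after every
mutation sequence.

# Import-time annotation

Annotation runs **exactly once per distinct variant** over the store's
lifetime (asserted by an invocation counter in the tests); later carriers
of a known variant only extend the link table. The annotator composes:

* **Region classification** against gene models. Per transcript, a
  position is exonic (inside an exon and the CDS span), UTR5/UTR3
  (strand-aware), intronic, splicing (intronic within `splice_window` of a
  junction), ncRNA (inside a transcript without a CDS), or
  upstream/downstream (within 1 kb outside the transcript). Across
  transcripts the highest-precedence class wins: exonic > splicing >
  ncRNA > UTR5 > UTR3 > intronic > upstream > downstream > intergenic.
  The strict order inside the pairs (exonic/splicing, UTR5/UTR3,
  upstream/downstream) is a deterministic tie-break; remaining ties go to
  the alphabetically first gene symbol. An exonic position that is also
  within the splice window of a junction (possible only through another
  transcript) reports exonic, with its coding effect computed — splicing
  is reserved for intronic-side positions.
* **Coding effects** from the spliced CDS sequence that travels with the
  gene-model file (an extra `cdsSeq` column in coding orientation). SNVs
  translate the reference and alternative codon with the standard genetic
  code: same amino acid → synonymous, gained stop → stopgain, lost stop →
  stoploss, otherwise nonsynonymous. Exonic indels are classified purely
  by length arithmetic: `(inserted − deleted) mod 3 ≠ 0` is a frameshift.
  When several transcripts cover an exonic SNV, the reported effect is the
  most severe (stopgain > stoploss > frameshift > nonsynonymous >
  nonframeshift > synonymous) — a deterministic and clinically
  conservative choice. If a variant's stated reference allele contradicts
  the CDS sequence, the direct classifier refuses; the composed annotator
  records `none` rather than guessing, since a warehouse ingesting calls
  from heterogeneous pipelines cannot verify either side.
* **Lookups** in dbSNP-style and score tables, matched on the full
  `(chrom, pos, ref, alt)` key. Scores are looked up for SNVs only,
  mirroring the SNV-centric score catalogues.

`splice_window` defaults to 2 bp — the canonical donor/acceptor
dinucleotide and the default of the annotation ecosystem this vocabulary
comes from; it is configurable per store.

# Filtering semantics

`filter_spec()` partitions the registered samples into the in-, discard-
and filter-groups; the partition must be exact (the command-line interface
defaults unassigned samples into the filter-group). A variant passes when

* its in-group carrier count is at least `ceiling(X · |I|)`, and
* its filter-group carrier count is at most `floor(Y · |F|)` or an
  absolute cap.

`ceiling`/`floor` were chosen so the boundary cases mean what a user
says: `X = 1` is *all* of the in-group, `Y = 0` is *none* of the
filter-group, with both thresholds inclusive and integer-safe. Carrier
frequencies count individuals, not alleles: a heterozygous and a
homozygous carrier each count once. An empty filter-group is legal (the
predicate is vacuously true); an empty in-group is rejected. Class
constraints, dbSNP exclusion (`all` vs `common_only`) and the
homozygous-in-group requirement are conjunctive predicates evaluated on
the summary row; class constraints use the annotation stored at import
time — re-annotating at query time is deliberately out of scope, so a
store's results are stable under annotation-table upgrades until samples
are re-imported.

Output order is deterministic (natural chromosome order, then position,
then alternative allele) so result files are diffable.

The central correctness argument is an oracle-equivalence property: on
randomized stores (at most 8 samples, at most 50 pooled variants) with
randomized specifications, the engine's output is compared with an
exhaustive enumeration over every variant and group, re-read from the
on-disk files with base R; the shipped suite runs 1050 such trials, plus
baseline comparisons of `naive_filter()` wherever its restricted shape
(two in-group samples, `X = 1`, cap 0) is defined.

# The scaling contract, without wall clocks

The design claim — filtering cost independent of cohort size — is
hardware-bound if stated in seconds, so the package states it as a
countable property: `group_filter()` opens at most `|I|` per-sample
tables (only to fetch genotype details for surviving variants), at every
store size, while the naive baseline opens `2 + |F|` tables. Both are
measured by instrumentation counters (`filter_cost_counters()`), and the
acceptance suite verifies the bound on a 10 → 50 → 100 → 200-sample
series with a planted pair-exclusive variant. Published wall-clock figures
for specific hardware are not reproduced.

# The synthetic cohort generator

`generate_cohort()` emulates the cohort structure the filtering designs
assume, not sequencing physics. Background variation has two components:
a shared pool (default 30 variants, each carried by each sample with
probability 0.3 — standing in for polymorphisms and recurrent artifacts
seen across a cohort) and private per-sample variants (10 candidate sites
per sample at rate 0.2). Depths are binomial around 40x coverage and
qualities uniform on [30, 99] — plausible exome values; nothing downstream
depends on them. Planted truths are *realized exactly, never sampled*: an
explicit carrier list is used as-is, and a per-population frequency `f`
assigns the variant to the first `round(f · n)` samples of a seed-fixed
shuffled order. This makes scenario truths equality-assertable (a 10%
planting in 100 samples is exactly 10 carriers) rather than statistical.

What the generator does **not** model: linkage disequilibrium, mutation
rate heterogeneity, sequencing error profiles, relatedness beyond the
explicitly planted carrier sets, and allele-frequency spectra. Passing the
planted-scenario tests therefore shows the *filter semantics* recover the
designed truths; it says nothing about power on real data, where the
candidate lists are narrowed by the same predicates but the signal/noise
structure is real.

The worked-example fixture (`build_wdm_fixture()`) rebuilds a published
dominant-disorder screen at desk scale: the 13 candidate SNP loci with
their rsids, classes and gene symbols are the published ones, and the gene
models are crafted so the package's own annotator reproduces those classes
(tiny single-exon CDS genes for the nonsynonymous candidates, two-exon
genes for the intronic ones, one gene carrying both an intronic and a
synonymous candidate). Alleles, depths and qualities are fixture values,
documented as such, because the source table prints none. The published
screen's conditions are in-group = the two affected exomes, `X = 1`, at
most one filter-group carrier, and dbSNP-common exclusion — the published
candidate list contains rsid-bearing, intronic, synonymous and intergenic
rows, so no damaging-class constraint and no blanket dbSNP exclusion can
have been applied, and the published rsids are loaded as non-common dbSNP
entries. Decoy variants each violate exactly one condition (carried by
two filter-group samples, dbSNP-common, or carried by only one of the two
affected), and two candidates are given exactly one filter-group carrier
to pin the at-most-one boundary. Two synthetic indel candidates exercise
the indel path; the published screen reported two indel candidates without
printing their loci, so these are not treated as reproduced values.

# Numerical and degenerate-input choices

* Thresholds: `ceiling` on the in-group, `floor` on the filter-group,
  both inclusive (see above).
* Chromosome names are stored verbatim; mixing `chr1` and `1` in one
  store warns but does not fail (verbatim storage is lossless, and the
  mixture is usually a pipeline mistake the user wants to hear about).
* Genotypes: `0/1`-style and phased `|` genotypes are mapped to het/hom by
  counting alternative-allele copies; half-calls (`./1`) are rejected
  rather than guessed; `0/0` and `./.` records are skipped. Missing `AD`
  falls back to `DP` as the alternative depth, then to a 0/1 placeholder,
  each with a warning.
* A sample importing the same variant key twice is an error (ambiguous
  carrier row); re-importing a registered sample id is a logged skip so
  batch imports are idempotent.
* Removing a sample deletes summary rows whose carrier set would become
  empty; `remove(add(S))` restores a byte-identical audit dump.

# Problem sizes used by the shipped suite

Oracle equivalence runs 25 random stores × 42 random specifications
(1050 trials); the consistency test performs 110 randomized add/remove
operations with full-scan audits every tenth step; the scaling series
imports 200 samples; the annotator check classifies 1100 random positions
against a per-base interval-scan oracle and enumerates all nine
substitutions of four codons. These sizes were chosen so each property is
exercised well past its boundary cases while the whole suite stays fast
enough to run on every change.

# Known limitations

* No multi-user access control, replication, or schema migration; one
  store is one directory owned by one analyst.
* gVCF, BCF, SAM/BAM/CRAM and structural variants are out of scope;
  multi-sample VCFs must be split upstream.
* Annotation is desk-scale by construction: gene models, dbSNP and score
  tables are plain files supplied to `init_store()`; real genome-wide
  catalogues are neither shipped nor downloaded.
* Group filtering is exactly that — filtering. No association statistics,
  kinship inference or phasing is attempted.
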