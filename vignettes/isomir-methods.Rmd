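---
title: "Methods: isomiR calling, quantification and trend testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR calling, quantification and trend testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirseq)
```

This vignette documents the models, conventions and numerical choices
behind `isomirseq`, in the order the pipeline applies them.

## Reference model and coordinates

A hairpin reference is a precursor sequence plus `flank_len` downstream
genomic bases stored in mature (5′→3′) orientation (minus-strand loci are
reverse-complemented at load time). The flank exists solely so the isomiR
caller can decide whether an added 3′ base continues the genome
(templated) or not (non-templated). `flank_len` defaults to 10 nt and
must exceed the 3′ offset cap (6 nt): a templated-extension call can
never run out of reference context.

File interfaces use 1-based inclusive coordinates (the GFF3 convention);
mature arms are annotated on hairpin-local coordinates with `ID=`
(accession) and `Name=` attributes. All comparison logic runs in DNA
space: U is normalized to T on input, and the input alphabet is
remembered so sequences can be written back as given. The archetype of
an arm is the annotated substring of its hairpin; it is re-derived, never
stored independently, so the two cannot disagree.

## Trimming, alignment and arm assignment

Adapter trimming removes the read suffix matching a prefix of the 3′
adapter: an exact match of at least `min_overlap = 3` bases, or a
full-length adapter occurrence with at most 10 % mismatches. Untrimmed
reads pass through flagged. After collapsing identical inserts, reads
outside 15–28 nt are dropped — the window brackets the mature-miRNA size
range with margin for tailed and trimmed isoforms — as are reads below
mean Phred 20.

Alignment is deliberately minimal: a contiguous, ungapped match of a
read *prefix* to hairpin + flank with at most one internal substitution;
no insertions or deletions are representable. The unexplained 3′
remainder (≤ `max_tail = 6` bases) is the candidate NTA tail. Two rules
deal with the intrinsic ambiguity at the 3′ terminus:

* a 3′-terminal mismatching base is never accepted as the one allowed
  substitution — it is indistinguishable from a non-templated addition
  and is shunted into the tail;
* candidate placements are ranked by (fewest mismatches, then shortest
  tail), so a clean templated extension is always preferred over an
  interpretation that invokes a substitution.

A read whose best rank occurs on two different hairpins is ambiguous and
excluded from quantification; equal-rank placements on one hairpin are
resolved at arm assignment toward the smaller |5′ offset|, then the
smaller start, making the whole path deterministic. A minimum templated
length of 14 nt keeps spurious short placements out. Reads are assigned
to the arm whose annotated 5′ end is nearest, provided |5′ offset| ≤ 4
and |templated 3′ offset| ≤ 6; reads farther from both arms (e.g. loop
fragments) stay unassigned. Every stage reports a count tally, and the
identity input = kept + filtered + unaligned + ambiguous + assigned is
asserted in the test suite.

The aligner works directly on hairpins plus flanks rather than on a
whole genome: for arm-level quantification the two are equivalent, and
genome-wide decoy mapping is out of scope here.

## IsomiR nomenclature and classification

An isomiR is identified by `(arm, s, e, NTA)`: `s` is the 5′ offset, `e`
the templated 3′ offset (both rightward-positive along the hairpin), and
NTA the non-templated tail. The label writes signs explicitly (`"+1|-2"`,
archetype `"0|0"`). The aligner's tail is re-resolved against the
reference continuation with a maximal-prefix rule — the longest prefix of
the tail that continues the reference is absorbed into `e`; the remainder
is NTA. A tail of `"UU"` over a genomic continuation `"UA"` is therefore
`e + 1` with a single-U NTA.

Classification is a pure function of `(s, e, NTA)` into six exclusive
categories: canonical `(0, 0, none)`; 5′ deletion (`s > 0` only);
5′ addition (`s < 0` only); 3′ deletion (`e < 0` only); 3′ addition
(`e > 0` only); mixed for any combination of a 5′ change with a 3′
change, or an NTA alongside a templated 3′ change. Uridylation — a tail
consisting only of U — is a cross-cutting flag, not a seventh category.
Where a pure-NTA record `(0, 0, tail)` belongs is genuinely open (the
six-way scheme predates NTA-aware callers); by default it is counted in
the 3′ addition column, and `nta_mode = "own"` gives it its own column
instead. The exhaustive truth table over the full offset grid is part of
the test suite.

## Quantification

RPM uses the arm-aligned denominator: per sample, reads that passed
trimming and filtering and were assigned to an arm. Whether the one
allowed mismatch belongs in that denominator is ambiguous; the default
includes ≤1-mismatch assignments and `strict_denominator = TRUE`
restricts to perfect matches — both are recorded in the output metadata.
Arm abundance is the sum of member isomiR abundances (raw and RPM), so
totals are conserved by construction.

Category proportion tables pool replicate counts within condition before
computing percentages (per-replicate averaging is available behind
`pooling = "average"`); pooling is the default because one value per
condition is the natural report for count-based proportions and needs no
variance model. Percentages are kept at full precision internally and
rounded to 2 decimals only for display. The six exclusive columns sum to
100; uridylation is reported alongside over the same denominator.
Proportion differences between the two treated conditions are tested per
category with the pooled two-proportion z-test, reported unadjusted, as
is conventional for per-arm proportion panels. The population-doubling
utility implements PD = (log10 F − log10 I)/log10 2 with a running sum
for cumulative PD.

## Count modelling and trend tests

The testing stack is self-contained NB machinery (concordance with any
specific external DE package is a non-goal; calibration is the design
target, and it is measured, not assumed):

* **Size factors** — median-of-ratios: per sample, the median over
  features positive in all samples of count / geometric mean, with log
  factors mean-centred. If no feature is positive everywhere, library
  size is used (with a message).
* **Dispersions** — per-feature Cox–Reid-adjusted profile maximum
  likelihood (group means profiled out by Newton iterations), then a
  parametric trend α(µ) = a0 + a1/µ fit by robust iterated least
  squares, and shrinkage of log α toward the trend weighting the
  feature's residual degrees of freedom against `prior_df = 50`. With
  three replicates per condition a feature has only 3–6 residual df, so
  the trend must dominate: without the adjustment and the strong prior
  the raw tests are markedly anticonservative at this design size,
  whereas the shipped configuration keeps the raw type-I rate of both
  tests near the nominal 5 % (the acceptance suite asserts the
  2,000-feature null simulation lands in [0.03, 0.07]). The floor is
  1e-8.
* **Wald DE test** — one NB mean per condition with size-factor offsets;
  the two-sided Wald p on the log fold change; BH across features. A
  feature is *called* at FDR < 0.05 and |FC| ≥ 1.5 (|log2 FC| ≥ 0.585).
  All-zero features get NA and leave the BH family.
* **LRT trend test** — full model (one mean per condition) vs reduced
  (common mean), same dispersion, statistic 2Δℓ against χ² with
  (conditions − 1) df, BH across features.
* **Shape classification** — flat unless the LRT FDR < 0.05; otherwise
  the signs of the two transitions (Young→SEN, SEN→SEN+M) give
  linear-up/linear-down (same sign or one zero), U (down–up) or
  inverted-U (up–down). The rule depends only on orderings, so it is
  invariant under monotone rescaling of the means.
* **Global category test** — chi-square homogeneity of the pooled
  six-way category counts between two conditions by default; the
  identity of the appropriate test is not canonical, so a Monte-Carlo
  permutation alternative (margins fixed, `r2dtable`) is available and
  agrees within simulation error.
* **QC** — Pearson correlations and PCA on log2(RPM + 1). rlog-style
  variance-stabilising transforms are package-specific; the pseudo-log
  preserves the ordering/sign structure the QC needs.

## Seeds, targets and enrichment

The seed is mature positions 2–8 (7 nt, TargetScan convention). A +k 5′
offset slides the window k bases 3′-ward; a −k offset prepends k
templated hairpin bases. Site classes on 3′UTRs: 7mer-m8 (reverse
complement of seed 2–8), 7mer-A1 (reverse complement of seed 2–7
followed by A), 8mer (both); 6mer sites are excluded by default as the
weakest class. Scanning is on the given strand only, exact matches.
Seed collisions report exact 7-mer equality between an isomiR seed and
another arm's canonical seed (self-pairs excluded). Target-set overlap
returns exact Venn region counts for 2–3 sets (pairwise matrix beyond).
Enrichment is the one-sided Fisher exact test (hypergeometric upper
tail) per gene set with BH across sets and significance at p < 0.01; the
universe defaults to the union of all gene-set members, since an
external web tool's universe is not reproducible offline. The reported
ratio is the targeted fraction of each set.

## Synthetic data: what it emulates, and what not

`simulate_reads` emulates small-RNA sequencing of mature isoforms:
each read is templated isoform + NTA tail + 3′ adapter, with constant
high base quality and optional uniform substitution errors. By default
errors avoid the first and last templated base, because a terminal
substitution is genuinely indistinguishable from an offset/NTA change
and would make truth labels ill-defined; `uniform_errors = TRUE` lifts
this for robustness tests. Count allocation across the spectrum is
deterministic largest-remainder by default — so recovered proportions
are *exactly* the configured fractions — with multinomial sampling as
the stochastic alternative. The generator refuses spectra whose planted
tail begins with the genomic continuation base (the truth label would be
wrong by construction) and validates all bounds before writing any file.
Not modelled: PCR duplicates, UMIs, ligation bias, indel errors (the
aligner forbids indels anyway) and quality degradation along the read.
Passing tests on this generator therefore validate the calling logic and
bookkeeping, not robustness to library-preparation artefacts in real
data.

`simulate_counts` draws NB counts (Poisson at dispersion 0) for a
3 × 3 design with per-feature log-normal baselines (default meanlog
log 200, sdlog 1, dispersion 0.05 — a realistic bulk small-RNA scale)
and planted per-transition fold changes following linear or U-shaped
patterns. `simulate_utrs_genesets` plants 8mer sites for designated
seed/gene pairs and rejection-samples all other sequence against
accidental sites of any planted seed, so predicted target sets equal the
planted truth exactly.

All randomness flows from explicit seeds; per-sample and per-stage
streams are derived deterministically (and kept below 2^31), so equal
seeds give byte-identical FASTQ, tables and reports. The test suite and
the worked examples run the full pipeline at 2 hairpins × 9 samples ×
1,500–2,000 reads and the statistical simulations at 2,000 features —
sizes chosen to keep the whole suite fast while every code path is
exercised. The same code runs unchanged at depth (the preprocessing
stages are vectorized across reads and the aligner operates on collapsed
unique sequences, so runtime grows with sequence diversity rather than
raw read count).

## Known limitations

* A-to-I editing and internal (non-terminal) variants are not called.
* Whether a 3′ tail was added at the pre-miRNA or mature stage cannot be
  distinguished from sequencing data and is not attempted.
* The aligner has no multi-mapper rescue: cross-hairpin ambiguous reads
  are dropped, which undercounts recently duplicated miRNA families.
* The DE machinery is designed for the small-replicate bulk setting;
  it does not provide moderated log-fold-change shrinkage, and exact
  numerical agreement with external DE packages is not a goal.
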