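---
title: "Germline variant analysis for targeted capture panels: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Germline variant analysis for targeted capture panels: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germpanel)
library(dplyr)
```

germpanel implements the germline arm of a hybridization-capture
cancer-predisposition panel analysis: coverage quality control at single-base
resolution, union merging of two variant callers with depth/allele-fraction
filters, exon-level copy-number calling against a pool of reference diploid
normals, breakpoint refinement of coverage-derived CNVs with
structural-variant evidence, five-class ACMG classification, and the
statistics used to validate such an assay. This vignette explains the models
behind each component, the parameters that matter, and the design choices
made where more than one defensible option existed.

## Coordinates and the panel model

Internally every interval is 0-based half-open (BED-native); 1-based
positions appear only in variant records, which are VCF-native. A panel is a
set of exon target regions labelled `GENE_exonN`, each with an *effective
intronic flank*. Capture baits tile exon edges, so coverage extends into the
flanking introns and splice-region variants up to ~50 bp from the boundary
are callable; 50 bp is therefore the default flank. In short introns the
nominal flanks of adjacent exons would overlap, so they are truncated at the
intron midpoint — a declared convention chosen so that every intronic
position belongs to at most one exon's flank (the upstream exon receives
`gap %/% 2` bp, the downstream exon the remainder). Position classification
(`exonic` / `noncoding_flank` / `off_target`) drives the filter thresholds
downstream; exonic status always wins over another exon's flank.

## Coverage QC: the minimum-position rule

An exon passes coverage QC only if its *lowest-covered* base reaches 50
reads — an average can hide an uncallable corner of an exon, so means are
reported but never gate anything. Panel positions absent from the depth
table count as depth 0, the conservative reading for a minimum rule.
Duplicate depth rows for one (sample, chrom, pos) are an error rather than
silently aggregated: ambiguity there signals corrupt input. "Consistently
poorly performing" exons — those failing the minimum rule in more than 50%
of the reference cohort (a configurable fraction; no published value exists
for it) — are excluded from CNV calling.

`flank_coverage_profile()` sweeps flank distance d = 1..200 and reports the
mean depth at exactly d bp outside an exon boundary and the fraction of
flank regions of size d whose minimum stays at or above 50 reads. The
fraction is non-increasing in d by construction (a larger region's minimum
can only stay or drop). The profile deliberately ignores midpoint
truncation: it describes the capture chemistry, not the calling convention.

## Variant filtering

Two callers are merged by set union on *normalized* variant keys: alleles
are reduced by trimming the shared suffix, then the shared prefix (always
keeping one base of each allele), advancing the position by the trimmed
prefix length. This unifies the padded indel encodings different callers
emit. When both callers report a variant, depth (DP) and alt fraction (VF)
are taken from caller A — a declared precedence; VF disagreements above 10
percentage points are reported. Indels of 30 bp or longer are routed out of
the SNV/indel path (they belong to CNV/SV calling).

Filters are region-class dependent and inclusive: a call passes when
DP ≥ 50 and VF ≥ 0.20 for exonic calls, or VF ≥ 0.25 for anything outside
an exon, and the position is on target. Failure reasons are assigned depth
first, then VF, then region. Zygosity is assigned from VF alone:
heterozygous in [0.40, 0.60], homozygous at ≥ 0.90, ambiguous between the
bands — the ambiguous band is reported, never auto-resolved, because skewed
fractions in flanking homopolymer regions are a known artifact, not a
genotype. A passing call is *borderline* when DP is within 10 reads of the
depth cutoff or VF within 0.03 of its class threshold; these margins are
configuration defaults (the concept of a barely-passing call has no
published margins) and exist to explain replicate discordance, not to
change filtering.

## CNV calling against reference diploid normals

The depth matrix holds per-exon mean depths for one test sample and a pool
of reference diploid normals (minimum 2 for the arithmetic; a warning below
10 because the per-exon variance estimate degrades). Normalization is
per-sample library-size scaling only: each sample's exon depths are divided
by that sample's mean over retained exons, so a diploid sample centers at
1.0 and calls are invariant to sequencing yield. GC- or bait-efficiency
correction is deliberately omitted (bait effects are shared across samples
and cancel in the reference ratio); the hook is the normalization function
itself, which can be swapped.

For each exon the test/reference ratio r is reported with a signed fold
change — r for gains, −1/r for losses — so a heterozygous deletion
(r = 0.5) sits at −2.0 and a single-copy gain (r = 1.5) at +1.5. This
signed-reciprocal convention is the only one under which a loss threshold
of −1.7 is met by a het deletion's expectation. Significance is a
two-sided one-sample z test of the test sample's log2 value against the
reference pool's per-exon log2 mean and standard deviation, with an SD
floor of 0.05 on the log2 scale so that near-constant exons cannot produce
vanishing p-values from a degenerate variance estimate. An exon is called
when fold change exceeds +1.3 (gain) or falls below −1.7 (loss) *and*
p < 0.05; thresholds are applied per exon exactly as stated, with no
multiple-testing correction — a fidelity-over-taste decision; the
Fisher-combined p-value reported per segment is for ranking only.

Maximal runs of consecutive same-direction significant exons form segments;
a single intervening non-significant callable exon splits a run (bridging
gaps would manufacture spans the data do not support). A segment covering
every callable exon of its gene is `whole_gene`, otherwise `intragenic`.
Exons where any reference normal has zero coverage are uncallable and
excluded.

A note on normalization bias: because the library-size factor is the mean
over *all* retained exons, a CNV spanning a large fraction of a small panel
drags its own sample's normalizer and attenuates the observed ratio. On
realistic panels (dozens of genes) the effect is negligible; the package's
simulations use multi-gene panels for exactly this reason.

## SV-evidence breakpoint refinement

Coverage calling has exon resolution; split-read/read-pair SV records have
base resolution. Each CNV segment is matched to the SV record of the same
direction (DEL↔loss, DUP↔gain) maximizing reciprocal overlap with the
segment's genomic interval, requiring reciprocal overlap ≥ 0.5 and at least
3 supporting reads — both declared defaults, since no published matching
criteria exist. Ties break by higher support, then smaller interval, then
leftmost start, making the result order-independent. A matched segment
gains base-level `refined_start`/`refined_end` and a `boundary_note`
locating each breakpoint in exon anatomy (e.g. "starts in the middle of
exon 10; ends in the intron between exons 17 and 18, 5' of exon 18" — the
5'-of label follows transcript orientation via the gene's strand).
Refinement never alters the base segment's direction, scope, fold change or
p-value. Translocations and inversions are out of scope by design.

## ACMG classification

The evidence-combining rules of the ACMG/AMP guideline (Richards et al.
2015) are implemented as an explicit, testable rule table over tag-category
counts — a deliberate dependency on the guideline as *data*, not code.
Combinations qualifying as pathogenic map to Class 5, likely pathogenic to
Class 4, benign to Class 1, likely benign to Class 2, everything else to
Class 3 (VUS). BA1 — maximum population allele frequency strictly greater
than 5% across the supplied cohort tables — is stand-alone benign and is
forced into the evidence set automatically from the population-AF table;
the maximum-over-supplied-tables semantics is the declared reading since no
specific resource ceiling is published. When both a pathogenic-qualifying
and a benign-qualifying combination hold simultaneously, the call is
Class 3 with a `conflict` flag, following the guideline's
conflicting-evidence default. Reporting groups calls as Class_1_2 /
Class_3 / Class_4_5, the grouping used in clinical summaries.

## Validation statistics

**Detection power.** A variant at true allele fraction f sequenced to depth
d is detected when the observed fraction clears the exonic threshold t,
i.e. when the alt-read count X ~ Binomial(d, f) reaches ⌈t·d⌉. Power is the
exact binomial tail — never a normal approximation, because the depths of
interest are small:

```{r power}
detection_power(17, 0.5, 0.20)
```

The ceiling makes power *non-monotone* in depth: isolated lower depths can
transiently exceed a target before dipping back under it
(`detection_power(15, 0.5, 0.2)` exceeds 0.99 while depth 16 does not).
`min_depth_for_power()` therefore returns the smallest depth from which the
target holds at that depth and every greater one — the operationally
meaningful guarantee, and 17 for a heterozygous variant at the 99% target:

```{r mindepth}
min_depth_for_power(0.5, 0.20, 0.99)
```

**Noise characterization.** From replicated control samples, a pre-filter
call is *reproducible* only when present in every replicate of its control
(a strictly binary reading — majority presence is still noise). The
surviving count for a candidate threshold pair is the number of
non-reproducible calls that would pass filtering in at least one replicate;
the production question is whether (DP 50, VF 0.20/0.25) drives it to zero.

**Replicate concordance.** Filtered call sets from intra- or inter-run
replicates are compared per region class by pairwise Jaccard index on
normalized keys, with a flag for exonic sets being identical and the
fraction of discordant variants explained by borderline status. Barcode
labels are carried through and reported but never alter any computation.

## The synthetic-data generator

All inputs are simulated with planted ground truth so that every component
is testable without sequencing data; every artifact is a deterministic
function of a mandatory seed (byte-identical files on repeated
invocation). Defaults, chosen once as a realistic compact study:

* 8 genes of 4–12 exons (uniform), exon lengths 80–300 bp, introns
  200–2000 bp — spanning single-exon CNV challenge cases through mid-size
  predisposition genes while keeping simulations compact;
* 20 reference diploid normals, mean exonic depth 800 reads,
  negative-binomial depth noise at 10% per-exon coefficient of variation,
  with a log-normal per-exon capture-efficiency factor shared across
  samples (it cancels in the reference ratio, as bait effects do);
* CNV spikes at copy ratios 0.5 / 1.5 / 0 / 2 — the integer copy states of
  a diploid genome;
* variant calls whose VF is a binomial draw at the call's DP — the same
  model the power analysis assumes — with true variants present in every
  replicate (both callers with probability 0.85) and noise calls present in
  a strict subset of replicates with DP or VF below the production
  thresholds by construction;
* 13 control samples and 3 replicates for the noise and concordance
  studies, with run and barcode labels.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: alignment and homopolymer-realignment artifacts,
GC-dependent coverage waves correlated across samples, batch effects in the
reference pool, and mosaicism. The noise model places artifacts below the
production thresholds because that is the structure the thresholds were
designed against; the generator can plant louder noise to demonstrate the
failure mode.

The recovery surface the package reports
(`cnv_recovery_study()`) simulates cohorts of 20 normals at 10% CV, plants
a whole-gene heterozygous deletion, a single-exon duplication and an
unspiked null sample per cohort, and measures recovery sensitivity and the
per-gene false segment rate at the production thresholds; 100 cohorts of 6
genes keep the run inside a few minutes while giving stable estimates
(several hundred gene-draws for the false-call rate).

## Numerical choices and degenerate inputs

* z statistics are capped at |z| = 38 so p-values stay strictly positive in
  double precision; a zero test-sample depth at a callable exon yields a
  capped, maximally significant loss rather than a NaN.
* Fisher's combination uses `pchisq(-2·Σlog p, 2k, lower.tail = FALSE)`
  with p floored at the smallest positive double.
* Reference-pool exons containing a zero are uncallable rather than
  imputed.
* `union_merge` rejects duplicate normalized keys within one caller and
  conflicting ref alleles at one site (both indicate broken upstream
  normalization) instead of guessing.
* Ties in SV matching are broken deterministically (support, then interval
  size, then leftmost start); all report files are written with fixed
  formatting so identical inputs give byte-identical outputs.

## Known limitations

The CNV caller assumes a reference pool that is copy-neutral and
batch-matched; it performs no GC correction, no allele-fraction-informed
genotyping, and no FDR control across exons (by design, see above). The
ACMG engine consumes evidence tags; it does not derive them from
predictors, segregation or literature. Population allele frequencies are
supplied as tables, never queried live. BAM-level depth extraction is out
of scope: depth tables are consumed as emitted by standard tools.
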