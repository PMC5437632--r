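# germpanel

Germline variant analysis for targeted hybridization-capture
cancer-predisposition panels.

Clinical panels sequence the exons (and ~50 bp of flanking intron) of a few
dozen predisposition genes at high depth in blood normals. Turning those
reads into a reportable germline result takes more than a caller: exons must
be vetted by their *worst*-covered base, two callers' SNV/indel output must
be unified and filtered on depth (DP) and variant allele fraction (VF),
exon-scale copy-number variants must be detected from coverage ratios
against a pool of reference diploid normals, their breakpoints sharpened
with structural-variant (SV) evidence, and every passing variant placed into
the five ACMG classes. germpanel implements that pipeline for analysts
building or validating such an assay, plus the statistics used to validate
one — exact binomial detection power, false-positive threshold
characterization from replicated controls, and replicate concordance — and a
seeded synthetic-data generator so everything runs without sequencing data.

## The models in brief

* **Coverage QC** — an exon passes only if min over its positions of depth
  is ≥ 50 reads; missing positions count as zero. A flank-distance profile
  tracks mean depth and the fraction of flanks keeping ≥ 50× as distance
  from the exon boundary grows.
* **Variant filtering** — calls are the union of two callers on normalized
  (trimmed) variant keys; a call passes when DP ≥ 50 and VF ≥ 0.20
  (exonic) or 0.25 (noncoding flank), thresholds inclusive. VF in
  [0.40, 0.60] is heterozygous, ≥ 0.90 homozygous. Calls barely above the
  cutoffs are flagged *borderline*.
* **CNV calling** — per-exon normalized coverage ratio r of test vs the
  reference-normal mean, reported as signed fold change (r, or −1/r below
  1, so a het deletion sits at −2.0); an exon is significant when fold
  change > +1.3 or < −1.7 *and* p < 0.05 from a one-sample z test on the
  log2 scale against the reference pool (SD floor 0.05). Consecutive
  significant exons form whole-gene or intragenic segments.
* **SV reconciliation** — segments are matched to same-direction DEL/DUP
  records by maximal reciprocal overlap (≥ 0.5, support ≥ 3) and gain
  base-resolution breakpoints with notes like "starts in the middle of
  exon 10".
* **ACMG classification** — the published evidence-combining table over
  PVS/PS/PM/PP/BA1/BS/BP tags, mapped to Class 1–5; population allele
  frequency > 5% is stand-alone benign (BA1); conflicting evidence falls
  back to Class 3 (VUS).
* **Detection power** — with alt reads X ~ Binomial(depth, VF), a variant
  is detected when X ≥ ⌈0.20·depth⌉; power is the exact tail, e.g. 0.9936
  at 17× for a heterozygous variant, and 17× is the smallest depth from
  which ≥ 99% sensitivity holds at every greater depth.

## Worked example

Simulate a 12-gene panel with an intragenic heterozygous deletion of
GENE02 exons 2–5 planted in sample T1, then run the full germline arm:

```r
library(germpanel)

cfg <- sim_config(seed = 42, n_genes = 12,
                  spikes = tibble::tibble(sample_id = "T1", gene = "GENE02",
                                          first_exon = 2L, last_exon = 5L,
                                          copy_ratio = 0.5))
sim_bundle(cfg, "demo")

res <- run_germline(run_config(
  panel_bed    = "demo/panel.bed",
  calls_a      = "demo/calls_T1_rep1_A.tsv",
  calls_b      = "demo/calls_T1_rep1_B.tsv",
  sample_id    = "T1",
  depth_matrix = "demo/depth_matrix.tsv",
  svs          = "demo/svs.tsv",
  evidence     = "demo/evidence.tsv",
  pop_af       = "demo/population_af.tsv",
  out_dir      = "demo/out"))
res$segments
```

```
[germpanel] panel: 78 exons, 12 genes
[germpanel] variants: 18 merged, 16 pass, 1 fail_depth, 1 fail_vf, 0 fail_region
[germpanel] cnv: 1 segment(s) across 1 test sample(s)
[germpanel] sv: 1 of 1 segment(s) refined
  sample_id   gene first_exon last_exon n_exons direction      scope mean_fold_change   combined_p
1        T1 GENE02          2         5       4      loss intragenic         -2.01571 2.088525e-40
```

The planted deletion is recovered exactly (exons 2–5, fold change ≈ −2 as
expected for one lost copy of two), and the matching DEL record relocates
its breakpoints:

```r
res$refined$boundary_note
#> "starts in the intron between exons 1 and 2, 5' of exon 2;
#>  ends in the intron between exons 5 and 6, 5' of exon 6"
```

`demo/out/summary.json` counts passing calls by region and ACMG group —
here 16 of 18 merged calls pass, most classified benign (Class_1_2) from
population frequency alone, one noncoding call pathogenic (Class_4_5):

```json
"exonic":    { "Class_1_2": 7, "Class_3": 1, "Class_4_5": 0 },
"noncoding": { "Class_1_2": 5, "Class_3": 2, "Class_4_5": 1 }
```

The power analysis answers assay-design questions directly:

```r
detection_power(17, 0.5, 0.20)   # 0.9936371
min_depth_for_power(0.5, 0.20)   # 17
```

Fitted-object verbs work throughout: `tidy()` on a `call_cnv()` result
returns its segment table, `glance()` a one-row summary, `autoplot()` the
log2-ratio plot; likewise for `classify_callset()`,
`characterize_noise()` and `replicate_concordance()` results. A thin CLI
over the same functions lives at `inst/cli/germpanel.R`
(subcommands `simulate`, `filter`, `cnv`, `reconcile`, `classify`,
`power`, `concordance`, `run`).

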