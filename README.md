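# tirscan

Sequence analysis of translation initiation regions (TIRs) in archaea whose
transcriptomes are dominated by **leaderless mRNAs** — transcripts that begin
at, or within a few nucleotides of, the start codon and initiate translation
without a Shine-Dalgarno (SD) duplex. The package is written for
microbiologists and RNA biochemists who have a genome, transcription-unit
(TU) annotations with transcription start sites (TSS), and bench data
(circular-ligation clone sequences, toeprinting gels) and want the
genome-scale and assay-scale statistics computed the same way, reproducibly.

## What it computes

**Leader classification.** For each TU the 5'UTR length of the proximal
cistron is the number of transcribed nucleotides strictly 5' of the start
codon. mRNAs are classified as

- *leaderless*: 5'UTR ≤ 5 nt,
- *short leader*: 6–10 nt,
- *leadered*: ≥ 11 nt,

a partition that tiles the non-negative integers. Distal cistrons of
polycistronic TUs have no transcript 5'UTR and receive class `NA`.

**Positional SD calling.** Exact occurrences of SD motifs (default GGAGG and
UGAGG; GGAGG/GGTGG available as `sd_motifs_alt`) are searched in the 30-nt
window upstream of each annotated start codon. An occurrence is an SD
*signal* only if its 5' base lies between positions −18 and −9 (inclusive,
−1 = the base immediately 5' of the start codon) of the annotated start **or
of an in-frame alternative start codon** (AUG/GUG/UUG within ±30 nt). Signal
frequencies are stratified into leadered proximal cistrons versus distal
cistrons, where reinitiation may use SD:anti-SD pairing.

**SD:anti-SD duplex scoring.** `longest_antiparallel_duplex()` reports the
maximum run of contiguous antiparallel Watson-Crick (optionally G:U) base
pairs between an SD sequence and the 16S rRNA 3' tail over all alignments —
e.g. GGAGG pairs all 5 bp with the processed tail 5'-CCUCC-3' but only 4 bp
with the genome-encoded 5'-CCUCA-3'.

**16S rRNA 3'-end variants from circularization clones.** Reads sequenced
across the ligation junction of self-circularized 16S rRNA are split at the
5'-end anchor (default AAUCC) and the read suffix abutting the junction is
matched against a variant catalog (CCUCC, CCUCA, CCUC, CCU; longest exact
match wins) to tally 3'-end heterogeneity.

**Toeprint quantification.** For each primer-extension lane the toeprint
percentage is `100 * T / (T + RT)` (T = arrest band, RT = read-through);
signals are optionally normalized within each mRNA so the mean of a
reference condition (default the 5'-monophosphorylated mRNA) is exactly 100.

**Synthetic data with planted truth.** `sim_config()` +
`generate_genome_and_tus()`, `generate_junction_reads()` and
`generate_toeprint_table()` build desk-scale datasets in which every ground
truth is known: leader classes allocated exactly, SD motifs planted inside
the positional window (positives) or outside it relative to every enumerated
start (decoys), junction reads with an exact variant mixture, toeprint lanes
with known means. Every analysis stage is validated by recovering these
plantings exactly.

## Worked example

```r
library(tirscan)

cfg <- sim_config(seed = 42, n_tus = 200)   # defaults emulate the study conditions
sim <- generate_genome_and_tus(cfg)

ann <- annotate_leaders(sim$tus, sim$genes)
summarize_leader_classes(ann)
#>              leader_class   n percent
#> leaderless     leaderless 146      73
#> short_leader short_leader  22      11
#> leadered         leadered  32      16

calls <- scan_sd_signals(sim$genome, sim$genes)
summarize_sd(calls, ann)
#>    stratum motif n_total n_with_signal percent
#> 1 proximal GGAGG      32             2     6.3
#> 2 proximal TGAGG      32             1     3.1
#> 3   distal GGAGG      71             6     8.5
#> 4   distal TGAGG      71             4     5.6
```

73/11/16% of the 200 proximal cistrons are leaderless / short-leader /
leadered (the generator's exact-count allocation of its default
proportions). Of the 32 leadered proximal cistrons, 2 (6.3%) carry a GGAGG
signal passing the positional rule and 1 (3.1%) a UGAGG signal; among the 71
distal cistrons the rates are higher (8.5% and 5.6%), the planted pattern
mirroring the real transcriptome's enrichment of SD signals at distal
cistrons. Decoy motifs planted outside the −18..−9 window are present in
other windows but, correctly, never counted.

```r
longest_antiparallel_duplex("GGAGG", "CCUCC")$max_contiguous_bp  # processed 3' tail
#> [1] 5
longest_antiparallel_duplex("GGAGG", "CCUCA")$max_contiguous_bp  # genome-encoded tail
#> [1] 4
```

`run_pipeline()` ties the stages together from files and writes per-stage
TSV/GFF3 outputs plus `report.json`; `inst/scripts/tir` wraps it for the
shell (`tir run-all --genome g.fa --genes genes.tsv --tus tus.tsv --out-dir out`).

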