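---
title: "Translation initiation regions of leaderless-mRNA transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translation initiation regions of leaderless-mRNA transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirscan)
```

## The biological setting

In many archaea — *Saccharolobus solfataricus* is the motivating organism —
the large majority of mRNAs are *leaderless*: transcription starts at or
within a few nucleotides of the start codon, so there is no 5'UTR to carry a
Shine-Dalgarno (SD) element and initiation proceeds without an SD:anti-SD
duplex. SD-like signals still matter in two places: the minority of leadered
mRNAs, and the *distal* cistrons of polycistronic transcription units, where
a ribosome reinitiating after an upstream cistron can be positioned by
pairing between an upstream GGAGG-like element and the 3'-terminal tail of
the 16S rRNA (the anti-SD). A further wrinkle is that the anti-SD tail
itself can differ from the genome: circular-ligation sequencing of the 16S
rRNA shows a processed 3' end (5'-CCUCC-3') in place of the genome-encoded
5'-CCUCA-3', changing which SD variants can pair fully.

This package implements the sequence-level procedures that quantify this
picture: leader classification from TSS coordinates, positional SD calling
stratified by cistron role, duplex scoring against the anti-SD tail, 3'-end
variant classification of circularization clones, and toeprint
quantification — plus a generator of synthetic datasets with planted ground
truth so every stage can be verified exactly.

## Coordinate and alphabet conventions

All genomic coordinates are 1-based and inclusive (the GFF3 convention) and
are converted exactly once, at the package boundary. All offsets relative to
a start codon use the **−1 convention**: the base immediately 5' of the
start codon's first base is −1, so a 30-nt upstream window spans offsets
−30..−1. Sequences are held internally in the uppercase DNA alphabet; RNA
input (and RNA motif spellings such as UGAGG) is normalized by U→T on entry,
and N never matches any motif position. Minus-strand genes are handled by
reverse-complementing the genomic segment 3' of the CDS so windows always
read 5'→3' on the mRNA; a property test asserts exact strand symmetry.

## Leader classification

For the proximal cistron of a TU the 5'UTR (leader) length is the number of
transcribed nucleotides strictly 5' of the start codon's first base: 0 when
the TSS coincides with it. Classes: leaderless (≤ 5 nt), short leader
(6–10 nt), leadered (≥ 11 nt). The ≥ 11 bound was chosen over the
alternative "more than 11" phrasing so the three classes tile the integers
with no gap at 11; this is the only reading under which every length has a
class. Distal cistrons have no transcript 5'UTR and receive class `NA`;
summaries therefore run over proximal cistrons only.

## The positional SD rule

Exact motif occurrences (no fuzzy matching, overlaps allowed) are searched
in the window `width = 30` nt upstream of the annotated start. An occurrence
is a *signal* when its 5' base falls in `rule = c(-18, -9)`, inclusive,
relative to the annotated start **or** to any in-frame alternative start
codon (`start_codons = c("ATG","GTG","TTG")`) whose first base lies within
`span = c(-30, 30)` nt of the annotated one, offsets being multiples of 3.
Notes on deliberately open choices:

- **Motif set.** The default scan counts GGAGG and UGAGG (TGAGG in DNA), the
  pair whose stratified frequencies the analysis reports; GGAGG/GGTGG is
  provided as `sd_motifs_alt`. The "5' base" anchoring the rule is simply
  the motif's first base, whatever it is.
- **Alternative-start span.** No span is stated anywhere for "another
  in-frame start codon"; ±30 nt was fixed once as the span within which a
  repositioned initiation event is still plausibly the same TIR. Widening it
  admits more anchors and can only increase call rates.
- **No TSS clipping by default.** The 30-nt window is scanned even where it
  extends past the TSS into untranscribed DNA, because the procedure is
  defined as a fixed upstream window; `respect_tss = TRUE` enables clipping
  for sensitivity analyses.
- **Gene-level dedup.** A gene counts at most once per motif regardless of
  how many hits pass and via how many reference starts — required for counts
  like 9 signals among 169 cistrons to be well defined.
- **Strata.** The proximal stratum is restricted to *leadered* proximal
  cistrons (a leaderless mRNA has no room for an SD); the distal stratum is
  all distal cistrons. Distal windows may overlap the upstream gene's CDS;
  they are scanned without masking, since reinitiation signals can lie
  within upstream coding sequence.
- **Rounding.** Percentages are rounded half-up to one decimal (so 9/169 →
  5.3, 47/879 → 5.3), not banker's rounding.

## Duplex scoring

`longest_antiparallel_duplex()` returns the maximum number of contiguous
antiparallel Watson-Crick pairs (optionally G:U) over all relative
alignments of two 5'→3' sequences — a deliberately simple, exactly testable
complementarity score rather than a thermodynamic ΔG model (nearest-neighbor
energetics are a non-goal). It quantifies the observation that motivates the
3'-end analysis: GGAGG forms a 5-bp duplex with the processed anti-SD tail
CCUCC but only 4 bp with the genome-encoded CCUCA. The function is symmetric
in its arguments, and enabling wobble can never decrease the score; both
properties are asserted against a brute-force oracle.

## 3'-end variants from circularization clones

Self-ligation of the 16S rRNA followed by RT-PCR across the junction yields
clones reading `...3'-end variant | 5'-start...`. The junction is located at
the occurrence of the 5'-end anchor (AAUCC) that agrees best with the known
downstream 5' sequence (ties → leftmost; absence of the anchor is an error,
distinct from an unrecognized variant). The suffix ending at the junction is
then matched against the catalog CCUCC, CCUCA, CCUC, CCU in decreasing
length — longest exact match wins, so a CCUCC read can never be demoted to
CCUC — and anything else is `other`. Matching is exact by default because
the intended inputs are Sanger clone sequences; an anchor-only mismatch
tolerance exists for noisier inputs. A caveat inherited from the assay: a
clone ending CCUC cannot be distinguished from a truncated CCUCC by sequence
alone; the classifier is literal.

## Toeprint quantification

A lane contributes `percent = 100 * T / (T + RT)`; lanes with `T + RT = 0`
are unquantifiable and rejected. Normalization rescales within each mRNA
group so the reference condition's mean (default `"monophosphate"`) is
exactly 100 — by construction, to floating tolerance. Condition summaries
report sample SD (n−1); Welch/Student comparisons are exposed via
`compare_conditions()` as routine statistics. Band densitometry is upstream
of this package: inputs are intensity tables, not gel images, and no
background subtraction is applied.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
defaults fixed at the study conditions: leader classes 73/11/16%
(exact-count allocation by largest remainder), SD-positive rates 9/169 and
7/169 (GGAGG, UGAGG) among leadered proximal cistrons and 72/879, 47/879
among distal cistrons, a decoy rate of 0.25, a 27/1/3/1 variant mixture over
32 junction reads, and toeprint condition means (monophosphate 70/30,
triphosphate 55/45, hydroxyl 30/70, Gaussian noise SD 4) chosen once as
realistic gel intensities — the assay's true means are not published, only
the derived percentages.

Each TU is built on its own contig, on a random strand, as: a 40-nt upstream
pad (so windows are never truncated), the drawn leader, then cistrons of
12–42 random codons separated by 36–60 nt intergenic gaps (wide enough that
a distal window fits inside its gap). Positives receive their motif with the
5' base uniform in [−18, −9] of the annotated start; decoys receive it at an
offset in [−30, −5] outside that range. Every gene is then *verified* with
the real scan machinery — positives must be flagged, decoys must carry the
motif yet not be flagged (in particular not via any accidental in-frame
alternative start), and all other windows must be motif-free — and the TU is
resampled on failure, with a hard cap of 200 attempts after which the
configuration is reported as infeasible. A single root seed feeds
per-component sub-seeds, so regeneration is byte-identical and adding one
generator does not perturb the others.

What the generator does **not** emulate: realistic base composition (GC
skew, codon usage), overlapping genes, TSS uncertainty, sequencing error in
junction reads, and gel-image artifacts. Passing the planted-recovery tests
therefore demonstrates the correctness of the coordinate arithmetic and
decision rules, not robustness to annotation noise in real genomes.

## Problem sizes and numerical choices

The test suite and the acceptance script run fixtures of 169 and 1,000
single-cistron TUs, a 293-TU / 879-distal-cistron operon set, 32 junction
reads, and a few hundred randomized property cases; the full suite completes
in well under a minute on one core. Percentages use half-up rounding at one
decimal; all other quantities are exact integer counts or plain floating
arithmetic with no tolerances beyond 1e-9 on the normalization identity.
Degenerate inputs are errors, not silent values: empty TU tables,
unquantifiable lanes, anchors absent from a read, strata of size zero
(reported as `NA` percent, never 0).

## Known limitations

- TUs are inputs; no operon or TSS prediction is attempted.
- The SD rule is binary and positional; no PWM scoring or free-energy model.
- Junction classification is exact-match and catalog-bound; it cannot
  separate biological intermediates from cloning truncations.
- The GFF3 path covers plain CDS features with `ID` attributes; richer gene
  models (joined CDS parts, frameshifts) are out of scope.
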