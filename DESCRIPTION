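Package: tirscan
Title: Translation Initiation Region Analysis for Archaeal Leaderless mRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-analysis toolkit for translation initiation regions in
    archaea dominated by leaderless mRNAs. Classifies 5'UTR leaders from
    transcription start sites, scans upstream windows for exact
    Shine-Dalgarno motifs under a positional rule anchored on annotated or
    in-frame alternative start codons, stratifies signal frequencies by
    proximal versus distal cistron, scores SD:anti-SD duplex complementarity,
    classifies 16S rRNA 3'-end variants from circular-ligation junction
    reads, and quantifies toeprinting (primer-extension) band intensities.
    Includes a deterministic synthetic-data generator with planted ground
    truth so every stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
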