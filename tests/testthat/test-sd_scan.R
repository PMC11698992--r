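win <- function(seq, first = -nchar(seq)) {
  list(gene_id = "g", seq = seq, offset_of_first_base = first, truncated = FALSE)
}

test_that("exact motif search reports overlapping hits with -1 offsets", {
  expect_identical(nrow(find_motif_occurrences(win(strrep("C", 30)))), 0L)

  w <- win(paste0(strrep("C", 18), "GGAGG", strrep("C", 7)))  # 5' G at -12
  h <- find_motif_occurrences(w)
  expect_identical(h$motif, "GGAGG")
  expect_identical(h$offset_5prime, -12L)

  h <- find_motif_occurrences(win("GGAGGAGG"), motifs = "GGAGG")
  expect_identical(h$offset_5prime, c(-8L, -5L))             # overlap case

  # N never matches any motif position
  expect_identical(nrow(find_motif_occurrences(win("GGANGGAGN"), "GGAGG")), 0L)
  # RNA input is normalized
  h <- find_motif_occurrences(win("ccuGAGGcc"), motifs = "UGAGG")
  expect_identical(h$motif, "TGAGG")
})

test_that("motif search agrees with a brute-force oracle on random windows", {
  set.seed(101)
  motifs <- c("GGAGG", "TGAGG")
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    # GC-rich alphabet so motifs actually occur
    s <- rand_dna(n, alphabet = c("G", "G", "A", "C", "T"))
    w <- win(s)
    got <- find_motif_occurrences(w, motifs)
    exp <- oracle_motif_scan(s, w$offset_of_first_base, motifs)
    expect_identical(got[order(got$motif, got$offset_5prime), ],
                     exp[order(exp$motif, exp$offset_5prime), ],
                     ignore_attr = TRUE)
  }
})

test_that("reference start enumeration walks in-frame codons in the span", {
  # upstream: in-frame ATG at -9, out-of-frame GTG at -5 (ignored)
  up <- paste0(strrep("C", 16), "ATG", "CGTGCC")                 # 25 nt
  up <- paste0(strrep("C", 5), up)                               # 30 nt total
  cds <- paste0("ATG", "CCCGTG", strrep("GCA", 8), "TAA")        # GTG at +6
  fix <- tiny_gene_fixture(upstream = up, cds = cds, pad5 = strrep("A", 35))
  refs <- enumerate_reference_starts(fix$genome, fix$gene)
  expect_identical(refs$reference_start_offset[refs$reference_start == "annotated"], 0L)
  alt <- refs$reference_start_offset[refs$reference_start == "alternative"]
  expect_true(all(c(-9L, 6L) %in% alt))
  expect_true(all(alt %% 3L == 0L))
  expect_false(-5L %in% alt)
  expect_error(enumerate_reference_starts(fix$genome, fix$gene, span = c(-20L, 30L)),
               "multiples of 3")
})

test_that("positional rule is inclusive on [-18, -9] and uses alternative starts", {
  refs0 <- data.frame(reference_start = "annotated", reference_start_offset = 0L)
  hit_at <- function(o) data.frame(motif = "GGAGG", offset_5prime = o)
  expect_true(call_sd_signals(hit_at(-9L), refs0)$passes_rule)
  expect_true(call_sd_signals(hit_at(-18L), refs0)$passes_rule)
  expect_false(call_sd_signals(hit_at(-8L), refs0)$passes_rule)
  expect_false(call_sd_signals(hit_at(-19L), refs0)$passes_rule)

  # -21 of the annotated start is -12 of an upstream in-frame start at -9
  refs <- rbind(refs0, data.frame(reference_start = "alternative",
                                  reference_start_offset = -9L))
  calls <- call_sd_signals(hit_at(-21L), refs)
  expect_identical(calls$relative_offset, c(-21L, -12L))
  expect_identical(calls$passes_rule, c(FALSE, TRUE))
})

test_that("stratified summary counts genes once per motif and rounds half-up", {
  ann <- data.frame(
    gene_id = c(sprintf("p%03d", 1:169), sprintf("d%03d", 1:879)),
    role = rep(c("proximal", "distal"), c(169, 879)),
    leader_class = c(rep("leadered", 169), rep(NA, 879)))
  # 9 proximal genes pass for GGAGG, one of them twice (dedup check)
  calls <- data.frame(
    gene_id = c(sprintf("p%03d", 1:9), "p001", sprintf("d%03d", 1:72)),
    motif = "GGAGG",
    passes_rule = TRUE)
  s <- summarize_sd(calls, ann, motifs = "GGAGG")
  expect_identical(s$n_with_signal[s$stratum == "proximal"], 9L)
  expect_identical(s$percent[s$stratum == "proximal"], 5.3)
  expect_identical(s$n_with_signal[s$stratum == "distal"], 72L)
  expect_identical(s$percent[s$stratum == "distal"], 8.2)
  # recomputing percent from the counts reproduces the stored value
  expect_identical(s$percent,
                   floor(1000 * s$n_with_signal / s$n_total + 0.5) / 10)

  # empty stratum reports NA, not 0
  s0 <- summarize_sd(calls[0, ], ann[ann$role == "proximal", ][0, ], motifs = "GGAGG")
  expect_true(all(is.na(s0$percent)))

  # 0 of 10 flagged is 0.0, and 7/169 rounds to 4.1
  ann10 <- data.frame(gene_id = sprintf("p%d", 1:10), role = "proximal",
                      leader_class = "leadered")
  expect_identical(summarize_sd(calls[0, ], ann10, motifs = "GGAGG")$percent[1], 0)
  calls7 <- data.frame(gene_id = sprintf("p%03d", 1:7), motif = "TGAGG",
                       passes_rule = TRUE)
  s7 <- summarize_sd(calls7, ann, motifs = "TGAGG")
  expect_identical(s7$percent[s7$stratum == "proximal"], 4.1)
})

test_that("duplex scoring finds the longest contiguous antiparallel pairing", {
  # SD against the processed anti-SD tail: full 5-bp duplex
  expect_identical(longest_antiparallel_duplex("GGAGG", "CCUCC")$max_contiguous_bp, 5L)
  # against the genome-encoded tail: one fewer base pair
  expect_identical(longest_antiparallel_duplex("GGAGG", "CCUCA")$max_contiguous_bp, 4L)
  # any sequence against its reverse complement pairs end to end
  set.seed(7)
  for (i in 1:10) {
    s <- rand_dna(sample(4:12, 1))
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    expect_identical(longest_antiparallel_duplex(s, rc)$max_contiguous_bp, nchar(s))
  }
})

test_that("duplex scoring matches brute force, is symmetric, wobble monotone", {
  set.seed(55)
  for (i in 1:200) {
    a <- rand_dna(sample(3:12, 1))
    b <- rand_dna(sample(3:12, 1))
    d <- longest_antiparallel_duplex(a, b)$max_contiguous_bp
    expect_identical(d, oracle_duplex(a, b))
    expect_identical(longest_antiparallel_duplex(b, a)$max_contiguous_bp, d)
    dw <- longest_antiparallel_duplex(a, b, allow_wobble = TRUE)$max_contiguous_bp
    expect_identical(dw, oracle_duplex(a, b, allow_wobble = TRUE))
    expect_gte(dw, d)
  }
})

test_that("SD hits export to GFF3 with genomic coordinates and scores", {
  up <- paste0(strrep("C", 18), "GGAGG", strrep("C", 7))   # 5' G at -12
  fix <- tiny_gene_fixture(upstream = up, pad5 = strrep("A", 10))
  genes <- fix$gene
  calls <- scan_sd_signals(fix$genome, genes)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_sd_gff3(calls, genes, gff)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  f <- strsplit(lines[2], "\t")[[1]]
  expect_identical(f[3], "SD_signal")
  expect_identical(as.integer(f[6]), 12L)                  # score = -offset
  expect_identical(as.integer(f[4]), fix$gene$cds_start - 12L)
  expect_identical(as.integer(f[5]), fix$gene$cds_start - 12L + 4L)
})
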