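# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (character-by-character loops) so they cannot share a
# defect with the implementation they check.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# O(n*m) sliding-window motif scan over a window's sequence; returns offsets
# of each motif's 5' base in the window's -1 convention.
oracle_motif_scan <- function(win_seq, offset_of_first_base, motifs) {
  w <- strsplit(win_seq, "")[[1]]
  out <- list()
  for (m in motifs) {
    mc <- strsplit(m, "")[[1]]
    if (length(w) < length(mc)) next
    for (p in 1:(length(w) - length(mc) + 1)) {
      hit <- TRUE
      for (q in seq_along(mc)) {
        if (w[p + q - 1] != mc[q]) { hit <- FALSE; break }
      }
      if (hit) {
        out[[length(out) + 1]] <- data.frame(
          motif = m, offset_5prime = offset_of_first_base + p - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(motif = character(0), offset_5prime = integer(0),
                  stringsAsFactors = FALSE)
}

# Brute-force longest contiguous antiparallel duplex: try every pair of
# starting positions, extend while bases pair.
oracle_duplex <- function(a, b, allow_wobble = FALSE) {
  a <- strsplit(chartr("Uu", "TT", toupper(a)), "")[[1]]
  b <- strsplit(chartr("Uu", "TT", toupper(b)), "")[[1]]
  pairs <- function(x, y) {
    wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "G" & y == "C") | (x == "C" & y == "G")
    if (allow_wobble) wc | (x == "G" & y == "T") | (x == "T" & y == "G") else wc
  }
  best <- 0L
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      # a runs 5'->3' from i, b runs 3'->5' from j
      len <- 0L
      while (i + len <= length(a) && j - len >= 1 &&
             pairs(a[i + len], b[j - len])) {
        len <- len + 1L
      }
      best <- max(best, len)
    }
  }
  best
}

# Brute-force end-variant call: try every catalog entry as the read suffix
# ending at the junction, keep the longest that matches.
oracle_end_variant <- function(read, junction_index, catalog) {
  read <- chartr("Uu", "TT", toupper(read))
  best <- "other"; best_len <- 0L
  for (v in catalog) {
    vd <- chartr("Uu", "TT", toupper(v))
    w <- nchar(vd)
    if (junction_index >= w &&
        substr(read, junction_index - w + 1, junction_index) == vd &&
        w > best_len) {
      best <- v; best_len <- w
    }
  }
  best
}

# One-contig fixture: a plus-strand gene with a controlled upstream region.
# upstream is placed immediately 5' of the start codon.
tiny_gene_fixture <- function(upstream, cds = paste0("ATG", "GCTGCAGCT", "TAA"),
                              pad5 = "", pad3 = "AAAA") {
  contig <- paste0(pad5, upstream, cds, pad3)
  genome <- c(chr = contig)
  gene <- data.frame(gene_id = "g1", contig = "chr", strand = "+",
                     cds_start = nchar(pad5) + nchar(upstream) + 1L,
                     cds_end = nchar(pad5) + nchar(upstream) + nchar(cds),
                     stringsAsFactors = FALSE)
  list(genome = genome, gene = gene)
}
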