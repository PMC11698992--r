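#' Default Shine-Dalgarno motif sets
#'
#' The default set pairs GGAGG with UGAGG (TGAGG after U->T normalization),
#' the two motifs whose stratified frequencies are reported for this genome;
#' `sd_motifs_alt` holds the GGAGG/GGTGG pair used as the search set in the
#' upstream-window scan. Both are plain character vectors and any custom set
#' can be supplied wherever a `motifs` argument appears.
#'
#' @format Character vector of DNA motifs.
#' @export
sd_motifs_default <- c("GGAGG", "TGAGG")

#' @rdname sd_motifs_default
#' @export
sd_motifs_alt <- c("GGAGG", "GGTGG")

check_motifs <- function(motifs) {
  motifs <- normalize_seq(motifs)
  if (length(motifs) == 0L) stop("motif set must be non-empty", call. = FALSE)
  if (any(nchar(motifs) < 3L)) stop("motifs must be at least 3 nt long", call. = FALSE)
  assert_dna(motifs, what = "motif", allow_n = FALSE)
  motifs
}

#' Find exact motif occurrences in an upstream window
#'
#' Reports every exact, possibly overlapping occurrence of each motif. N
#' bases never match. Offsets use the -1 convention of the window: the
#' reported `offset_5prime` is the offset of the motif's 5' base relative to
#' the first base of the start codon.
#'
#' @param window A window as returned by [extract_upstream_window()] (list or
#'   one-row data.frame with `seq` and `offset_of_first_base`).
#' @param motifs Character vector of motifs (default [sd_motifs_default]).
#' @return `data.frame` with columns `motif` and `offset_5prime` (0 rows when
#'   nothing matches).
#' @export
find_motif_occurrences <- function(window, motifs = sd_motifs_default) {
  motifs <- check_motifs(motifs)
  win <- normalize_seq(window$seq)
  n <- nchar(win)
  out <- lapply(motifs, function(m) {
    w <- nchar(m)
    if (n < w) return(NULL)
    starts <- seq_len(n - w + 1L)
    at <- starts[substring(win, starts, starts + w - 1L) == m]
    if (!length(at)) return(NULL)
    data.frame(motif = m,
               offset_5prime = window$offset_of_first_base + at - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(motif = character(0), offset_5prime = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}

# mRNA-sense codon whose first base sits `offset` nt from the first base of
# the annotated start codon (offset 0 = the annotated start itself). NA when
# the codon falls off the contig.
codon_at_offset <- function(genome, gene, offset) {
  seq <- contig_of(genome, gene)
  n <- nchar(seq)
  if (gene$strand == "+") {
    p <- gene$cds_start + offset
    if (p < 1L || p + 2L > n) return(NA_character_)
    substr(seq, p, p + 2L)
  } else {
    p <- gene$cds_end - offset
    if (p > n || p - 2L < 1L) return(NA_character_)
    revcomp(substr(seq, p - 2L, p))
  }
}

#' Enumerate reference start codons for the positional rule
#'
#' Returns the annotated start (frame offset 0) plus every in-frame
#' occurrence of a configured start codon whose first base lies within a span
#' around the annotated start. In-frame alternative starts give the
#' positional rule additional anchors.
#'
#' @param genome Named character vector from [read_genome_fasta()].
#' @param gene One-row gene-model data.frame or list.
#' @param start_codons Start-codon set (default ATG/GTG/TTG).
#' @param span Two integers, both multiples of 3: the offset range scanned
#'   for alternative starts (default `c(-30, 30)`).
#' @return `data.frame` with `reference_start` ("annotated"/"alternative")
#'   and `reference_start_offset` (multiple of 3; 0 for the annotated start).
#' @export
enumerate_reference_starts <- function(genome, gene,
                                       start_codons = c("ATG", "GTG", "TTG"),
                                       span = c(-30L, 30L)) {
  start_codons <- normalize_seq(start_codons)
  if (any(span %% 3L != 0L)) stop("span bounds must be multiples of 3", call. = FALSE)
  offs <- seq(span[1], span[2], by = 3L)
  offs <- offs[offs != 0L]
  alt <- offs[vapply(offs, function(d) {
    cod <- codon_at_offset(genome, gene, d)
    !is.na(cod) && cod %in% start_codons
  }, logical(1))]
  data.frame(
    reference_start = c("annotated", rep("alternative", length(alt))),
    reference_start_offset = c(0L, as.integer(alt)),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the SD positional rule for motif hits
#'
#' A hit is an SD signal when the motif's 5' base lies between `rule[1]` and
#' `rule[2]` (inclusive; default -18 and -9) of the annotated start codon or
#' of an in-frame alternative start. Each (hit, reference start) pair is
#' evaluated: the hit's offset relative to that reference is
#' `offset_5prime - reference_start_offset`.
#'
#' @param hits Output of [find_motif_occurrences()] (offsets relative to the
#'   annotated start).
#' @param reference_starts Output of [enumerate_reference_starts()].
#' @param rule Two integers: inclusive offset bounds (default `c(-18, -9)`).
#' @param gene_id Gene id to stamp on the calls.
#' @return `data.frame` of SD hit evaluations: `gene_id`, `motif`,
#'   `offset_5prime`, `reference_start`, `reference_start_offset`,
#'   `relative_offset`, `passes_rule`.
#' @export
call_sd_signals <- function(hits, reference_starts, rule = c(-18L, -9L),
                            gene_id = NA_character_) {
  if (rule[1] > rule[2]) stop("rule bounds must satisfy rule[1] <= rule[2]", call. = FALSE)
  if (nrow(hits) == 0L || nrow(reference_starts) == 0L) {
    return(data.frame(gene_id = character(0), motif = character(0),
                      offset_5prime = integer(0), reference_start = character(0),
                      reference_start_offset = integer(0),
                      relative_offset = integer(0), passes_rule = logical(0),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(h = seq_len(nrow(hits)), r = seq_len(nrow(reference_starts)))
  rel <- hits$offset_5prime[grid$h] - reference_starts$reference_start_offset[grid$r]
  data.frame(
    gene_id = gene_id,
    motif = hits$motif[grid$h],
    offset_5prime = hits$offset_5prime[grid$h],
    reference_start = reference_starts$reference_start[grid$r],
    reference_start_offset = reference_starts$reference_start_offset[grid$r],
    relative_offset = as.integer(rel),
    passes_rule = rel >= rule[1] & rel <= rule[2],
    stringsAsFactors = FALSE
  )
}

#' Scan a genome for SD signals
#'
#' Full scan: extracts the upstream window of every gene, finds exact motif
#' occurrences, enumerates reference starts and applies the positional rule.
#'
#' @inheritParams extract_upstream_windows
#' @inheritParams enumerate_reference_starts
#' @inheritParams call_sd_signals
#' @param motifs Motif set (default [sd_motifs_default]).
#' @return `data.frame` of SD hit evaluations over all genes (see
#'   [call_sd_signals()]).
#' @export
scan_sd_signals <- function(genome, genes, motifs = sd_motifs_default,
                            width = 30L, rule = c(-18L, -9L),
                            start_codons = c("ATG", "GTG", "TTG"),
                            span = c(-30L, 30L),
                            tus = NULL, respect_tss = FALSE) {
  motifs <- check_motifs(motifs)
  windows <- extract_upstream_windows(genome, genes, width = width,
                                      tus = tus, respect_tss = respect_tss)
  calls <- lapply(seq_len(nrow(genes)), function(i) {
    w <- windows[i, ]
    hits <- find_motif_occurrences(w, motifs)
    refs <- enumerate_reference_starts(genome, genes[i, ],
                                       start_codons = start_codons, span = span)
    call_sd_signals(hits, refs, rule = rule, gene_id = genes$gene_id[i])
  })
  do.call(rbind, calls)
}

#' Per-gene SD signal flags
#'
#' A gene carries a signal for a motif when at least one of its hits passes
#' the positional rule for at least one reference start; multiple passing
#' hits still count once.
#'
#' @param calls Output of [scan_sd_signals()] or [call_sd_signals()].
#' @param gene_ids Genes to report (default: all genes present in `calls`).
#' @param motifs Motif set.
#' @return `data.frame` with `gene_id`, `motif`, `has_signal`.
#' @export
gene_sd_flags <- function(calls, gene_ids = unique(calls$gene_id),
                          motifs = sd_motifs_default) {
  motifs <- check_motifs(motifs)
  grid <- expand.grid(gene_id = gene_ids, motif = motifs,
                      stringsAsFactors = FALSE)
  pass <- calls[calls$passes_rule, c("gene_id", "motif"), drop = FALSE]
  key <- paste(grid$gene_id, grid$motif, sep = "\r")
  grid$has_signal <- key %in% paste(pass$gene_id, pass$motif, sep = "\r")
  grid
}

#' Stratified SD summary
#'
#' Counts and percentages of genes with an SD signal per motif and cistron
#' stratum. The proximal stratum is restricted to leadered proximal cistrons
#' (leaderless and short-leader mRNAs have no room for an SD duplex); the
#' distal stratum includes all distal cistrons.
#'
#' @param calls Output of [scan_sd_signals()].
#' @param leader_annotations Output of [annotate_leaders()].
#' @param motifs Motif set.
#' @return `data.frame` with `stratum`, `motif`, `n_total`, `n_with_signal`,
#'   `percent` (one decimal, half-up; `NA` when `n_total` is 0).
#' @export
summarize_sd <- function(calls, leader_annotations, motifs = sd_motifs_default) {
  motifs <- check_motifs(motifs)
  strata <- list(
    proximal = leader_annotations$gene_id[
      leader_annotations$role == "proximal" &
        !is.na(leader_annotations$leader_class) &
        leader_annotations$leader_class == "leadered"],
    distal = leader_annotations$gene_id[leader_annotations$role == "distal"]
  )
  rows <- list()
  for (s in names(strata)) {
    ids <- strata[[s]]
    flags <- if (length(ids)) gene_sd_flags(calls, gene_ids = ids, motifs = motifs)
             else NULL
    for (m in motifs) {
      n_total <- length(ids)
      n_sig <- if (n_total) sum(flags$has_signal[flags$motif == m]) else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, motif = m, n_total = n_total,
        n_with_signal = as.integer(n_sig),
        percent = if (n_total) round_half_up(100 * n_sig / n_total, 1) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Longest contiguous antiparallel duplex between two sequences
#'
#' Scores SD:anti-SD complementarity: the maximum number of contiguous
#' antiparallel Watson-Crick base pairs (optionally including G:U wobble)
#' over all relative alignments of the two strands. Both inputs are read
#' 5' to 3'; RNA and DNA are accepted.
#'
#' @param seq_a,seq_b Nucleotide strings, 5' to 3'.
#' @param allow_wobble Also count G:U (G:T) pairs (default `FALSE`).
#' @return List with `max_contiguous_bp`, `pairing_start_offsets` (1-based 5'
#'   positions of the best duplex in `seq_a` and `seq_b`) and `allow_wobble`.
#' @export
longest_antiparallel_duplex <- function(seq_a, seq_b, allow_wobble = FALSE) {
  a <- strsplit(normalize_seq(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(normalize_seq(seq_b), "", fixed = TRUE)[[1]]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both sequences must be non-empty", call. = FALSE)
  pairs <- c(A = "T", T = "A", G = "C", C = "G")
  is_pair <- function(x, y) {
    ok <- !is.na(pairs[x]) & pairs[x] == y
    if (allow_wobble) ok <- ok | (x == "G" & y == "T") | (x == "T" & y == "G")
    ok
  }
  rb <- rev(b)  # rb[j] is b[nb - j + 1]; a[i] : rb[i - s] is antiparallel
  best <- 0L; best_a <- NA_integer_; best_b <- NA_integer_
  for (s in (1L - nb):(na - 1L)) {
    i <- max(1L, s + 1L):min(na, s + nb)
    ok <- is_pair(a[i], rb[i - s])
    r <- rle(ok)
    if (!any(r$values)) next
    runs <- which(r$values)
    lens <- r$lengths[runs]
    k <- runs[which.max(lens)]
    len <- max(lens)
    if (len > best) {
      best <- len
      start_i <- i[1] + if (k > 1L) sum(r$lengths[1:(k - 1L)]) else 0L
      j_last <- (start_i + len - 1L) - s          # rb index of run's last pair
      best_a <- start_i
      best_b <- nb - j_last + 1L                  # 5' start of run on b
    }
  }
  list(max_contiguous_bp = as.integer(best),
       pairing_start_offsets = c(a = best_a, b = best_b),
       allow_wobble = allow_wobble)
}

#' Write SD hits as GFF3
#'
#' One `SD_signal` feature per distinct (gene, motif, offset) hit; the score
#' column carries the negated offset of the motif's 5' base relative to the
#' annotated start codon.
#'
#' @param calls Output of [scan_sd_signals()].
#' @param genes Gene-model table (for genomic coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sd_gff3 <- function(calls, genes, path) {
  ann <- calls[calls$reference_start == "annotated", , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "motif", "offset_5prime", "passes_rule")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  pass_by <- tapply(calls$passes_rule, paste(calls$gene_id, calls$motif,
                                             calls$offset_5prime, sep = "\r"), any)
  for (i in seq_len(nrow(ann))) {
    g <- genes[genes$gene_id == ann$gene_id[i], ]
    w <- nchar(ann$motif[i]); o <- ann$offset_5prime[i]
    if (g$strand == "+") {
      s <- g$cds_start + o; e <- s + w - 1L
    } else {
      e <- g$cds_end - o; s <- e - w + 1L
    }
    key <- paste(ann$gene_id[i], ann$motif[i], o, sep = "\r")
    writeLines(paste(g$contig, "tirscan", "SD_signal", s, e, -o, g$strand, ".",
                     sprintf("ID=sd_%s_%s_%d;gene=%s;motif=%s;passes_rule=%s",
                             ann$gene_id[i], ann$motif[i], -o, ann$gene_id[i],
                             ann$motif[i], tolower(as.character(pass_by[[key]]))),
                     sep = "\t"), con)
  }
  invisible(path)
}
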