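#' Read a genome FASTA file
#'
#' Reads nucleotide sequences and normalizes them to the uppercase DNA
#' alphabet (U is mapped to T, lowercase to uppercase). The result is the
#' genome container used throughout the package.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record; names are contig
#'   ids (first whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_seq(as.character(set))
  assert_dna(seqs, what = paste0("FASTA record in ", path))
  if (any(nchar(seqs) == 0L)) stop("zero-length FASTA record in ", path, call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(normalize_seq(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene-model table
#'
#' Gene models arrive as a TSV with columns `gene_id`, `contig`, `strand`,
#' `cds_start`, `cds_end` (1-based inclusive genomic coordinates; for minus
#' strand genes the first base of the start codon is `cds_end`).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of gene models.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "strand", "cds_start", "cds_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df$cds_start <- as.integer(df$cds_start)
  df$cds_end <- as.integer(df$cds_end)
  validate_gene_models(df)
  df[need]
}

#' Read gene models from GFF3
#'
#' Accepts GFF3 with CDS features carrying an `ID` attribute. Requires the
#' rtracklayer package.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with the same columns as [read_gene_table()].
#' @export
read_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[as.character(gr$type) == "CDS", , drop = FALSE]
  if (nrow(gr) == 0L) stop("no CDS features in ", path, call. = FALSE)
  df <- data.frame(
    gene_id = as.character(gr$ID),
    contig = as.character(gr$seqnames),
    strand = as.character(gr$strand),
    cds_start = as.integer(gr$start),
    cds_end = as.integer(gr$end),
    stringsAsFactors = FALSE
  )
  validate_gene_models(df)
  df
}

validate_gene_models <- function(genes) {
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table", call. = FALSE)
  bad <- genes$cds_start > genes$cds_end
  if (any(bad)) stop("cds_start > cds_end for gene ", genes$gene_id[which(bad)[1]], call. = FALSE)
  len <- genes$cds_end - genes$cds_start + 1L
  if (any(len %% 3L != 0L)) {
    stop("CDS length not a multiple of 3 for gene ",
         genes$gene_id[which(len %% 3L != 0L)[1]], call. = FALSE)
  }
  invisible(genes)
}

#' Start codon of a gene on the mRNA sense strand
#'
#' @param genome Named character vector from [read_genome_fasta()].
#' @param gene One-row gene-model data.frame (or list) with `contig`,
#'   `strand`, `cds_start`, `cds_end`.
#' @return 3-character string, mRNA sense (DNA alphabet).
#' @export
start_codon_of <- function(genome, gene) {
  seq <- contig_of(genome, gene)
  if (gene$strand == "+") {
    substr(seq, gene$cds_start, gene$cds_start + 2L)
  } else {
    revcomp(substr(seq, gene$cds_end - 2L, gene$cds_end))
  }
}

contig_of <- function(genome, gene) {
  if (!gene$contig %in% names(genome)) {
    stop("gene ", gene$gene_id %||% "?", " references unknown contig '",
         gene$contig, "'", call. = FALSE)
  }
  genome[[gene$contig]]
}

#' Read a transcription-unit table
#'
#' TSV with columns `tu_id`, `contig`, `strand`, `tss` (1-based genomic
#' coordinate of the first transcribed base) and `genes` (comma-separated
#' gene ids ordered 5' to 3' in transcript direction; the first is the
#' proximal cistron).
#'
#' @param path Path to the TSV file.
#' @param genes Optional gene-model table; when given, TU/gene consistency is
#'   validated (genes exist, strands and contigs agree, cistrons are ordered,
#'   the proximal start codon is not upstream of the TSS).
#' @return A `data.frame` with columns `tu_id`, `contig`, `strand`, `tss`,
#'   `genes`.
#' @export
read_tu_table <- function(path, genes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tu_id", "contig", "strand", "tss", "genes")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TU table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df$tss <- as.integer(df$tss)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("TU strand must be '+' or '-' (offending tu: ",
         df$tu_id[which(!df$strand %in% c("+", "-"))[1]], ")", call. = FALSE)
  }
  if (any(!nzchar(df$genes))) stop("TU with empty cistron list", call. = FALSE)
  if (!is.null(genes)) validate_tus(df, genes)
  df[need]
}

tu_cistrons <- function(tu) strsplit(tu$genes, ",", fixed = TRUE)[[1]]

validate_tus <- function(tus, genes) {
  for (i in seq_len(nrow(tus))) {
    tu <- tus[i, ]
    cis <- tu_cistrons(tu)
    missing <- setdiff(cis, genes$gene_id)
    if (length(missing)) {
      stop("TU ", tu$tu_id, " references unknown gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    g <- genes[match(cis, genes$gene_id), ]
    if (any(g$strand != tu$strand) || any(g$contig != tu$contig)) {
      stop("TU ", tu$tu_id, " has cistrons on a different strand or contig", call. = FALSE)
    }
    firsts <- ifelse(g$strand == "+", g$cds_start, g$cds_end)
    ord <- if (tu$strand == "+") !is.unsorted(firsts, strictly = TRUE)
           else !is.unsorted(rev(firsts), strictly = TRUE)
    if (!ord) stop("TU ", tu$tu_id, " cistrons not ordered 5'->3'", call. = FALSE)
    prox_first <- firsts[1]
    downstream_ok <- if (tu$strand == "+") prox_first >= tu$tss else prox_first <= tu$tss
    if (!downstream_ok) {
      stop("TU ", tu$tu_id, ": proximal start codon lies upstream of the TSS", call. = FALSE)
    }
  }
  invisible(tus)
}

#' Extract the upstream window of a gene
#'
#' Returns the `width` bases immediately 5' of the start codon on the mRNA
#' sense strand (minus-strand genes are reverse-complemented so the window
#' always reads 5' to 3' on the mRNA). Offsets follow the -1 convention: the
#' base immediately preceding the first base of the start codon has offset
#' -1, so a full window spans offsets `-width .. -1`.
#'
#' By default the window is not clipped at the TSS: the scan covers a fixed
#' 30-nt region even for leaderless genes, where it extends past the TSS into
#' upstream DNA. Set `respect_tss = TRUE` (and supply `tss`) to clip.
#'
#' @param genome Named character vector from [read_genome_fasta()].
#' @param gene One-row gene-model data.frame or list.
#' @param width Window width in nucleotides (default 30).
#' @param tss Optional TSS coordinate of the gene's transcription unit.
#' @param respect_tss Clip the window at the TSS (default `FALSE`).
#' @return List with `gene_id`, `seq`, `offset_of_first_base`, `truncated`.
#' @export
extract_upstream_window <- function(genome, gene, width = 30L,
                                    tss = NULL, respect_tss = FALSE) {
  if (width <= 0L) stop("width must be positive", call. = FALSE)
  seq <- contig_of(genome, gene)
  n <- nchar(seq)
  if (gene$cds_start < 1L || gene$cds_end > n) {
    stop("gene ", gene$gene_id, " lies outside contig ", gene$contig, call. = FALSE)
  }
  truncated <- FALSE
  if (gene$strand == "+") {
    hi <- gene$cds_start - 1L
    lo <- gene$cds_start - width
    if (lo < 1L) { lo <- 1L; truncated <- TRUE }
    if (respect_tss && !is.null(tss) && lo < tss) { lo <- as.integer(tss); truncated <- TRUE }
    win <- if (hi >= lo) substr(seq, lo, hi) else ""
  } else {
    lo <- gene$cds_end + 1L
    hi <- gene$cds_end + width
    if (hi > n) { hi <- n; truncated <- TRUE }
    if (respect_tss && !is.null(tss) && hi > tss) { hi <- as.integer(tss); truncated <- TRUE }
    win <- if (hi >= lo) revcomp(substr(seq, lo, hi)) else ""
  }
  if (nchar(win) == 0L) truncated <- TRUE
  list(gene_id = gene$gene_id, seq = win,
       offset_of_first_base = -nchar(win), truncated = truncated)
}

#' Extract upstream windows for a gene table
#'
#' @inheritParams extract_upstream_window
#' @param genes Gene-model table.
#' @param tus Optional TU table used to look up per-gene TSS when
#'   `respect_tss = TRUE`.
#' @return `data.frame` with one row per gene: `gene_id`, `seq`,
#'   `offset_of_first_base`, `truncated`.
#' @export
extract_upstream_windows <- function(genome, genes, width = 30L,
                                     tus = NULL, respect_tss = FALSE) {
  tss_of <- rep(NA_integer_, nrow(genes))
  if (!is.null(tus)) {
    for (i in seq_len(nrow(tus))) {
      cis <- tu_cistrons(tus[i, ])
      tss_of[genes$gene_id %in% cis] <- tus$tss[i]
    }
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    w <- extract_upstream_window(
      genome, genes[i, ], width = width,
      tss = if (is.na(tss_of[i])) NULL else tss_of[i],
      respect_tss = respect_tss
    )
    data.frame(gene_id = w$gene_id, seq = w$seq,
               offset_of_first_base = w$offset_of_first_base,
               truncated = w$truncated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
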