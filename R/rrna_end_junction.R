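#' Default 3'-end variant catalog for the 16S rRNA circularization assay
#'
#' Variants are labelled in the RNA alphabet as read from clone sequences:
#' the processed 3' end (CCUCC), the genome-encoded end (CCUCA) and the two
#' intermediate trimmed forms (CCUC, CCU). Matching is done after U->T
#' normalization; longer entries take precedence.
#'
#' @format Character vector ordered by decreasing length.
#' @export
end_variant_catalog <- c("CCUCC", "CCUCA", "CCUC", "CCU")

#' Locate the circularization junction in a read
#'
#' A circularized-rRNA junction read contains the molecule's 3'-end variant
#' immediately followed by its 5' start. The junction is located by finding
#' the occurrence of the 5'-start anchor whose downstream sequence agrees
#' best with the known 5' region; ties go to the leftmost occurrence.
#'
#' @param read_seq Read sequence (RNA or DNA).
#' @param five_prime_anchor 5'-terminal anchor of the molecule (default
#'   `"AAUCC"`, the mapped 16S rRNA 5' end).
#' @param reference_5prime Known 5'-region sequence beginning with the
#'   anchor, used to disambiguate multiple anchor occurrences.
#' @param max_mismatch Mismatches tolerated in the anchor itself (default 0).
#' @return Integer junction index: the number of read bases 5' of the
#'   junction (0 when the read starts at the anchor), i.e. the length of the
#'   3'-end side of the read.
#' @export
locate_junction <- function(read_seq, five_prime_anchor = "AAUCC",
                            reference_5prime = five_prime_anchor,
                            max_mismatch = 0L) {
  read <- normalize_seq(read_seq)
  anchor <- normalize_seq(five_prime_anchor)
  ref <- normalize_seq(reference_5prime)
  if (nchar(anchor) < 5L) stop("anchor must be at least 5 nt", call. = FALSE)
  if (substr(ref, 1L, nchar(anchor)) != anchor) {
    stop("reference_5prime must begin with the anchor", call. = FALSE)
  }
  n <- nchar(read); w <- nchar(anchor)
  starts <- seq_len(max(0L, n - w + 1L))
  mm <- vapply(starts, function(p) {
    sum(strsplit(substr(read, p, p + w - 1L), "")[[1]] !=
          strsplit(anchor, "")[[1]])
  }, integer(1))
  cand <- starts[mm <= max_mismatch]
  if (!length(cand)) {
    stop("5' anchor '", five_prime_anchor, "' not found in read", call. = FALSE)
  }
  # agreement: length of the exact match between the read from the anchor on
  # and the reference 5' region
  agree <- vapply(cand, function(p) {
    x <- strsplit(substr(read, p, n), "")[[1]]
    y <- strsplit(ref, "")[[1]]
    k <- min(length(x), length(y))
    if (k == 0L) return(0L)
    d <- which(x[seq_len(k)] != y[seq_len(k)])
    if (length(d)) d[1] - 1L else k
  }, integer(1))
  best <- cand[which.max(agree)]  # which.max takes the leftmost on ties
  best - 1L
}

#' Classify the 3'-end variant of a junction read
#'
#' The longest catalog entry that exactly matches the read suffix ending at
#' the junction wins; reads matching no entry are called `"other"`.
#'
#' @param read_seq Read sequence.
#' @param junction_index Output of [locate_junction()].
#' @param catalog Variant catalog (default [end_variant_catalog]); labels may
#'   be RNA or DNA, reported labels keep the catalog's spelling.
#' @return List with `variant`, `junction_index` and `matched_suffix` (empty
#'   string for `"other"`).
#' @export
classify_end_variant <- function(read_seq, junction_index,
                                 catalog = end_variant_catalog) {
  read <- normalize_seq(read_seq)
  if (junction_index < 0L || junction_index > nchar(read)) {
    stop("junction_index out of range", call. = FALSE)
  }
  cat_dna <- normalize_seq(catalog)
  ord <- order(nchar(cat_dna), decreasing = TRUE)
  prefix <- substr(read, 1L, junction_index)
  for (k in ord) {
    w <- nchar(cat_dna[k])
    if (junction_index >= w &&
        substr(prefix, junction_index - w + 1L, junction_index) == cat_dna[k]) {
      return(list(variant = catalog[k], junction_index = junction_index,
                  matched_suffix = catalog[k]))
    }
  }
  list(variant = "other", junction_index = junction_index, matched_suffix = "")
}

#' Classify every junction read in a FASTA file or sequence set
#'
#' @param reads Named character vector of read sequences, or a FASTA path.
#' @inheritParams locate_junction
#' @inheritParams classify_end_variant
#' @return `data.frame` with `read_id`, `variant`, `junction_index`,
#'   `matched_suffix`.
#' @export
classify_junction_reads <- function(reads, five_prime_anchor = "AAUCC",
                                    reference_5prime = five_prime_anchor,
                                    catalog = end_variant_catalog,
                                    max_mismatch = 0L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_genome_fasta(reads)
  }
  ids <- names(reads) %||% as.character(seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    j <- locate_junction(reads[[i]], five_prime_anchor, reference_5prime,
                         max_mismatch = max_mismatch)
    v <- classify_end_variant(reads[[i]], j, catalog = catalog)
    data.frame(read_id = ids[i],
               variant = v$variant, junction_index = v$junction_index,
               matched_suffix = v$matched_suffix, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tally 3'-end variant calls
#'
#' @param calls Output of [classify_junction_reads()] (or any data.frame with
#'   a `variant` column).
#' @param catalog Variant catalog fixing the output order; `"other"` is
#'   always appended.
#' @return `data.frame` with `variant`, `n`; counts sum to `nrow(calls)` and
#'   the row order is deterministic (catalog order, then `"other"`).
#' @export
tally_variants <- function(calls, catalog = end_variant_catalog) {
  if (nrow(calls) == 0L) stop("no calls to tally", call. = FALSE)
  lev <- c(catalog, "other")
  unknown <- setdiff(unique(calls$variant), lev)
  if (length(unknown)) {
    stop("calls contain variants absent from the catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- vapply(lev, function(v) sum(calls$variant == v), integer(1))
  data.frame(variant = lev, n = as.integer(n), stringsAsFactors = FALSE)
}
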