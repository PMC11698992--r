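#' Leader length of a proximal cistron
#'
#' Number of transcribed nucleotides strictly 5' of the first base of the
#' start codon; 0 when the TSS coincides with the start codon.
#'
#' @param tu One-row TU data.frame or list (`tu_id`, `strand`, `tss`, `genes`).
#' @param gene One-row gene-model data.frame or list; must be the proximal
#'   cistron of `tu`.
#' @return Integer leader length in nucleotides.
#' @export
leader_length <- function(tu, gene) {
  cis <- tu_cistrons(tu)
  if (cis[1] != gene$gene_id) {
    stop("gene ", gene$gene_id, " is not the proximal cistron of TU ", tu$tu_id,
         call. = FALSE)
  }
  first <- if (gene$strand == "+") gene$cds_start else gene$cds_end
  len <- if (tu$strand == "+") first - tu$tss else tu$tss - first
  if (len < 0L) {
    stop("TU ", tu$tu_id, ": TSS lies downstream of the start codon", call. = FALSE)
  }
  as.integer(len)
}

#' Classify a 5'UTR length into leader classes
#'
#' Leaderless mRNAs carry at most 5 nt of 5'UTR, short leaders span 6-10 nt,
#' and leadered mRNAs carry at least 11 nt. The three classes tile the
#' non-negative integers.
#'
#' @param length Integer vector of leader lengths (nt), all `>= 0`; `NA`
#'   propagates (used for distal cistrons, whose transcript 5'UTR is not
#'   defined).
#' @return Character vector of classes: `"leaderless"`, `"short_leader"`,
#'   `"leadered"` (or `NA`).
#' @export
classify_leader <- function(length) {
  if (any(!is.na(length) & length < 0)) stop("leader length must be >= 0", call. = FALSE)
  out <- rep(NA_character_, length(length))
  out[!is.na(length) & length <= 5] <- "leaderless"
  out[!is.na(length) & length >= 6 & length <= 10] <- "short_leader"
  out[!is.na(length) & length >= 11] <- "leadered"
  out
}

leader_classes <- c("leaderless", "short_leader", "leadered")

#' Annotate cistron roles and leader classes for a TU table
#'
#' @param tus TU table (see [read_tu_table()]).
#' @param genes Gene-model table.
#' @return `data.frame` with `gene_id`, `tu_id`, `role` (proximal/distal),
#'   `leader_length` (NA for distal cistrons) and `leader_class`.
#' @export
annotate_leaders <- function(tus, genes) {
  rows <- lapply(seq_len(nrow(tus)), function(i) {
    tu <- tus[i, ]
    cis <- tu_cistrons(tu)
    g <- genes[match(cis, genes$gene_id), ]
    if (any(is.na(g$gene_id))) {
      stop("TU ", tu$tu_id, " references unknown gene(s)", call. = FALSE)
    }
    ll <- leader_length(tu, g[1, ])
    data.frame(
      gene_id = cis,
      tu_id = tu$tu_id,
      role = c("proximal", rep("distal", length(cis) - 1L)),
      leader_length = c(ll, rep(NA_integer_, length(cis) - 1L)),
      stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, rows)
  ann$leader_class <- classify_leader(ann$leader_length)
  ann
}

#' Summarize leader-class proportions over proximal cistrons
#'
#' @param annotations Output of [annotate_leaders()] (or any data.frame with
#'   `role` and `leader_class`).
#' @return `data.frame` with `leader_class`, `n` and `percent` (one decimal,
#'   half-up), over proximal cistrons only.
#' @export
summarize_leader_classes <- function(annotations) {
  prox <- annotations[annotations$role == "proximal", , drop = FALSE]
  if (nrow(prox) == 0L) stop("no proximal cistrons to summarize", call. = FALSE)
  n <- vapply(leader_classes, function(cl) sum(prox$leader_class == cl), integer(1))
  data.frame(
    leader_class = leader_classes,
    n = as.integer(n),
    percent = round_half_up(100 * n / nrow(prox), 1),
    stringsAsFactors = FALSE
  )
}
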