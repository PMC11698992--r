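#' Run the full translation-initiation-region pipeline
#'
#' Executes leader classification, the SD scan with stratified summary and,
#' when the corresponding inputs are given, junction-read classification and
#' toeprint quantification. Inputs may be in-memory objects or file paths
#' (FASTA for sequences, TSV for tables). Stage outputs are plain files so
#' every stage can be re-run independently; there is no hidden state.
#'
#' @param genome Genome: named character vector or FASTA path.
#' @param genes Gene models: data.frame, TSV path or GFF3 path (`.gff`/`.gff3`).
#' @param tus Transcription units: data.frame or TSV path.
#' @param junction_reads Optional junction reads: named character vector or
#'   FASTA path.
#' @param toeprint_table Optional toeprint lanes: data.frame or TSV path.
#' @param out_dir Optional output directory; when given, per-stage TSV/GFF3
#'   files and `report.json` are written there.
#' @param motifs,width,rule,start_codons,span,respect_tss SD-scan parameters.
#' @param anchor,reference_5prime,catalog Junction-stage parameters.
#' @param reference_condition Toeprint normalization reference.
#' @return A report list: `leader_summary`, `sd_summary`, optional
#'   `junction_tally`, `toeprint_summary`, and a `manifest` (package version,
#'   input checksums, per-stage row counts).
#' @export
run_pipeline <- function(genome, genes, tus,
                         junction_reads = NULL, toeprint_table = NULL,
                         out_dir = NULL,
                         motifs = sd_motifs_default, width = 30L,
                         rule = c(-18L, -9L),
                         start_codons = c("ATG", "GTG", "TTG"),
                         span = c(-30L, 30L), respect_tss = FALSE,
                         anchor = "AAUCC", reference_5prime = anchor,
                         catalog = end_variant_catalog,
                         reference_condition = "monophosphate") {
  checksums <- list()
  take <- function(x, reader, label) {
    if (is.character(x) && length(x) == 1L && is.null(names(x))) {
      if (!file.exists(x)) stop("missing input for ", label, ": ", x, call. = FALSE)
      checksums[[label]] <<- unname(tools::md5sum(x))
      reader(x)
    } else x
  }
  genome <- take(genome, read_genome_fasta, "genome")
  genes <- take(genes, function(p) {
    if (grepl("\\.gff3?$", p)) read_gene_models_gff3(p) else read_gene_table(p)
  }, "genes")
  tus <- take(tus, read_tu_table, "tus")
  if (nrow(tus) == 0L) stop("TU table is empty: nothing to classify", call. = FALSE)
  validate_tus(tus, genes)

  ann <- annotate_leaders(tus, genes)
  leader_summary <- summarize_leader_classes(ann)
  calls <- scan_sd_signals(genome, genes, motifs = motifs, width = width,
                           rule = rule, start_codons = start_codons,
                           span = span, tus = tus, respect_tss = respect_tss)
  sd_summary <- summarize_sd(calls, ann, motifs = motifs)

  report <- list(leader_annotations = ann, leader_summary = leader_summary,
                 sd_calls = calls, sd_summary = sd_summary)

  if (!is.null(junction_reads)) {
    junction_reads <- take(junction_reads, read_genome_fasta, "junction_reads")
    jcalls <- classify_junction_reads(junction_reads, anchor, reference_5prime,
                                      catalog = catalog)
    report$junction_calls <- jcalls
    report$junction_tally <- tally_variants(jcalls, catalog = catalog)
  }
  if (!is.null(toeprint_table)) {
    toeprint_table <- take(toeprint_table, read_toeprint_table, "toeprint")
    tstats <- toeprint_stats(toeprint_table)
    tstats <- tryCatch(normalize_to_reference(tstats, reference_condition),
                       error = function(e) tstats)
    report$toeprint_stats <- tstats
    report$toeprint_summary <- summarize_conditions(tstats)
  }

  report$manifest <- list(
    tool = "tirscan",
    version = as.character(utils::packageVersion("tirscan")),
    inputs_md5 = checksums,
    rows = list(genes = nrow(genes), tus = nrow(tus),
                sd_calls = nrow(calls),
                junction_reads = if (is.null(report$junction_calls)) 0L
                                 else nrow(report$junction_calls),
                toeprint_lanes = if (is.null(report$toeprint_stats)) 0L
                                 else nrow(report$toeprint_stats)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(ann, "leader_annotations.tsv")
    wtsv(leader_summary, "leader_summary.tsv")
    wtsv(calls, "sd_calls.tsv")
    wtsv(sd_summary, "sd_summary.tsv")
    write_sd_gff3(calls, genes, file.path(out_dir, "sd_hits.gff3"))
    if (!is.null(report$junction_tally)) {
      wtsv(report$junction_calls, "junction_calls.tsv")
      wtsv(report$junction_tally, "junction_tally.tsv")
    }
    if (!is.null(report$toeprint_summary)) {
      wtsv(report$toeprint_stats, "toeprint_stats.tsv")
      wtsv(report$toeprint_summary, "toeprint_summary.tsv")
    }
    json <- report[c("leader_summary", "sd_summary")]
    json$junction_tally <- report$junction_tally
    json$toeprint_summary <- report$toeprint_summary
    json$manifest <- report$manifest["rows"]
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  report
}
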