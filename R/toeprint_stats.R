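#' Toeprint percentage of a lane
#'
#' A toeprinting lane yields the intensity of the reverse-transcriptase
#' arrest band (`T`, the toeprint) and of the read-through band (`RT`). The
#' statistic is the percentage of T relative to T + RT.
#'
#' @param T,RT Non-negative band intensities (vectors recycle as usual).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
toeprint_percent <- function(T, RT) {
  if (any(T < 0 | RT < 0)) stop("band intensities must be non-negative", call. = FALSE)
  tot <- T + RT
  if (any(tot == 0)) stop("unquantifiable lane: T + RT == 0", call. = FALSE)
  100 * T / tot
}

#' Read a toeprint lane table
#'
#' TSV with columns `lane_id`, `condition`, `mrna`, `T`, `RT`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of lanes.
#' @export
read_toeprint_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "condition", "mrna", "T", "RT")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("toeprint table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df[need]
}

#' Compute per-lane toeprint statistics
#'
#' @param lanes Lane table (see [read_toeprint_table()]).
#' @return The lane table with a `percent_toeprint` column appended.
#' @export
toeprint_stats <- function(lanes) {
  lanes$percent_toeprint <- toeprint_percent(lanes$T, lanes$RT)
  lanes
}

#' Normalize toeprint percentages to a reference condition
#'
#' Within each mRNA group the percentages are scaled so the mean of the
#' reference condition (by default the 5'-monophosphorylated mRNA) equals
#' exactly 100.
#'
#' @param stats Output of [toeprint_stats()].
#' @param reference_condition Condition whose group mean maps to 100
#'   (default `"monophosphate"`).
#' @return `stats` with a `normalized_percent` column appended.
#' @export
normalize_to_reference <- function(stats, reference_condition = "monophosphate") {
  stats$normalized_percent <- NA_real_
  for (m in unique(stats$mrna)) {
    grp <- stats$mrna == m
    ref <- grp & stats$condition == reference_condition
    if (!any(ref)) {
      stop("mRNA group '", m, "' has no lane in reference condition '",
           reference_condition, "'", call. = FALSE)
    }
    stats$normalized_percent[grp] <-
      stats$percent_toeprint[grp] * 100 / mean(stats$percent_toeprint[ref])
  }
  stats
}

#' Per-condition summary of toeprint signals
#'
#' @param stats Output of [toeprint_stats()] (optionally after
#'   [normalize_to_reference()]).
#' @param value Column to summarize (default `"percent_toeprint"`).
#' @return `data.frame` with `mrna`, `condition`, `n`, `mean`, `sd` (sample
#'   SD, n-1 denominator; `NA` when n == 1).
#' @export
summarize_conditions <- function(stats, value = "percent_toeprint") {
  key <- interaction(stats$mrna, stats$condition, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- stats[key == k, , drop = FALSE]
    x <- sub[[value]]
    data.frame(mrna = sub$mrna[1], condition = sub$condition[1],
               n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mrna, out$condition), , drop = FALSE]
}

#' Two-sample comparison of toeprint signals between conditions
#'
#' Routine Welch (default) or pooled-variance Student t test between two
#' conditions within one mRNA group.
#'
#' @param stats Output of [toeprint_stats()].
#' @param mrna mRNA group.
#' @param cond_a,cond_b Conditions to compare.
#' @param var_equal Use the pooled-variance Student test (default `FALSE`,
#'   i.e. Welch).
#' @param value Column to compare.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_conditions <- function(stats, mrna, cond_a, cond_b,
                               var_equal = FALSE, value = "percent_toeprint") {
  a <- stats[[value]][stats$mrna == mrna & stats$condition == cond_a]
  b <- stats[[value]][stats$mrna == mrna & stats$condition == cond_b]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least two lanes per condition for a t test", call. = FALSE)
  }
  stats::t.test(a, b, var.equal = var_equal)
}
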