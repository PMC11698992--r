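#' @keywords internal
"_PACKAGE"

# Sequence normalization: uppercase, U -> T. The package works on the DNA
# alphabet internally; RNA input is accepted everywhere.
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains illegal characters (first offender: '%s'); allowed: A/C/G/T%s (U is normalized to T)",
                 what, x[which(bad)[1]], if (allow_n) "/N" else ""), call. = FALSE)
  }
  invisible(x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Half-up decimal rounding (R's round() is half-to-even); percentages in
# summaries are reported to one decimal, half-up.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible sub-seed so each generator consumes an independent
# stream and adding one generator does not perturb the others.
sub_seed <- function(seed, k) {
  (as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483399 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
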