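#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

stop_circscape <- function(msg, class) {
  stop(structure(
    class = c(class, "circscape_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_circscape(sprintf("'%s' must be a single number in [0, 1]", name),
                   "circscape_parameter_error")
  }
  invisible(x)
}

# Nucleotide string helpers. Sequences are plain uppercase character strings;
# Biostrings is used for file I/O and pattern search, not for these tiny ops.

check_dna <- function(seq, name = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop_circscape(sprintf("'%s' must be a single non-empty string", name),
                   "circscape_sequence_error")
  }
  s <- toupper(seq)
  if (grepl("[^ACGT]", s)) {
    stop_circscape(sprintf("'%s' contains characters outside ACGT", name),
                   "circscape_sequence_error")
  }
  s
}

reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

dna_to_rna <- function(seq) chartr("T", "U", toupper(seq))
rna_to_dna <- function(seq) chartr("U", "T", toupper(seq))

#' Percentage of a count relative to a total
#'
#' Reporting helper used when summarising annotation overlap (for example the
#' fraction of detected circRNAs present in circBase, or also detected by a
#' second caller), rounded to a fixed number of decimals as typically printed.
#'
#' @param n Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimals to round to (default 1).
#' @return A single number, `100 * n / total` rounded to `digits`.
#' @examples
#' percent_of(6911, 8738)  # 79.1
#' @export
percent_of <- function(n, total, digits = 1) {
  if (!is.numeric(n) || !is.numeric(total) || total <= 0) {
    stop_circscape("'n' and 'total' must be numeric with total > 0",
                   "circscape_parameter_error")
  }
  round(100 * n / total, digits)
}

#' Total-read equivalent of a mean abundance threshold
#'
#' A mean of `min_mean` BSJ-spanning reads per sample over `n_samples`
#' samples corresponds to `min_mean * n_samples` reads in total; the helper
#' makes the arithmetic behind the high-abundance definition explicit.
#'
#' @param min_mean Mean reads-per-sample threshold.
#' @param n_samples Number of samples.
#' @return Total read count equivalent to the mean threshold.
#' @examples
#' min_total_reads(5, 15)  # 75
#' @export
min_total_reads <- function(min_mean, n_samples) {
  if (!is.numeric(min_mean) || !is_count(n_samples)) {
    stop_circscape("'min_mean' must be numeric and 'n_samples' a count",
                   "circscape_parameter_error")
  }
  min_mean * n_samples
}
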