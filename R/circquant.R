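# BSJ-level quantification: candidate bookkeeping, caller harmonization,
# abundance filtering, RPM, circular-to-linear ratios, median-of-ratios
# normalization and the log2/z display transform.

#' Container for BSJ and linear junction counts across samples
#'
#' Holds the candidate table, the sample metadata and three same-shape
#' nonnegative integer matrices: reads spanning each back-splice junction
#' (BSJ), and linear reads spanning the splice donor and splice acceptor
#' sites of the same junction.
#'
#' @param candidates Data frame with at least columns `chrom`, `start`,
#'   `end`, `strand`, `id` (0-based half-open coordinates, BED convention;
#'   `id` unique).
#' @param samples Data frame with columns `sample`, `condition`,
#'   `replicate`, `library_size` (total reads, > 0).
#' @param bsj,donor,acceptor Nonnegative count matrices, candidates x samples.
#' @return An object of class `junction_count_set`.
#' @export
junction_count_set <- function(candidates, samples, bsj, donor, acceptor) {
  need_cand <- c("chrom", "start", "end", "strand", "id")
  if (!is.data.frame(candidates) || !all(need_cand %in% names(candidates))) {
    stop_circscape("candidates must carry chrom, start, end, strand, id",
                   "circscape_format_error")
  }
  need_samp <- c("sample", "condition", "replicate", "library_size")
  if (!is.data.frame(samples) || !all(need_samp %in% names(samples))) {
    stop_circscape("samples must carry sample, condition, replicate, library_size",
                   "circscape_format_error")
  }
  if (anyDuplicated(candidates$id)) {
    stop_circscape("candidate ids must be unique", "circscape_format_error")
  }
  if (nrow(candidates) > 0 && any(candidates$start >= candidates$end)) {
    stop_circscape("candidate coordinates must satisfy start < end",
                   "circscape_format_error")
  }
  if (nrow(candidates) > 0 && !all(candidates$strand %in% c("+", "-"))) {
    stop_circscape("strand must be '+' or '-'", "circscape_format_error")
  }
  if (any(samples$library_size <= 0)) {
    stop_circscape("library_size must be > 0 for every sample",
                   "circscape_parameter_error")
  }
  dims <- c(nrow(candidates), nrow(samples))
  for (nm in c("bsj", "donor", "acceptor")) {
    m <- get(nm)
    if (!is.matrix(m) || !all(dim(m) == dims)) {
      stop_circscape(sprintf("'%s' must be a %d x %d matrix", nm, dims[1], dims[2]),
                     "circscape_format_error")
    }
    if (length(m) > 0 && (any(m < 0) || any(m != floor(m)))) {
      stop_circscape(sprintf("'%s' must contain nonnegative integer counts", nm),
                     "circscape_data_error")
    }
  }
  structure(list(candidates = candidates, samples = samples,
                 bsj = bsj, donor = donor, acceptor = acceptor),
            class = "junction_count_set")
}

#' @export
print.junction_count_set <- function(x, ...) {
  cat(sprintf("junction_count_set: %d candidates x %d samples (%d conditions)\n",
              nrow(x$candidates), nrow(x$samples),
              length(unique(x$samples$condition))))
  invisible(x)
}

#' @export
dim.junction_count_set <- function(x) dim(x$bsj)

subset_candidates <- function(jcs, keep) {
  junction_count_set(
    jcs$candidates[keep, , drop = FALSE], jcs$samples,
    jcs$bsj[keep, , drop = FALSE],
    jcs$donor[keep, , drop = FALSE],
    jcs$acceptor[keep, , drop = FALSE]
  )
}

#' Harmonize circRNA candidate lists from two detection pipelines
#'
#' Candidates found by both callers are flagged as cross-validated;
#' candidates reported by a single caller are marked as needing manual
#' inspection (mapping artifacts are a known failure mode of single-caller
#' circRNA calls). An explicit exclusion list stands in for that manual
#' review: listed ids get `inspection = "fail"` and are dropped when
#' `drop_failed = TRUE`.
#'
#' @param calls_a,calls_b Data frames of candidates (`chrom`, `start`,
#'   `end`, `strand`; an `id` column is derived if absent) from the primary
#'   and secondary caller.
#' @param caller_a,caller_b Caller names recorded in the output.
#' @param exclusion Character vector of candidate ids failing inspection.
#' @param drop_failed Drop candidates with `inspection == "fail"`?
#' @return Data frame of harmonized candidates with `callers` (comma-joined
#'   names), `detected_by_both`, and `inspection` in pass/fail/unreviewed.
#' @export
harmonize_callers <- function(calls_a, calls_b,
                              caller_a = "find_circ", caller_b = "CIRCexplorer",
                              exclusion = character(0), drop_failed = FALSE) {
  norm <- function(df, who) {
    if (nrow(df) > 0 && any(df$start >= df$end)) {
      stop_circscape(sprintf("caller '%s': start >= end suggests a coordinate-convention mismatch", who),
                     "circscape_format_error")
    }
    if (is.null(df$id)) {
      df$id <- sprintf("%s:%d-%d:%s", df$chrom, df$start, df$end, df$strand)
    }
    df
  }
  a <- norm(calls_a, caller_a)
  b <- norm(calls_b, caller_b)
  out <- a[!duplicated(a$id), , drop = FALSE]
  only_b <- b[!duplicated(b$id) & !(b$id %in% out$id), , drop = FALSE]
  common <- intersect(names(out), names(only_b))
  out <- rbind(out[, common, drop = FALSE], only_b[, common, drop = FALSE])
  in_a <- out$id %in% a$id
  in_b <- out$id %in% b$id
  out$callers <- ifelse(in_a & in_b, paste(caller_a, caller_b, sep = ","),
                        ifelse(in_a, caller_a, caller_b))
  out$detected_by_both <- in_a & in_b
  out$inspection <- ifelse(out$detected_by_both, "pass", "unreviewed")
  out$inspection[out$id %in% exclusion] <- "fail"
  if (drop_failed) out <- out[out$inspection != "fail", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidates to high-abundance circRNAs
#'
#' Retains candidates supported by at least `min_mean` BSJ-spanning reads on
#' average per sample (inclusive at the threshold; a mean of exactly
#' `min_mean` is kept). Candidate order is preserved.
#'
#' @param jcs A [junction_count_set()].
#' @param min_mean Mean-reads-per-sample threshold (default 5).
#' @return The filtered [junction_count_set()].
#' @export
filter_high_abundance <- function(jcs, min_mean = 5) {
  stopifnot(inherits(jcs, "junction_count_set"))
  if (nrow(jcs$samples) < 1) {
    stop_circscape("at least one sample is required", "circscape_parameter_error")
  }
  if (nrow(jcs$candidates) == 0) return(jcs)
  keep <- rowMeans(jcs$bsj) >= min_mean
  subset_candidates(jcs, keep)
}

#' Reads per million (RPM) for BSJ-spanning reads
#'
#' `rpm[i, j] = bsj[i, j] / library_size[j] * 1e6`, the BSJ read count
#' scaled by the sample's total sequenced reads.
#'
#' @param jcs A [junction_count_set()].
#' @return Numeric matrix of the same shape as `jcs$bsj`.
#' @export
rpm <- function(jcs) {
  stopifnot(inherits(jcs, "junction_count_set"))
  if (any(jcs$samples$library_size <= 0)) {
    stop_circscape("library sizes must be positive", "circscape_parameter_error")
  }
  sweep(jcs$bsj, 2, jcs$samples$library_size, "/") * 1e6
}

#' Circular-to-linear (CTL) ratio per candidate and sample
#'
#' The BSJ read count divided by the average of the linear reads spanning
#' the splice donor and splice acceptor sites of the same junction, plus a
#' pseudocount that prevents division by zero:
#' `ctl = bsj / ((donor + acceptor) / 2 + pseudocount)`.
#'
#' @param jcs A [junction_count_set()].
#' @param pseudocount Positive pseudocount added to the mean linear count
#'   (default 1).
#' @return Numeric matrix of CTL ratios (0 wherever the BSJ count is 0).
#' @export
ctl_ratio <- function(jcs, pseudocount = 1) {
  stopifnot(inherits(jcs, "junction_count_set"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop_circscape("pseudocount must be > 0", "circscape_parameter_error")
  }
  jcs$bsj / ((jcs$donor + jcs$acceptor) / 2 + pseudocount)
}

#' Median-of-ratios size factors and normalized counts
#'
#' The standard RNA-seq normalization: a pseudo-reference per gene (row) is
#' the geometric mean across samples over rows with all counts positive;
#' each sample's size factor is the median of its count-to-reference
#' ratios over those rows, and normalized counts are raw counts divided
#' columnwise by the size factor.
#'
#' @param counts Nonnegative numeric matrix, genes x samples.
#' @return List of class `normalization_result` with `size_factors`
#'   (per-sample positive reals) and `normalized_counts`.
#' @export
median_of_ratios <- function(counts) {
  if (!is.matrix(counts) || any(counts < 0)) {
    stop_circscape("counts must be a nonnegative matrix", "circscape_data_error")
  }
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop_circscape("no row with all-positive counts; size factors are undefined",
                   "circscape_normalization_error")
  }
  log_ref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  size_factors <- apply(counts[all_pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_ref))
  })
  structure(list(size_factors = size_factors,
                 normalized_counts = sweep(counts, 2, size_factors, "/")),
            class = "normalization_result")
}

#' Row-wise log2 / z-score transform for display matrices
#'
#' Computes `log2(count + pseudocount)` and z-scales each row with the
#' sample standard deviation, the transform used for marker heatmaps.
#' Constant rows (zero variance) map to all-zero rows by convention.
#'
#' @param counts Nonnegative numeric matrix (e.g. normalized counts).
#' @param pseudocount Added before the log (default 1).
#' @return Matrix of row z-scores of the log2 counts.
#' @export
log2_z_matrix <- function(counts, pseudocount = 1) {
  if (!is.matrix(counts) || any(counts < 0)) {
    stop_circscape("counts must be a nonnegative matrix", "circscape_data_error")
  }
  x <- log2(counts + pseudocount)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Per-candidate expression summary across conditions
#'
#' Convenience wrapper computing the RPM and CTL matrices plus per-condition
#' means of each, the inputs to fold-change classification and to the global
#' expression-shift test.
#'
#' @param jcs A [junction_count_set()].
#' @param pseudocount_ctl Pseudocount for the CTL denominator (default 1).
#' @return List of class `expression_summary`: `rpm`, `ctl`,
#'   `mean_rpm`/`mean_ctl` (candidates x conditions), `conditions`,
#'   `candidates`, and the pseudocount used.
#' @export
expression_summary <- function(jcs, pseudocount_ctl = 1) {
  stopifnot(inherits(jcs, "junction_count_set"))
  r <- rpm(jcs)
  ctl <- ctl_ratio(jcs, pseudocount_ctl)
  conds <- unique(jcs$samples$condition)
  cond_mean <- function(m) {
    out <- sapply(conds, function(cc) {
      rowMeans(m[, jcs$samples$condition == cc, drop = FALSE])
    })
    if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, conds))
    out
  }
  structure(list(rpm = r, ctl = ctl,
                 mean_rpm = cond_mean(r), mean_ctl = cond_mean(ctl),
                 conditions = conds, candidates = jcs$candidates,
                 pseudocount_ctl = pseudocount_ctl),
            class = "expression_summary")
}
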