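# File formats and the end-to-end pipeline driver. Canonical tabular
# dialect: TSV with a header, UTF-8, '.' decimal. Candidate coordinates are
# BED-style 0-based half-open. FASTA goes through Biostrings.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

matrix_to_df <- function(m) {
  cbind(data.frame(id = rownames(m), stringsAsFactors = FALSE),
        as.data.frame(m, check.names = FALSE))
}

df_to_matrix <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  m
}

#' Write a junction count set to a directory
#'
#' Emits `bsj.tsv` (rows = candidate id, columns = sample id), `linear.tsv`
#' (the donor and acceptor blocks stacked, distinguished by a
#' `junction_side` column), `samples.tsv` (sample, condition, replicate,
#' library_size) and `candidates.tsv`.
#'
#' @param jcs A [junction_count_set()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_junction_counts <- function(jcs, dir) {
  stopifnot(inherits(jcs, "junction_count_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(matrix_to_df(jcs$bsj), file.path(dir, "bsj.tsv"))
  lin <- rbind(
    cbind(data.frame(junction_side = "donor"), matrix_to_df(jcs$donor)),
    cbind(data.frame(junction_side = "acceptor"), matrix_to_df(jcs$acceptor))
  )
  write_tsv(lin, file.path(dir, "linear.tsv"))
  write_tsv(jcs$samples, file.path(dir, "samples.tsv"))
  write_tsv(jcs$candidates, file.path(dir, "candidates.tsv"))
  invisible(dir)
}

#' Read a junction count set from TSV files
#'
#' Counterpart of [write_junction_counts()]: validates that the BSJ, donor
#' and acceptor matrices share candidates and samples, that the sample
#' columns match the metadata rows (mismatches are reported by name), and
#' that all counts are nonnegative integers.
#'
#' @param bsj_path Path to the BSJ count TSV.
#' @param linear_path Path to the stacked donor/acceptor TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @param candidates_path Optional path to the candidate table; when absent,
#'   candidates are reconstructed from the `chrom:start-end:strand` ids.
#' @return A validated [junction_count_set()].
#' @export
read_junction_counts <- function(bsj_path, linear_path, meta_path,
                                 candidates_path = NULL) {
  bsj_df <- read_tsv(bsj_path)
  lin_df <- read_tsv(linear_path)
  samples <- read_tsv(meta_path)
  need <- c("sample", "condition", "replicate", "library_size")
  if (!all(need %in% names(samples))) {
    stop_circscape("sample metadata must carry sample, condition, replicate, library_size",
                   "circscape_format_error")
  }
  bsj <- df_to_matrix(bsj_df)
  miss_meta <- setdiff(colnames(bsj), samples$sample)
  miss_counts <- setdiff(samples$sample, colnames(bsj))
  if (length(miss_meta) || length(miss_counts)) {
    fmt <- function(x) if (length(x)) paste(x, collapse = ",") else "none"
    stop_circscape(sprintf(
      "sample mismatch between counts and metadata (missing in metadata: %s; missing in counts: %s)",
      fmt(miss_meta), fmt(miss_counts)
    ), "circscape_format_error")
  }
  bsj <- bsj[, samples$sample, drop = FALSE]
  if (!"junction_side" %in% names(lin_df)) {
    stop_circscape("linear TSV must carry a junction_side column",
                   "circscape_format_error")
  }
  side <- lin_df$junction_side
  lin_df$junction_side <- NULL
  donor <- df_to_matrix(lin_df[side == "donor", , drop = FALSE])
  acceptor <- df_to_matrix(lin_df[side == "acceptor", , drop = FALSE])
  donor <- donor[rownames(bsj), samples$sample, drop = FALSE]
  acceptor <- acceptor[rownames(bsj), samples$sample, drop = FALSE]
  for (nm in c("bsj", "donor", "acceptor")) {
    m <- get(nm)
    bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop_circscape(sprintf("%s counts invalid at row '%s', sample '%s'",
                             nm, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
                     "circscape_data_error")
    }
  }
  if (!is.null(candidates_path)) {
    candidates <- read_tsv(candidates_path)
  } else {
    parts <- regmatches(rownames(bsj),
                        regexec("^(.+):(\\d+)-(\\d+):([+-])$", rownames(bsj)))
    if (any(lengths(parts) != 5)) {
      stop_circscape("candidate ids are not chrom:start-end:strand; supply candidates_path",
                     "circscape_format_error")
    }
    candidates <- data.frame(
      chrom = vapply(parts, `[`, "", 2),
      start = as.integer(vapply(parts, `[`, "", 3)),
      end = as.integer(vapply(parts, `[`, "", 4)),
      strand = vapply(parts, `[`, "", 5),
      id = rownames(bsj), stringsAsFactors = FALSE
    )
  }
  junction_count_set(candidates, samples, bsj, donor, acceptor)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @param rna_to_dna Convert U to T (default FALSE).
#' @return Named character vector of uppercase sequences (empty for an
#'   empty file).
#' @export
read_fasta <- function(path, rna_to_dna = FALSE) {
  if (file.size(path) == 0) return(character(0))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (rna_to_dna) seqs <- chartr("U", "T", seqs)
  stats::setNames(unname(seqs), sub("\\s.*$", "", names(set)))
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(toupper(records))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Run the circRNA landscape pipeline end to end on synthetic data
#'
#' Generates a synthetic landscape, writes its inputs, then runs the
#' quantification and statistics stages: high-abundance filtering, RPM and
#' CTL ratios, the normality-gated global shift test between the first and
#' last state (on per-candidate `log2(RPM + 1)` averaged over replicates),
#' fold-change classification of last versus first state, and the
#' circular-linear coupling regression. Artifacts and a machine-readable
#' JSON report (counts in/out per filter, test statistics, seed) are
#' written to `out_dir`. Deterministic for a fixed seed.
#'
#' @param params A [landscape_params()] object (its seed drives all RNG).
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @param min_mean High-abundance threshold (mean BSJ reads per sample).
#' @param threshold_fold Fold-change classification threshold.
#' @param pseudocount_fc Pseudocount for RPM fold changes.
#' @return The run report (a list), invisibly when writing.
#' @export
run_pipeline <- function(params = landscape_params(), out_dir = NULL,
                         min_mean = 5, threshold_fold = 2,
                         pseudocount_fc = 1) {
  sim <- gen_junction_counts(params)
  jcs <- sim$counts
  kept <- filter_high_abundance(jcs, min_mean = min_mean)
  summ <- expression_summary(kept)
  conds <- summ$conditions
  first <- conds[1]; last <- conds[length(conds)]

  sample_cond <- kept$samples$condition
  log_rpm <- log2(summ$rpm + 1)
  mean_first <- rowMeans(log_rpm[, sample_cond == first, drop = FALSE])
  mean_last <- rowMeans(log_rpm[, sample_cond == last, drop = FALSE])
  shift <- global_shift_test(mean_first, mean_last)

  fc_circ <- fold_change(summ$mean_rpm[, first], summ$mean_rpm[, last],
                         pseudocount = pseudocount_fc)
  classes <- classify_regulation(fc_circ$log2fc, threshold_fold)
  fc_ctl <- fold_change(summ$mean_ctl[, first], summ$mean_ctl[, last],
                        pseudocount = pseudocount_fc)
  coupling <- coupling_regression(fc_circ$log2fc, fc_ctl$log2fc)
  ma <- ma_table(rowMeans(summ$rpm), fc_circ$log2fc, threshold_fold,
                 id = kept$candidates$id)

  report <- list(
    seed = params$seed,
    n_candidates_simulated = nrow(jcs$candidates),
    n_candidates_high_abundance = nrow(kept$candidates),
    min_mean = min_mean,
    contrast = paste(first, "vs", last),
    global_shift = list(test_used = shift$test_used,
                        statistic = shift$statistic,
                        p_value = shift$p_value,
                        n_pairs_used = shift$n_pairs_used),
    regulation_counts = as.list(table(classes)),
    coupling = list(slope = coupling$slope, r_squared = coupling$r_squared,
                    f_statistic = coupling$f_statistic,
                    p_value = coupling$p_value, n = coupling$n),
    package_version = as.character(utils::packageVersion("circscape"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_junction_counts(jcs, file.path(out_dir, "inputs"))
    write_tsv(sim$truth, file.path(out_dir, "inputs", "truth.tsv"))
    write_tsv(ma, file.path(out_dir, "ma_table.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
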