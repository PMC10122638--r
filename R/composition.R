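# Single-cell QC filtering and cluster-composition bias analysis. All
# threshold comparisons follow the strict wording of the underlying rules
# ("less than", "more than"), so borderline values behave predictably.

check_cells <- function(cells, need) {
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    stop_circscape(sprintf("cell table must carry columns: %s",
                           paste(need, collapse = ", ")),
                   "circscape_data_error")
  }
  invisible(cells)
}

#' Quality-control filtering of single cells
#'
#' Applies the droplet scRNA-seq QC rules in sequence, each strict:
#' cells with less than `umi_min` UMI are removed; cells with more than
#' `mito_max_pct` percent mitochondrial counts are removed; only cells
#' expressing more than `genes_min` genes are kept; cells with more than
#' `genes_max` genes are removed; finally (the final-clustering pass,
#' `apply_final = TRUE`) cells with less than `final_umi_min` UMI are
#' removed. A cell with exactly `final_umi_min` UMI is retained.
#'
#' @param cells Data frame with `cell_id`, `umi_count`, `pct_mito`,
#'   `n_genes` (extra columns pass through).
#' @param umi_min First-pass UMI minimum (default 200).
#' @param mito_max_pct Maximum percent mitochondrial counts (default 5).
#' @param genes_min Cells must express more than this many genes (default 10).
#' @param genes_max Cells with more than this many genes are removed
#'   (default 2500).
#' @param final_umi_min Final-pass UMI minimum (default 500).
#' @param apply_final Apply the final-pass UMI rule (default TRUE)?
#' @return List with `cells` (retained rows) and `tally` (named integer
#'   vector of removals per rule, evaluated sequentially).
#' @export
qc_filter_cells <- function(cells, umi_min = 200, mito_max_pct = 5,
                            genes_min = 10, genes_max = 2500,
                            final_umi_min = 500, apply_final = TRUE) {
  check_cells(cells, c("cell_id", "umi_count", "pct_mito", "n_genes"))
  rules <- list(
    low_umi = function(df) df$umi_count >= umi_min,
    high_mito = function(df) df$pct_mito <= mito_max_pct,
    few_genes = function(df) df$n_genes > genes_min,
    many_genes = function(df) df$n_genes <= genes_max
  )
  if (apply_final) {
    rules$final_low_umi <- function(df) df$umi_count >= final_umi_min
  }
  tally <- stats::setNames(integer(length(rules)), names(rules))
  out <- cells
  for (nm in names(rules)) {
    keep <- rules[[nm]](out)
    tally[nm] <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  list(cells = out, tally = tally)
}

#' Filter genes by the number of cells expressing them
#'
#' Keeps genes expressed in more than `min_cells` cells (strict; a gene in
#' exactly `min_cells` cells is dropped).
#'
#' @param presence Named integer vector (gene -> number of cells with
#'   nonzero expression) or data frame with `gene` and `n_cells` columns.
#' @param min_cells Threshold (default 3).
#' @return Character vector of retained gene names.
#' @export
filter_genes_min_cells <- function(presence, min_cells = 3) {
  if (is.data.frame(presence)) {
    presence <- stats::setNames(presence$n_cells, presence$gene)
  }
  if (any(presence < 0)) {
    stop_circscape("presence counts must be nonnegative", "circscape_data_error")
  }
  names(presence)[presence > min_cells]
}

#' Condition bias of cluster composition
#'
#' Tabulates, per cluster, how many cells derive from each condition and
#' labels a cluster condition-specific when more than `threshold` of its
#' cells originate from a single condition (strict: a cluster at exactly
#' the threshold is shared). With more than two conditions the
#' maximum-fraction condition is assessed.
#'
#' @param cells Data frame with `cluster` and `condition` columns (one row
#'   per cell), or a precomputed cluster x condition count matrix.
#' @param threshold Fraction above which a cluster is condition-specific
#'   (default 0.75).
#' @param conditions Optional expected condition labels; unknown labels in
#'   the data raise an error.
#' @return Data frame of class `cluster_condition_table`: one row per
#'   cluster with per-condition counts (`n_<condition>`), `total`,
#'   per-condition fractions (`frac_<condition>`), `top_condition`,
#'   `top_fraction` and `bias_label` (`"<condition>-specific"` or
#'   `"shared"`).
#' @export
condition_bias <- function(cells, threshold = 0.75, conditions = NULL) {
  if (is.matrix(cells)) {
    counts <- cells
  } else {
    check_cells(cells, c("cluster", "condition"))
    if (!is.null(conditions) && !all(cells$condition %in% conditions)) {
      bad <- setdiff(unique(cells$condition), conditions)
      stop_circscape(sprintf("unknown condition labels: %s",
                             paste(bad, collapse = ", ")),
                     "circscape_data_error")
    }
    counts <- as.matrix(table(cells$cluster, cells$condition))
  }
  if (!is.null(conditions)) {
    missing_cond <- setdiff(conditions, colnames(counts))
    for (mc in missing_cond) counts <- cbind(counts, stats::setNames(rep(0, nrow(counts)), NULL))
    if (length(missing_cond)) colnames(counts)[(ncol(counts) - length(missing_cond) + 1):ncol(counts)] <- missing_cond
    counts <- counts[, conditions, drop = FALSE]
  }
  total <- rowSums(counts)
  if (any(total == 0)) {
    stop_circscape("every cluster must contain at least one cell",
                   "circscape_data_error")
  }
  fracs <- counts / total
  top_idx <- max.col(fracs, ties.method = "first")
  top_condition <- colnames(counts)[top_idx]
  top_fraction <- fracs[cbind(seq_len(nrow(fracs)), top_idx)]
  bias_label <- ifelse(top_fraction > threshold,
                       paste0(top_condition, "-specific"), "shared")
  out <- data.frame(cluster = rownames(counts), stringsAsFactors = FALSE)
  for (cc in colnames(counts)) out[[paste0("n_", cc)]] <- counts[, cc]
  out$total <- total
  for (cc in colnames(counts)) out[[paste0("frac_", cc)]] <- fracs[, cc]
  out$top_condition <- top_condition
  out$top_fraction <- top_fraction
  out$bias_label <- bias_label
  rownames(out) <- NULL
  class(out) <- c("cluster_condition_table", "data.frame")
  out
}

#' Select highly abundant cells for differential expression
#'
#' Retains cells with more than `umi_low` and less than `umi_high` UMI
#' (strict open interval; cells at either bound are excluded), the
#' selection used before treating cells as replicates in a
#' cluster-versus-cluster DE analysis.
#'
#' @param cells Data frame with an `umi_count` column.
#' @param umi_low,umi_high Open-interval bounds (defaults 2000 and 4000).
#' @return The retained rows of `cells`.
#' @export
select_de_cells <- function(cells, umi_low = 2000, umi_high = 4000) {
  check_cells(cells, "umi_count")
  if (umi_low >= umi_high) {
    stop_circscape("umi_low must be less than umi_high", "circscape_parameter_error")
  }
  out <- cells[cells$umi_count > umi_low & cells$umi_count < umi_high, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
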