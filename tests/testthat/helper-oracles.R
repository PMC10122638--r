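# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive: loops and direct formula evaluation, no shared code
# with the implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# junction_count_set from bare matrices
make_jcs <- function(bsj, donor = NULL, acceptor = NULL, library_size = NULL,
                     conditions = NULL) {
  n <- nrow(bsj); m <- ncol(bsj)
  if (is.null(donor)) donor <- matrix(0L, n, m)
  if (is.null(acceptor)) acceptor <- matrix(0L, n, m)
  if (is.null(library_size)) library_size <- rep(1e7, m)
  if (is.null(conditions)) conditions <- rep("c1", m)
  candidates <- data.frame(
    chrom = rep("chr1", n), start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 500L, strand = rep("+", n),
    id = sprintf("chr1:%d-%d:+", seq_len(n) * 1000L, seq_len(n) * 1000L + 500L),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample = sprintf("s%02d", seq_len(m)), condition = conditions,
    replicate = ave(seq_len(m), conditions, FUN = seq_along),
    library_size = library_size, stringsAsFactors = FALSE
  )
  rownames(bsj) <- rownames(donor) <- rownames(acceptor) <- candidates$id
  colnames(bsj) <- colnames(donor) <- colnames(acceptor) <- samples$sample
  junction_count_set(candidates, samples, bsj, donor, acceptor)
}

# hand Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  ranked <- p[o] * n / seq_len(n)
  # monotonicity from the largest rank down
  for (i in seq_len(n)) {
    adj[i] <- min(ranked[i:n], 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_enum_oracle <- function(a, b) {
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force off-target scan: every position, both strands, count
# mismatches and require an exact run >= min_word
offtarget_oracle <- function(guide, transcripts, max_mismatch = 2,
                             min_word = 7, exclude_pattern = "^X[MR]_") {
  guide <- chartr("U", "T", toupper(guide))
  pats <- list("+" = revcomp_chr(guide), "-" = guide)
  rows <- list()
  for (tx in names(transcripts)) {
    if (grepl(exclude_pattern, tx)) next
    s <- toupper(transcripts[[tx]])
    for (strand in names(pats)) {
      pc <- strsplit(pats[[strand]], "")[[1]]
      L <- length(pc)
      if (nchar(s) < L) next
      for (pos in seq_len(nchar(s) - L + 1)) {
        wc <- strsplit(substr(s, pos, pos + L - 1), "")[[1]]
        mm <- wc != pc
        if (sum(mm) > max_mismatch) next
        runs <- rle(mm)
        best <- if (any(!runs$values)) max(runs$lengths[!runs$values]) else 0
        if (best < min_word) next
        rows[[length(rows) + 1]] <- data.frame(
          transcript_id = tx, position = pos, strand = strand,
          mismatches = sum(mm), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(transcript_id = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$transcript_id, out$position, out$strand), , drop = FALSE]
}

# brute-force QC predicate (single pass, same strictness as the rules)
qc_oracle_keep <- function(cells, umi_min = 200, mito_max = 5, genes_min = 10,
                           genes_max = 2500, final_umi_min = 500) {
  !(cells$umi_count < umi_min) & !(cells$pct_mito > mito_max) &
    (cells$n_genes > genes_min) & !(cells$n_genes > genes_max) &
    !(cells$umi_count < final_umi_min)
}
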