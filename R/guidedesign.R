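# Knockdown-construct design against back-splice junctions. A BSJ target
# is the circular join of the donor side (3' end of the circle's last exon)
# and the acceptor side (5' start of its first exon); constructs are only
# specific for the circle if their target windows span that join. The
# off-target scan screens mature guide strands against a transcript set by
# seeded, mismatch-tolerant ungapped matching.

#' Build the junction-spanning target sequence of a circRNA
#'
#' Concatenates the last `flank` nt of the splice-donor-side exon (the
#' circle's final exon) with the first `flank` nt of the splice-acceptor-side
#' exon (its first exon) -- the sequence that exists in the circular
#' transcript but not in the linear host mRNA. The junction lies between
#' positions `flank` and `flank + 1` of the result. A single-exon circle
#' wraps the same exon.
#'
#' @param circ_exon_seqs Exon sequences (ACGT) in order around the junction:
#'   the exon ending at the splice donor first, the exon beginning at the
#'   splice acceptor last. A single exon is allowed (circular wrap). For a
#'   multi-exon circle in transcription order `e1..en`, pass
#'   `c(en, e1)`.
#' @param flank Nucleotides to take from each side of the junction.
#' @param circ_id Optional identifier carried through to constructs.
#' @return Object of class `bsj_target`: `circ_id`, `upstream_seq`,
#'   `downstream_seq`, `junction_seq`, `junction` (= `flank`).
#' @examples
#' build_bsj_target(c("AAAACGT", "GGCCTTT"), flank = 4)$junction_seq  # "ACGTGGCC"
#' @export
build_bsj_target <- function(circ_exon_seqs, flank, circ_id = "circ") {
  if (!is_count(flank) || flank < 1) {
    stop_circscape("flank must be an integer >= 1", "circscape_parameter_error")
  }
  if (length(circ_exon_seqs) < 1) {
    stop_circscape("at least one exon sequence is required",
                   "circscape_parameter_error")
  }
  exons <- unname(vapply(circ_exon_seqs, check_dna, character(1), name = "exon"))
  donor_exon <- exons[1]
  acceptor_exon <- exons[length(exons)]
  if (nchar(donor_exon) < flank || nchar(acceptor_exon) < flank) {
    stop_circscape("flank exceeds the available exon sequence",
                   "circscape_parameter_error")
  }
  upstream <- substr(donor_exon, nchar(donor_exon) - flank + 1L, nchar(donor_exon))
  downstream <- substr(acceptor_exon, 1L, flank)
  structure(list(circ_id = circ_id, upstream_seq = upstream,
                 downstream_seq = downstream,
                 junction_seq = paste0(upstream, downstream),
                 junction = as.integer(flank)),
            class = "bsj_target")
}

# window [start, end] (1-based, inclusive) on the junction sequence; the
# junction sits between positions j and j+1, so a window spans it iff it
# covers both.
window_spans_junction <- function(start, end, junction) {
  start <= junction && end >= junction + 1L
}

#' Design a pair of BSJ-spanning shRNA hairpins
#'
#' Two target windows of `window_len` nt are centred `offsets` nt upstream
#' and downstream of the back-splice junction (default -3 and +3); both
#' must still span the junction, otherwise the construct would also silence
#' the linear host transcript. Each hairpin insert is
#' `sense + loop + antisense`, with an XhoI site (CTCGAG) and a poly-T pol
#' III termination signal appended.
#'
#' @param target A [build_bsj_target()] object.
#' @param window_len Target window length (default 21).
#' @param offsets Signed shifts of the two window centres from the junction.
#' @param loop_seq Hairpin loop (DNA top-strand).
#' @param add_xhoi Append the XhoI site?
#' @param termination Termination signal (default `"TTTTTT"`).
#' @return Object of class `guide_construct`, kind `"shrna_pair"`, with the
#'   target windows, guide strands (RNA, antisense to the target), the two
#'   full inserts and per-insert feature coordinates.
#' @export
design_shrna_pair <- function(target, window_len = 21, offsets = c(-3, 3),
                              loop_seq = "TTCAAGAGA", add_xhoi = TRUE,
                              termination = "TTTTTT") {
  stopifnot(inherits(target, "bsj_target"))
  loop_seq <- check_dna(loop_seq, "loop_seq")
  termination <- check_dna(termination, "termination")
  if (!is_count(window_len) || window_len < 3) {
    stop_circscape("window_len must be an integer >= 3", "circscape_parameter_error")
  }
  j <- target$junction
  len <- nchar(target$junction_seq)
  half_lo <- (window_len - 1L) %/% 2L
  half_hi <- window_len - 1L - half_lo
  windows <- lapply(offsets, function(off) {
    centre <- j + off
    w <- c(start = centre - half_lo, end = centre + half_hi)
    if (w["start"] < 1 || w["end"] > len) {
      stop_circscape("window does not fit within the junction sequence; increase flank",
                     "circscape_design_error")
    }
    if (!window_spans_junction(w["start"], w["end"], j)) {
      stop_circscape(sprintf("window at offset %+d leaves the junction uncovered", off),
                     "circscape_design_error")
    }
    w
  })
  inserts <- list()
  features <- list()
  guides <- character(0)
  for (k in seq_along(windows)) {
    w <- windows[[k]]
    sense <- substr(target$junction_seq, w["start"], w["end"])
    antisense <- reverse_complement(sense)
    body <- paste0(sense, loop_seq, antisense)
    insert <- body
    feat <- list(
      sense = c(start = 1L, end = nchar(sense)),
      loop = c(start = nchar(sense) + 1L, end = nchar(sense) + nchar(loop_seq)),
      antisense = c(start = nchar(sense) + nchar(loop_seq) + 1L,
                    end = nchar(body))
    )
    if (add_xhoi) {
      if (grepl("CTCGAG", body, fixed = TRUE)) {
        stop_circscape("hairpin body already contains an XhoI site; choose another window or loop",
                       "circscape_design_error")
      }
      feat$xhoi <- c(start = nchar(insert) + 1L, end = nchar(insert) + 6L)
      insert <- paste0(insert, "CTCGAG")
    }
    feat$termination <- c(start = nchar(insert) + 1L,
                          end = nchar(insert) + nchar(termination))
    insert <- paste0(insert, termination)
    inserts[[k]] <- insert
    features[[k]] <- feat
    guides[k] <- dna_to_rna(antisense)
  }
  structure(list(
    kind = "shrna_pair", circ_id = target$circ_id,
    target_windows = windows, guide_seqs = guides, loop_seq = loop_seq,
    full_insert = unlist(inserts), features = features,
    spans_junction = rep(TRUE, length(windows)),
    offset_nt = offsets
  ), class = "guide_construct")
}

#' Design an AGO2-processed short hairpin (agoshRNA) against a BSJ
#'
#' The stem window is centred on the back-splice junction (at least
#' `min_side` nt on each side). The hairpin is
#' `guide + loop + passenger`, where the guide is antisense to the target
#' window. Three vector-level constraints are applied: the first
#' transcribed base is forced to adenosine (a substitution is recorded if
#' the guide does not already start with A); the passenger base pairing the
#' guide's 5' A is set to C, creating the single A-C mismatch at the base
#' of the stem; and a poly-T transcriptional stop immediately follows the
#' hairpin. Annealed cloning oligos carry BbsI-compatible overhangs.
#'
#' @param target A [build_bsj_target()] object.
#' @param stem_len Stem (and guide) length, default 18.
#' @param loop_seq Hairpin loop (DNA top-strand).
#' @param overhangs Named character vector with `top` and `bottom`
#'   5' overhangs for BbsI cloning.
#' @param termination Transcriptional stop signal (default `"TTTTTT"`).
#' @param min_side Minimum nt of the stem window on each side of the
#'   junction (default 5).
#' @return Object of class `guide_construct`, kind `"agoshrna"`, with the
#'   guide (RNA), hairpin, full insert, cloning oligos and recorded
#'   features (`plus_one_substituted`, `mismatch_position`, etc.).
#' @export
design_agoshrna <- function(target, stem_len = 18, loop_seq = "TTCAAGAGA",
                            overhangs = c(top = "ACCG", bottom = "AAAC"),
                            termination = "TTTTTT", min_side = 5) {
  stopifnot(inherits(target, "bsj_target"))
  loop_seq <- check_dna(loop_seq, "loop_seq")
  termination <- check_dna(termination, "termination")
  if (!is_count(stem_len) || stem_len < 2 * min_side) {
    stop_circscape(sprintf("stem_len must be an integer >= %d", 2 * min_side),
                   "circscape_design_error")
  }
  j <- target$junction
  len <- nchar(target$junction_seq)
  half_lo <- ceiling(stem_len / 2)          # nt on the donor side incl. junction base
  start <- j - half_lo + 1L
  end <- start + stem_len - 1L
  if (start < 1 || end > len) {
    stop_circscape("stem window does not fit; increase flank", "circscape_design_error")
  }
  if (j - start + 1L < min_side || end - j < min_side) {
    stop_circscape(sprintf("stem must cover >= %d nt on each side of the junction", min_side),
                   "circscape_design_error")
  }
  window <- substr(target$junction_seq, start, end)
  guide <- reverse_complement(window)       # antisense, transcribed first
  plus_one_substituted <- substr(guide, 1, 1) != "A"
  substr(guide, 1, 1) <- "A"
  passenger <- reverse_complement(guide)    # perfect complement of final guide
  # A-C mismatch "below the stem": the passenger base pairing the guide's
  # 5' A (last passenger base) becomes C instead of T.
  substr(passenger, nchar(passenger), nchar(passenger)) <- "C"
  hairpin <- paste0(guide, loop_seq, passenger)
  insert <- paste0(hairpin, termination)
  oligo_top <- paste0(check_dna(overhangs[["top"]], "top overhang"), insert)
  oligo_bottom <- paste0(check_dna(overhangs[["bottom"]], "bottom overhang"),
                         reverse_complement(insert))
  features <- list(
    guide = c(start = 1L, end = nchar(guide)),
    loop = c(start = nchar(guide) + 1L, end = nchar(guide) + nchar(loop_seq)),
    passenger = c(start = nchar(guide) + nchar(loop_seq) + 1L,
                  end = nchar(hairpin)),
    termination = c(start = nchar(hairpin) + 1L, end = nchar(insert)),
    plus_one = c(start = 1L, end = 1L),
    mismatch_position = c(start = nchar(hairpin), end = nchar(hairpin))
  )
  structure(list(
    kind = "agoshrna", circ_id = target$circ_id,
    target_windows = list(c(start = start, end = end)),
    guide_seqs = dna_to_rna(guide), loop_seq = loop_seq,
    full_insert = insert, oligo_top = oligo_top, oligo_bottom = oligo_bottom,
    overhangs = overhangs, features = features,
    plus_one_substituted = plus_one_substituted,
    spans_junction = TRUE, offset_nt = 0L
  ), class = "guide_construct")
}

#' @export
print.guide_construct <- function(x, ...) {
  cat(sprintf("%s construct against %s: %d guide(s), insert length(s) %s\n",
              x$kind, x$circ_id, length(x$guide_seqs),
              paste(nchar(x$full_insert), collapse = ", ")))
  invisible(x)
}

longest_exact_run <- function(mm_vector) {
  # longest run of FALSE (matches) in a logical mismatch vector
  r <- rle(mm_vector)
  runs <- r$lengths[!r$values]
  if (length(runs) == 0) 0L else max(runs)
}

#' Scan a transcript set for guide off-target sites
#'
#' Finds ungapped, full-length near-complementary sites of a mature guide
#' strand in a transcript set: positions where the guide's reverse
#' complement (plus strand, the site the guide would base-pair with) or the
#' guide sequence itself (minus strand) occurs with at most `max_mismatch`
#' mismatches. Following short-query BLASTN practice, a hit must contain an
#' exact match of at least `min_word` consecutive nucleotides, and
#' transcripts whose identifier matches `exclude_pattern` (predicted models
#' by default) are skipped. Candidate sites are generated with
#' [Biostrings::matchPattern()] and deduplicated by (transcript, position,
#' strand).
#'
#' @param guide Mature guide strand (RNA or DNA, length >= `min_word`).
#' @param transcripts Named character vector of transcript sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param max_mismatch Maximum mismatches within a full-length site.
#' @param min_word Minimum exact-match word length within a hit.
#' @param exclude_pattern Regular expression of transcript ids to skip
#'   (default predicted-model accessions `XM_`/`XR_`).
#' @return Data frame with `transcript_id`, `position` (1-based start),
#'   `strand`, `mismatches`, `matched_span`.
#' @export
offtarget_scan <- function(guide, transcripts, max_mismatch = 2, min_word = 7,
                           exclude_pattern = "^X[MR]_") {
  guide <- check_dna(rna_to_dna(guide), "guide")
  if (nchar(guide) < min_word) {
    stop_circscape("guide shorter than the seed word length",
                   "circscape_parameter_error")
  }
  if (inherits(transcripts, "DNAStringSet")) {
    transcripts <- stats::setNames(as.character(transcripts), names(transcripts))
  }
  if (length(transcripts) == 0) {
    return(data.frame(transcript_id = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      matched_span = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(names(transcripts))) {
    names(transcripts) <- sprintf("tx%04d", seq_along(transcripts))
  }
  keep <- !grepl(exclude_pattern, names(transcripts))
  patterns <- c("+" = reverse_complement(guide), "-" = guide)
  hits <- list()
  glen <- nchar(guide)
  for (tx in names(transcripts)[keep]) {
    seq_chr <- toupper(transcripts[[tx]])
    subject <- Biostrings::DNAString(seq_chr)
    for (strand in names(patterns)) {
      m <- Biostrings::matchPattern(patterns[[strand]], subject,
                                    max.mismatch = max_mismatch)
      if (length(m) == 0) next
      starts <- BiocGenerics::start(m)
      pat_chars <- strsplit(patterns[[strand]], "")[[1]]
      for (s in starts) {
        if (s < 1 || s + glen - 1L > nchar(seq_chr)) next  # edge overhang
        span <- substr(seq_chr, s, s + glen - 1L)
        mm <- strsplit(span, "")[[1]] != pat_chars
        if (sum(mm) > max_mismatch) next
        if (longest_exact_run(mm) < min_word) next
        hits[[length(hits) + 1L]] <- data.frame(
          transcript_id = tx, position = s, strand = strand,
          mismatches = sum(mm), matched_span = span,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(transcript_id = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      matched_span = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[c("transcript_id", "position", "strand")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[order(out$transcript_id, out$position), , drop = FALSE]
}

#' Cross-reference off-target hits with differentially expressed genes
#'
#' Returns the identifiers that occur both among the off-target hit genes
#' and in the DEG list -- the putative off-target effects that require
#' follow-up before attributing a phenotype to the intended knockdown.
#'
#' @param hits Data frame from [offtarget_scan()] (or any with a
#'   `transcript_id` or `gene` column).
#' @param deg_ids Character vector of DEG identifiers.
#' @param gene_map Optional named character vector mapping transcript ids to
#'   gene ids before intersecting.
#' @return Sorted character vector of shared identifiers.
#' @export
cross_reference_offtargets <- function(hits, deg_ids, gene_map = NULL) {
  ids <- if (!is.null(hits$gene)) hits$gene else hits$transcript_id
  if (!is.null(gene_map)) {
    mapped <- unname(gene_map[ids])
    ids <- ifelse(is.na(mapped), ids, mapped)
  }
  sort(unique(intersect(ids, deg_ids)))
}
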