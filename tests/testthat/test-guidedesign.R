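test_that("BSJ targets concatenate donor and acceptor flanks", {
  t <- build_bsj_target(c("AAAACGT", "GGCCTTT"), flank = 4)
  expect_equal(t$junction_seq, "ACGTGGCC")
  expect_equal(t$junction, 4L)
  expect_equal(t$upstream_seq, "ACGT")
  expect_equal(t$downstream_seq, "GGCC")

  # single-exon circle wraps the same exon
  t1 <- build_bsj_target("ACGGTTCA", flank = 3)
  expect_equal(t1$junction_seq, "TCAACG")

  expect_error(build_bsj_target("ACGTN", 2), class = "circscape_sequence_error")
  expect_error(build_bsj_target(c("ACG", "TTTT"), 4),
               class = "circscape_parameter_error")
})

shrna_demo_target <- function(flank = 30) {
  set.seed(2024)
  build_bsj_target(c(rand_dna(60), rand_dna(60)), flank = flank,
                   circ_id = "circDemo")
}

test_that("shRNA pair windows straddle the junction at the requested offsets", {
  t <- shrna_demo_target()
  con <- design_shrna_pair(t)
  expect_equal(con$kind, "shrna_pair")
  expect_length(con$full_insert, 2L)
  for (k in 1:2) {
    w <- con$target_windows[[k]]
    centre <- (w["start"] + w["end"]) / 2
    expect_equal(unname(centre), t$junction + con$offset_nt[k])
    expect_lte(w[["start"]], t$junction)
    expect_gte(w[["end"]], t$junction + 1)
    expect_equal(unname(w["end"] - w["start"] + 1), 21)
    # guide strand is the reverse complement of its target window (RNA)
    window_seq <- substr(t$junction_seq, w["start"], w["end"])
    expect_equal(chartr("U", "T", con$guide_seqs[k]), revcomp_chr(window_seq))
  }
  expect_error(design_shrna_pair(t, offsets = c(-15, 15)),
               class = "circscape_design_error")
})

test_that("shRNA inserts contain exactly one XhoI site plus termination signal", {
  con <- design_shrna_pair(shrna_demo_target())
  for (k in 1:2) {
    ins <- con$full_insert[k]
    expect_equal(length(gregexpr("CTCGAG", ins, fixed = TRUE)[[1]]), 1L)
    expect_true(endsWith(ins, "TTTTTT"))
    # recorded features are literally at their recorded positions
    f <- con$features[[k]]
    for (nm in names(f)) {
      span <- substr(ins, f[[nm]]["start"], f[[nm]]["end"])
      expect_equal(nchar(span), unname(f[[nm]]["end"] - f[[nm]]["start"] + 1))
    }
    expect_equal(substr(ins, f$xhoi["start"], f$xhoi["end"]), "CTCGAG")
    expect_equal(substr(ins, f$loop["start"], f$loop["end"]), con$loop_seq)
    sense <- substr(ins, f$sense["start"], f$sense["end"])
    anti <- substr(ins, f$antisense["start"], f$antisense["end"])
    expect_equal(anti, revcomp_chr(sense))
  }
})

test_that("agoshRNA construct enforces the +1 adenosine and A-C mismatch", {
  t <- shrna_demo_target()
  ago <- design_agoshrna(t, stem_len = 18)
  guide_dna <- chartr("U", "T", ago$guide_seqs)
  expect_equal(nchar(guide_dna), 18L)
  expect_equal(substr(guide_dna, 1, 1), "A")
  f <- ago$features
  hairpin_len <- unname(f$passenger["end"])
  expect_equal(hairpin_len, 2L * 18L + nchar(ago$loop_seq))
  expect_true(endsWith(ago$full_insert, "TTTTTT"))

  # exactly one mismatch between the passenger and the guide's complement,
  # at the recorded base-of-stem position, and it is A-C
  passenger <- substr(ago$full_insert, f$passenger["start"], f$passenger["end"])
  perfect <- revcomp_chr(guide_dna)
  mm <- which(strsplit(passenger, "")[[1]] != strsplit(perfect, "")[[1]])
  expect_equal(length(mm), 1L)
  expect_equal(unname(f$passenger["start"] + mm - 1L),
               unname(f$mismatch_position["start"]))
  expect_equal(substr(passenger, mm, mm), "C")
  expect_equal(substr(guide_dna, 1, 1), "A")  # the A of the A-C pair

  # cloning oligos anneal: bodies are exact reverse complements, overhangs excluded
  body_top <- substr(ago$oligo_top, nchar(ago$overhangs[["top"]]) + 1,
                     nchar(ago$oligo_top))
  body_bottom <- substr(ago$oligo_bottom, nchar(ago$overhangs[["bottom"]]) + 1,
                        nchar(ago$oligo_bottom))
  expect_equal(body_bottom, revcomp_chr(body_top))
})

test_that("agoshRNA records whether the +1 base needed substitution", {
  # the stem window's 3'-terminal base pairs the guide's 5' base, so a
  # window ending in T yields a guide that already starts with A
  t_a <- build_bsj_target(c("CCCCCGACGT", "GACGTCCCCC"), flank = 5)
  ago_a <- design_agoshrna(t_a, stem_len = 10)  # window "GACGTGACGT" ends T
  expect_false(ago_a$plus_one_substituted)
  expect_equal(substr(chartr("U", "T", ago_a$guide_seqs), 1, 1), "A")

  t_b <- build_bsj_target(c("CCCCCGACGT", "GACGGCCCCC"), flank = 5)
  ago_b <- design_agoshrna(t_b, stem_len = 10)  # window ends G -> guide starts C
  expect_true(ago_b$plus_one_substituted)
  expect_equal(substr(chartr("U", "T", ago_b$guide_seqs), 1, 1), "A")

  expect_error(design_agoshrna(shrna_demo_target(3), stem_len = 18),
               class = "circscape_design_error")  # < 5 nt on one side
})

test_that("off-target scan recovers planted sites and respects the mismatch cap", {
  guide <- "ACGGTCATTGACCAGTTCA"
  tx <- gen_transcriptome(8, 800, planted_guide = guide, seed = 13)
  hits <- offtarget_scan(guide, tx$records)
  planted <- hits[hits$transcript_id == tx$planted$transcript &
                    hits$position == tx$planted$position, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$mismatches, 0L)
  expect_equal(planted$strand, "+")

  expect_equal(nrow(offtarget_scan(guide, character(0))), 0L)

  tx3 <- gen_transcriptome(8, 800, planted_guide = guide,
                           n_mismatches = 3, seed = 17)
  hits3 <- offtarget_scan(guide, tx3$records, max_mismatch = 2)
  expect_false(any(hits3$transcript_id == tx3$planted$transcript &
                     hits3$position == tx3$planted$position))

  # model transcripts (XM_/XR_) are excluded from the scan
  named <- tx$records
  names(named)[names(named) == tx$planted$transcript] <- "XM_900001"
  expect_false("XM_900001" %in% offtarget_scan(guide, named)$transcript_id)
})

test_that("off-target scan equals the brute-force all-positions oracle", {
  set.seed(404)
  guide <- rand_dna(18)
  for (i in 1:12) {
    tx <- list(records = setNames(
      vapply(1:4, function(j) rand_dna(300), character(1)),
      c("NM_01", "NM_02", "XM_03", "NM_04")
    ))
    # plant a near-match to exercise nonzero mismatch counts
    site <- revcomp_chr(guide)
    substr(site, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(site, 4, 4))[1]
    pos <- sample(1:(300 - 18), 1)
    substr(tx$records[["NM_02"]], pos, pos + 17) <- site
    mine <- offtarget_scan(guide, tx$records, max_mismatch = 2, min_word = 7)
    oracle <- offtarget_oracle(guide, tx$records, max_mismatch = 2, min_word = 7)
    key <- function(df) df[order(df$transcript_id, df$position, df$strand),
                           c("transcript_id", "position", "strand", "mismatches")]
    expect_equal(key(mine), key(oracle), ignore_attr = TRUE)
  }
})

test_that("DEG cross-referencing is a set intersection with optional mapping", {
  hits <- data.frame(transcript_id = c("G1", "G2"), stringsAsFactors = FALSE)
  expect_equal(cross_reference_offtargets(hits, c("G2", "G3")), "G2")
  expect_length(cross_reference_offtargets(hits, c("G5", "G6")), 0L)
  mapped <- cross_reference_offtargets(
    data.frame(transcript_id = "NM_1"), c("PRDX6"),
    gene_map = c(NM_1 = "PRDX6")
  )
  expect_equal(mapped, "PRDX6")
})
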