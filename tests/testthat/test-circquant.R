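toy_calls <- function(ids) {
  n <- length(ids)
  data.frame(chrom = rep("chr1", n), start = ids * 100L,
             end = ids * 100L + 50L, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("caller harmonization flags shared and single-caller candidates", {
  a <- toy_calls(1:5)
  b <- toy_calls(1:3)
  h <- harmonize_callers(a, b)
  expect_equal(nrow(h), 5L)
  expect_equal(sum(h$detected_by_both), 3L)
  expect_true(all(h$inspection[h$detected_by_both] == "pass"))
  expect_true(all(h$inspection[!h$detected_by_both] == "unreviewed"))

  # exclusion list removes one unshared candidate on request: 4 retained
  excl <- h$id[!h$detected_by_both][1]
  h2 <- harmonize_callers(a, b, exclusion = excl, drop_failed = TRUE)
  expect_equal(nrow(h2), 4L)
  expect_false(excl %in% h2$id)

  bad <- toy_calls(1:2); bad$start <- bad$end + 10L
  expect_error(harmonize_callers(bad, b), class = "circscape_format_error")
})

test_that("high-abundance filter keeps rows with mean >= threshold, inclusively", {
  bsj <- rbind(rep(5, 15),                       # mean exactly 5 -> kept
               c(rep(5, 14), 4),                 # mean 4.93 -> dropped
               rep(80, 15))
  jcs <- make_jcs(bsj)
  kept <- filter_high_abundance(jcs, min_mean = 5)
  expect_equal(nrow(kept$candidates), 2L)
  expect_equal(rownames(kept$bsj), rownames(jcs$bsj)[c(1, 3)])

  expect_equal(filter_high_abundance(jcs, min_mean = 0)$candidates,
               jcs$candidates)
  # a total of exactly 75 reads over 15 samples is retained
  jcs75 <- make_jcs(matrix(c(rep(5, 15)), nrow = 1))
  expect_equal(sum(jcs75$bsj), 75)
  expect_equal(nrow(filter_high_abundance(jcs75, 5)$candidates), 1L)
})

test_that("high-abundance filter equals brute-force row-mean filtering", {
  set.seed(101)
  for (i in 1:25) {
    m <- matrix(rpois(12 * 6, lambda = 6), nrow = 12)
    jcs <- make_jcs(m)
    thr <- runif(1, 0, 10)
    kept <- filter_high_abundance(jcs, min_mean = thr)
    brute <- apply(jcs$bsj, 1, function(r) sum(r) / length(r) >= thr)
    expect_equal(kept$candidates$id, jcs$candidates$id[brute])
  }
})

test_that("RPM follows the reads-per-million formula and conserves totals", {
  jcs <- make_jcs(matrix(c(50, 0), nrow = 2), library_size = 1e7)
  r <- rpm(jcs)
  expect_equal(unname(r[1, 1]), 5)
  expect_equal(unname(r[2, 1]), 0)

  jcs2 <- make_jcs(matrix(c(50, 0), nrow = 2), library_size = 2e7)
  expect_equal(rpm(jcs2)[1, 1], r[1, 1] / 2)

  set.seed(7)
  m <- matrix(rpois(40, 20), nrow = 8)
  lib <- runif(5, 5e6, 2e7)
  jcs3 <- make_jcs(m, library_size = lib)
  expect_equal(unname(colSums(rpm(jcs3))), unname(colSums(m) / lib * 1e6))
})

test_that("CTL ratio matches the pseudocounted formula and is monotone", {
  jcs <- make_jcs(matrix(10, 1, 1), donor = matrix(4, 1, 1),
                  acceptor = matrix(6, 1, 1))
  expect_equal(unname(ctl_ratio(jcs)[1, 1]), 10 / 6)

  jcs0 <- make_jcs(matrix(5, 1, 1))  # donor = acceptor = 0
  expect_equal(unname(ctl_ratio(jcs0)[1, 1]), 5)
  jcsz <- make_jcs(matrix(0, 1, 1), donor = matrix(9, 1, 1))
  expect_equal(unname(ctl_ratio(jcsz)[1, 1]), 0)

  # monotone: increasing bsj raises the ratio, increasing linear lowers it
  base <- ctl_ratio(make_jcs(matrix(10, 1, 1), matrix(4, 1, 1), matrix(4, 1, 1)))[1, 1]
  up_bsj <- ctl_ratio(make_jcs(matrix(11, 1, 1), matrix(4, 1, 1), matrix(4, 1, 1)))[1, 1]
  up_lin <- ctl_ratio(make_jcs(matrix(10, 1, 1), matrix(5, 1, 1), matrix(4, 1, 1)))[1, 1]
  expect_gt(up_bsj, base)
  expect_lt(up_lin, base)
  expect_error(ctl_ratio(jcs, pseudocount = 0), class = "circscape_parameter_error")
})

test_that("median-of-ratios reproduces the hand-computed size factors", {
  m <- rbind(c(100, 10), c(200, 20))
  nr <- median_of_ratios(m)
  expect_equal(unname(nr$size_factors), c(sqrt(10), 1 / sqrt(10)))
  expect_equal(nr$normalized_counts[, 1], nr$normalized_counts[, 2])

  same <- matrix(rep(c(5, 50, 500), 4), ncol = 4)
  expect_equal(unname(median_of_ratios(same)$size_factors), rep(1, 4))

  # only relative depth matters: a global rescaling leaves size factors
  # unchanged, while scaling one column by c scales its size factor
  # relative to the others by c (the reference absorbs a common c^(1/m))
  set.seed(3)
  m2 <- matrix(rpois(30, 50) + 1, ncol = 3)
  sf <- median_of_ratios(m2)$size_factors
  expect_equal(median_of_ratios(m2 * 4)$size_factors, sf)
  m2c <- m2; m2c[, 2] <- m2c[, 2] * 4
  sfc <- median_of_ratios(m2c)$size_factors
  expect_equal(sfc[2] / sfc[1], 4 * sf[2] / sf[1])
  expect_equal(sfc[3] / sfc[1], sf[3] / sf[1])
  # row permutation invariance
  expect_equal(median_of_ratios(m2[sample(nrow(m2)), ])$size_factors, sf)

  expect_error(median_of_ratios(rbind(c(0, 1), c(2, 0))),
               class = "circscape_normalization_error")
})

test_that("median-of-ratios agrees with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(200 * 6, mu = 50, size = 5), ncol = 6)
  ours <- median_of_ratios(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("log2 z-scaling matches hand values and normalizes rows", {
  z <- log2_z_matrix(rbind(c(1, 3)))
  expect_equal(unname(z[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  zc <- log2_z_matrix(rbind(c(4, 4, 4)))
  expect_equal(unname(zc[1, ]), c(0, 0, 0))

  set.seed(8)
  m <- matrix(rpois(50, 30), nrow = 5)
  z2 <- log2_z_matrix(m)
  expect_equal(unname(rowMeans(z2)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 5), tolerance = 1e-12)
})

test_that("expression summary aggregates per-condition means", {
  set.seed(12)
  m <- matrix(rpois(24, 40), nrow = 4)
  jcs <- make_jcs(m, donor = matrix(10L, 4, 6), acceptor = matrix(10L, 4, 6),
                  conditions = rep(c("a", "b"), each = 3))
  s <- expression_summary(jcs)
  expect_equal(dim(s$mean_rpm), c(4L, 2L))
  expect_equal(unname(s$mean_rpm[, "a"]), unname(rowMeans(s$rpm[, 1:3])))
  expect_equal(unname(s$mean_ctl[, "b"]), unname(rowMeans(s$ctl[, 4:6])))
})
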