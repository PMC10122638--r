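test_that("fold change follows the pseudocounted ratio", {
  expect_equal(fold_change(2, 8)$fc, 4)
  expect_equal(fold_change(2, 8)$log2fc, 2)
  expect_equal(fold_change(3, 3)$fc, 1)
  expect_equal(fold_change(3, 3)$log2fc, 0)
  expect_equal(fold_change(0, 3, pseudocount = 1)$fc, 4)
  expect_error(fold_change(0, 0, pseudocount = 0),
               class = "circscape_undefined_error")
  v <- fold_change(c(1, 2), c(2, 8))
  expect_equal(v$fc, c(2, 4))
})

test_that("regulation classes use strict more-than-threshold-fold rules", {
  expect_equal(classify_regulation(log2(2.5)), "up")
  expect_equal(classify_regulation(1), "unchanged")     # exactly two-fold
  expect_equal(classify_regulation(log2(0.4)), "down")
  expect_equal(classify_regulation(-1), "unchanged")    # exactly half
  expect_error(classify_regulation(1, threshold_fold = 1),
               class = "circscape_parameter_error")
})

test_that("D'Agostino-Pearson K2 matches frozen reference values", {
  # expected values computed once with an independent reference
  # implementation of the omnibus test on these exact fixtures
  cases <- list(
    list(gen = function() { set.seed(42); rnorm(1000) },
         k2 = 0.8849610075, p = 0.642440866),
    list(gen = function() { set.seed(99); rexp(1000) },
         k2 = 402.1679152, p = 4.681088182e-88),
    list(gen = function() { set.seed(7); rnorm(50, 10, 2) },
         k2 = 2.553063989, p = 0.2790032092),
    list(gen = function() c(1.2, 3.4, 2.2, 5.6, 0.1, 8.9, 4.4, 2.0, 3.3, 7.7),
         k2 = 0.9275526502, p = 0.6289042088)
  )
  for (cs in cases) {
    r <- dagostino_pearson(cs$gen())
    expect_equal(r$k2, cs$k2, tolerance = 1e-8)
    expect_equal(r$p_value, cs$p, tolerance = 1e-6)
    expect_gte(r$k2, 0)
  }
  expect_error(dagostino_pearson(rnorm(7)),
               class = "circscape_sample_size_error")
})

test_that("normal draws pass and skewed draws fail the normality gate", {
  set.seed(1)
  expect_gt(dagostino_pearson(rnorm(1000))$p_value, 0.01)
  set.seed(2)
  expect_lt(dagostino_pearson(rexp(1000))$p_value, 1e-6)
})

test_that("signed-rank exact p equals full sign-assignment enumeration", {
  # hand case: n = 5, all differences positive -> two-sided p = 2/32
  w <- wilcoxon_signed_rank(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$method, "exact")

  set.seed(314)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    a <- round(rnorm(n, 0, 2), 1)
    b <- round(a + rnorm(n, 0.5, 2), 1)   # rounding induces ties and zeros
    mine <- wilcoxon_signed_rank(a, b)
    expect_equal(mine$p_value, wilcoxon_enum_oracle(a, b), tolerance = 1e-12,
                 info = sprintf("case %d", i))
  }
})

test_that("signed-rank normal approximation tracks the stats wilcox.test", {
  set.seed(55)
  a <- rnorm(80); b <- a + rnorm(80, 0.3)
  mine <- wilcoxon_signed_rank(a, b)
  ref <- wilcox.test(b, a, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(mine$method, "normal")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(mine$statistic), unname(ref$statistic))
})

test_that("global shift test gates on normality and handles degeneracy", {
  set.seed(21)
  a <- rexp(100)
  expect_equal(global_shift_test(a, a)$p_value, 1)
  expect_equal(global_shift_test(a, a)$test_used, "degenerate")
  expect_equal(global_shift_test(a, a)$n_pairs_used, 0L)

  b <- a * 2 + rexp(100, 5)
  gs <- global_shift_test(a, b)
  expect_equal(gs$test_used, "wilcoxon")   # skewed data fail the gate
  expect_lt(gs$p_value, 1e-6)

  set.seed(26)
  x <- rnorm(60); y <- x + rnorm(60, 0.1, 0.2)
  gs2 <- global_shift_test(x, y)
  expect_equal(gs2$test_used, "paired_t")  # all three gates pass
  expect_true(all(gs2$normality_p >= 0.05))
})

test_that("coupling regression matches OLS identities", {
  x <- seq_len(10)
  cr <- coupling_regression(x, 2 * x)
  expect_equal(cr$r_squared, 1)
  expect_equal(cr$slope, 2)
  expect_equal(cr$p_value, 0)

  set.seed(77)
  x <- rnorm(1000); y <- rnorm(1000)
  cr2 <- coupling_regression(x, y)
  expect_lt(cr2$r_squared, 0.02)

  # slope invariant under adding a constant to y; F equals t^2 from lm
  y2 <- x * 0.7 + rnorm(1000)
  cr3 <- coupling_regression(x, y2)
  cr4 <- coupling_regression(x, y2 + 13)
  expect_equal(cr3$slope, cr4$slope)
  fit <- summary(lm(y2 ~ x))
  expect_equal(cr3$f_statistic, unname(fit$coefficients["x", "t value"]^2),
               tolerance = 1e-10)
  expect_equal(cr3$p_value, unname(fit$coefficients["x", "Pr(>|t|)"]),
               tolerance = 1e-10)
  expect_error(coupling_regression(rep(1, 10), rnorm(10)),
               class = "circscape_regression_error")
  expect_error(coupling_regression(1:2, 1:2), class = "circscape_regression_error")
})

test_that("threshold filter applies all strict inequalities", {
  rec <- data.frame(
    id = paste0("g", 1:6),
    basemean = c(50, 50, 10, 50, 5, 50),
    log2fc = c(1, 0.5, 1, -2, 3, 0.51),
    p_value = c(0.01, 0.01, 0.01, 0.05, 0.001, 0.049),
    adj_p = c(0.02, 0.2, 0.02, 0.2, 0.01, 0.2),
    stringsAsFactors = FALSE
  )
  out <- threshold_filter(rec)
  brute <- rec[rec$p_value < 0.05 & rec$basemean > 10 & abs(rec$log2fc) > 0.5, ]
  expect_equal(out$id, brute$id)
  expect_false("g2" %in% out$id)  # |log2fc| = 0.5 exactly
  expect_false("g3" %in% out$id)  # basemean = 10 exactly
  expect_false("g4" %in% out$id)  # p = 0.05 exactly

  # adj mode skips the basemean filter when bm_min is NULL
  out_adj <- threshold_filter(rec, bm_min = NULL, use_adj = TRUE)
  expect_setequal(out_adj$id, c("g1", "g3", "g5"))
  expect_equal(nrow(threshold_filter(rec[0, ])), 0L)
  rec$adj_p <- NULL
  expect_error(threshold_filter(rec, use_adj = TRUE),
               class = "circscape_data_error")
})

test_that("BH adjustment matches the hand step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(6)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "circscape_data_error")
})

test_that("MA tables pair expression with fold change and class", {
  a <- c(10, 20, 30); m <- c(1.5, 0, -2)
  tab <- ma_table(a, m, id = c("x", "y", "z"))
  expect_equal(tab$A, a)
  expect_equal(tab$M, m)
  expect_equal(tab$class, classify_regulation(m))
  expect_equal(nrow(ma_table(numeric(0), numeric(0))), 0L)
  expect_error(ma_table(1:3, 1:2), class = "circscape_data_error")
})
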