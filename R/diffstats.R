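# Differential and coupling statistics: fold-change classification, the
# D'Agostino-Pearson omnibus normality test, the normality-gated global
# expression-shift test (Wilcoxon matched-pairs signed-rank with exact
# small-sample p-values), circular-linear coupling regression, strict
# threshold filters and BH adjustment.

#' Fold change between two condition means
#'
#' `fc = (mean_b + c) / (mean_a + c)`, `log2fc = log2(fc)`, with a shared
#' pseudocount `c`. Vectorized over candidates.
#'
#' @param mean_a,mean_b Nonnegative condition means (reference first).
#' @param pseudocount Pseudocount `c >= 0`; when 0, both means must be
#'   positive elementwise.
#' @return List with numeric vectors `fc` and `log2fc`.
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 0) {
  if (any(mean_a < 0) || any(mean_b < 0)) {
    stop_circscape("means must be nonnegative", "circscape_data_error")
  }
  if (pseudocount < 0) {
    stop_circscape("pseudocount must be >= 0", "circscape_parameter_error")
  }
  if (pseudocount == 0 && any(mean_a == 0 & mean_b == 0)) {
    stop_circscape("fold change undefined: both means zero with pseudocount 0",
                   "circscape_undefined_error")
  }
  fc <- (mean_b + pseudocount) / (mean_a + pseudocount)
  list(fc = fc, log2fc = log2(fc))
}

#' Classify regulation by a fold-change threshold
#'
#' "More than `threshold_fold`-fold" is read strictly: `up` iff
#' `fc > threshold_fold`, `down` iff `fc < 1/threshold_fold`, otherwise
#' `unchanged`; a fold change of exactly the threshold is unchanged.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param threshold_fold Fold threshold > 1 (default 2).
#' @return Character vector in `up`/`down`/`unchanged`.
#' @export
classify_regulation <- function(log2fc, threshold_fold = 2) {
  if (!is.numeric(threshold_fold) || threshold_fold <= 1) {
    stop_circscape("threshold_fold must be > 1", "circscape_parameter_error")
  }
  lt <- log2(threshold_fold)
  ifelse(log2fc > lt, "up", ifelse(log2fc < -lt, "down", "unchanged"))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus statistic combines the transformed sample skewness
#' z-score (D'Agostino 1970) and the transformed sample kurtosis z-score
#' (Anscombe & Glynn 1983): `K2 = Zskew^2 + Zkurt^2`, referred to a
#' chi-square distribution with 2 degrees of freedom.
#'
#' @param values Numeric vector, `n >= 8` after NA removal.
#' @return List with `k2` and `p_value` (plus the component z-scores).
#' @export
dagostino_pearson <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 8) {
    stop_circscape("D'Agostino-Pearson test requires n >= 8",
                   "circscape_sample_size_error")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) {
    stop_circscape("all values identical; normality test undefined",
                   "circscape_data_error")
  }
  b1 <- m3 / m2^1.5        # sample skewness g1
  b2 <- m4 / m2^2          # sample kurtosis g2 + 3

  # skewness z (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z_kurt <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(k2 = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (Wilcoxon's convention), ties in the absolute differences receive
#' mid-ranks. For `n <= exact_limit` nonzero pairs the p-value is exact,
#' computed from the permutation distribution of the positive-rank sum over
#' all 2^n sign assignments (evaluated by convolution over the doubled
#' mid-ranks, so ties are handled exactly); above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param exact_limit Largest n for which the exact distribution is used
#'   (default 25).
#' @param correct Continuity correction in the normal approximation.
#' @return List with `statistic` (positive-rank sum V), `p_value`,
#'   `n_pairs_used` (nonzero pairs) and `method` ("exact"/"normal"/
#'   "degenerate").
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25, correct = TRUE) {
  if (length(a) != length(b)) {
    stop_circscape("paired vectors must have equal length", "circscape_data_error")
  }
  d <- b - a
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_pairs_used = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of V over all 2^n sign flips, on doubled ranks (integers)
    w <- as.integer(round(2 * r))
    total <- sum(w)
    dist <- numeric(total + 1)   # dist[k+1] = #assignments with 2V = k
    dist[1] <- 1
    for (wi in w) {
      shifted <- c(rep(0, wi), dist[seq_len(total + 1 - wi)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- round(2 * v)
    p_le <- sum(dist[seq_len(v2 + 1)])
    p_ge <- sum(dist[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- v - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = v, p_value = p, n_pairs_used = as.integer(n), method = method)
}

#' Global expression-shift test with a normality gate
#'
#' Tests whether paired per-candidate expression values shift between two
#' sample groups. Both vectors and their paired differences are first
#' checked with the D'Agostino-Pearson normality test; if any of the three
#' fails at `alpha_normality`, the nonparametric Wilcoxon matched-pairs
#' signed-rank test is used (circRNA expression distributions are typically
#' right-skewed, so this is the usual branch), otherwise a paired t-test.
#'
#' @param paired_a,paired_b Paired expression vectors (e.g. per-candidate
#'   `log2(RPM + 1)` averaged over replicates), equal length, `n >= 8`.
#' @param alpha_normality Significance level of the normality gate.
#' @return Object of class `global_shift_result`: `normality_p` (named, for
#'   a/b/differences), `test_used`, `statistic`, `p_value`, `n_pairs_used`.
#' @export
global_shift_test <- function(paired_a, paired_b, alpha_normality = 0.05) {
  if (length(paired_a) != length(paired_b)) {
    stop_circscape("paired vectors must have equal length", "circscape_data_error")
  }
  n <- length(paired_a)
  if (n < 8) {
    stop_circscape("global shift test requires n >= 8 pairs",
                   "circscape_sample_size_error")
  }
  d <- paired_b - paired_a
  if (all(d == 0)) {
    res <- list(normality_p = c(a = NA_real_, b = NA_real_, diff = NA_real_),
                test_used = "degenerate", statistic = 0, p_value = 1,
                n_pairs_used = 0L)
    class(res) <- "global_shift_result"
    return(res)
  }
  safe_norm_p <- function(x) {
    if (stats::sd(x) == 0) 0 else dagostino_pearson(x)$p_value
  }
  norm_p <- c(a = safe_norm_p(paired_a), b = safe_norm_p(paired_b),
              diff = safe_norm_p(d))
  if (any(norm_p < alpha_normality)) {
    w <- wilcoxon_signed_rank(paired_a, paired_b)
    res <- list(normality_p = norm_p, test_used = "wilcoxon",
                statistic = w$statistic, p_value = w$p_value,
                n_pairs_used = w$n_pairs_used)
  } else {
    tt <- stats::t.test(paired_b, paired_a, paired = TRUE)
    res <- list(normality_p = norm_p, test_used = "paired_t",
                statistic = unname(tt$statistic), p_value = tt$p.value,
                n_pairs_used = as.integer(n))
  }
  class(res) <- "global_shift_result"
  res
}

#' @export
print.global_shift_result <- function(x, ...) {
  cat(sprintf("global shift test: %s, statistic = %.4g, p = %.4g (n pairs used = %d)\n",
              x$test_used, x$statistic, x$p_value, x$n_pairs_used))
  invisible(x)
}

#' Circular-linear coupling regression
#'
#' Ordinary least squares of linear-host fold changes on circular fold
#' changes, with the squared Pearson correlation and the F-test of a
#' non-zero slope: `F = r2 * (n - 2) / (1 - r2)` on (1, n - 2) degrees of
#' freedom (identical to the two-sided t-test on the slope).
#'
#' @param x Per-candidate circular log2 fold changes (not constant).
#' @param y Per-candidate linear log2 fold changes.
#' @return Object of class `coupling_result`: `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `p_value`, `n`.
#' @export
coupling_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    stop_circscape("coupling regression requires n >= 3", "circscape_regression_error")
  }
  if (stats::sd(x) == 0) {
    stop_circscape("predictor is constant; slope undefined",
                   "circscape_regression_error")
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  f <- if (r2 >= 1) Inf else r2 * (n - 2) / (1 - r2)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 f_statistic = f, p_value = p, n = n),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("coupling regression: slope = %.4g, R^2 = %.4g, F(1,%d) = %.4g, p = %.4g\n",
              x$slope, x$r_squared, x$n - 2, x$f_statistic, x$p_value))
  invisible(x)
}

#' Strict threshold filter for differential-expression records
#'
#' Retains records satisfying all of: `p < p_max`, `basemean > bm_min`
#' (skipped when `bm_min` is `NULL`), `|log2fc| > abs_log2fc_min`. All
#' comparisons are strict, matching the printed `<`/`>` thresholds.
#'
#' @param records Data frame with columns `id`, `basemean`, `log2fc`,
#'   `p_value` and (when `use_adj`) `adj_p`.
#' @param p_max P-value cutoff (strict).
#' @param bm_min Base-mean cutoff (strict), or `NULL` to skip.
#' @param abs_log2fc_min Absolute log2 fold-change cutoff (strict).
#' @param use_adj Filter on `adj_p` instead of `p_value`.
#' @return The retained rows of `records`.
#' @export
threshold_filter <- function(records, p_max = 0.05, bm_min = 10,
                             abs_log2fc_min = 0.5, use_adj = FALSE) {
  if (nrow(records) == 0) return(records)
  pcol <- if (use_adj) "adj_p" else "p_value"
  if (!pcol %in% names(records) || anyNA(records[[pcol]])) {
    stop_circscape(sprintf("records lack usable '%s' values", pcol),
                   "circscape_data_error")
  }
  keep <- records[[pcol]] < p_max & abs(records$log2fc) > abs_log2fc_min
  if (!is.null(bm_min)) keep <- keep & records$basemean > bm_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()] after validation).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_circscape("p-values must lie in [0, 1]", "circscape_data_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' MA table of average expression versus log2 fold change
#'
#' Pairs the mean expression (A) with the log2 fold change (M) per
#' candidate and attaches the fold-change regulation class, the table
#' behind an MA plot.
#'
#' @param mean_expr Average expression across the compared samples.
#' @param log2fc Log2 fold changes, same length.
#' @param threshold_fold Fold threshold for the class column.
#' @param id Optional identifiers.
#' @return Data frame with columns `id` (if given), `A`, `M`, `class`.
#' @export
ma_table <- function(mean_expr, log2fc, threshold_fold = 2, id = NULL) {
  if (length(mean_expr) != length(log2fc)) {
    stop_circscape("mean_expr and log2fc must have equal length",
                   "circscape_data_error")
  }
  out <- data.frame(A = mean_expr, M = log2fc,
                    class = classify_regulation(log2fc, threshold_fold),
                    stringsAsFactors = FALSE)
  if (!is.null(id)) out <- cbind(data.frame(id = id, stringsAsFactors = FALSE), out)
  out
}

#' Minimal MA plot
#'
#' Base-graphics scatter of `M` against `A` (log-scaled x axis) colouring
#' candidates by regulation class.
#'
#' @param tab A data frame from [ma_table()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_ma <- function(tab, ...) {
  cols <- c(up = "firebrick", down = "steelblue", unchanged = "grey60")
  graphics::plot(pmax(tab$A, .Machine$double.xmin), tab$M, log = "x",
                 col = cols[tab$class], pch = 16, cex = 0.6,
                 xlab = "mean expression (A)", ylab = "log2 fold change (M)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(tab)
}
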