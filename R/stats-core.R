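#' @keywords internal
new_test_result <- function(statistic, df, p, method, corrected = FALSE,
                            degenerate = FALSE) {
  structure(
    list(statistic = statistic, df = df, p = p, method = method,
         corrected = corrected, degenerate = degenerate),
    class = "aneu_test"
  )
}

#' @export
print.aneu_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic), " df =", format(x$df),
      " p =", format(x$p), "\n")
  if (isTRUE(x$degenerate)) cat("  (degenerate input)\n")
  invisible(x)
}

#' Chi-square goodness-of-fit test
#'
#' Tests observed category counts against expected proportions (uniform by
#' default). This is the directional bias test applied throughout the package
#' to (up, down) DEG counts: under no bias the two categories are expected in
#' equal proportion. No continuity correction is applied unless requested;
#' the uncorrected statistic is the one whose p-values match the published
#' bias tests this package reproduces.
#'
#' @param observed non-negative integer vector of category counts (total > 0).
#' @param expected_proportions proportions summing to 1; defaults to uniform.
#' @param correction apply a Yates-style continuity correction
#'   (\eqn{(|O-E|-0.5)^2/E}).
#' @return An `aneu_test` with fields `statistic`, `df`, `p`, `method`.
#' @examples
#' chisq_gof(c(1561, 1770))  # p = 2.93e-4
#' @export
chisq_gof <- function(observed, expected_proportions = NULL,
                      correction = FALSE) {
  if (any(observed < 0) || anyNA(observed))
    stop("observed counts must be non-negative and non-missing")
  total <- sum(observed)
  if (total <= 0) stop("total observed count must be positive")
  k <- length(observed)
  if (is.null(expected_proportions))
    expected_proportions <- rep(1 / k, k)
  if (length(expected_proportions) != k)
    stop("expected_proportions must match the number of categories")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop("expected_proportions must sum to 1")
  expected <- total * expected_proportions
  if (any(expected <= 0)) stop("every expected cell must be positive")
  dev <- abs(observed - expected)
  if (correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- k - 1
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  new_test_result(stat, df, p, "chi-square goodness-of-fit", correction)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param correction apply the Yates continuity correction.
#' @return An `aneu_test`.
#' @export
chisq_contingency <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("table must be 2x2")
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("every margin of the table must be positive")
  res <- suppressWarnings(stats::chisq.test(table, correct = correction))
  new_test_result(unname(res$statistic), unname(res$parameter), res$p.value,
                  "Pearson chi-square (2x2)", correction)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Welch two-sample t-test
#'
#' Two-sided Welch t with Satterthwaite degrees of freedom. When both samples
#' have zero variance the statistic is undefined; the result is flagged
#' `degenerate` with `p = NA` and callers decide by the sign of the mean
#' difference.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return An `aneu_test`; `degenerate = TRUE` when both variances are zero.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t needs at least 2 observations per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(new_test_result(NA_real_, NA_real_, NA_real_,
                           "Welch two-sample t", degenerate = TRUE))
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  new_test_result(unname(res$statistic), unname(res$parameter), res$p.value,
                  "Welch two-sample t")
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test of paired differences against zero.
#' Zero differences are dropped. For `n <= exact_max_n` the p-value comes
#' from the exact null distribution of the positive-rank sum, computed by a
#' generating-function convolution over doubled (integer) midranks, so ties
#' are handled exactly; above that a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param diffs numeric vector of differences.
#' @param exact_max_n largest n for which the exact distribution is used.
#' @return An `aneu_test`; `statistic` is the positive-rank sum W+.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max_n = 25) {
  if (anyNA(diffs)) stop("differences must be non-missing")
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    return(new_test_result(0, NA_real_, 1, "Wilcoxon signed-rank",
                           degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # exact distribution of W+ over the 2^n equiprobable sign assignments,
    # on doubled ranks so midranks (x.5) have integer support
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    f <- numeric(maxs + 1)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(maxs + 1 - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    w2 <- round(2 * w)
    p_lo <- sum(f[seq_len(w2 + 1)])              # P(W+ <= w)
    p_hi <- sum(f[(w2 + 1):(maxs + 1)])          # P(W+ >= w)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  new_test_result(w, NA_real_, p, method)
}
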