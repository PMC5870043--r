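#' Compensation class labels
#' @export
compensation_classes <- function() {
  c("non_expressed", "non_compensated", "compensated", "anti_compensated")
}

#' Classify one one-dose gene against the halved-expression null
#'
#' The null hypothesis is that expression of a one-dose gene in the test
#' line is exactly half its two-dose reference expression. It is tested with
#' a Welch two-sample t between the test replicates and the halved reference
#' replicates, on the log2(x + 1) scale by default. Null not rejected:
#' `non_compensated`; rejected with mean above the halved expectation:
#' `compensated`; rejected below: `anti_compensated`. Genes whose reference
#' mean is at or below `nonexpr_threshold` FPKM are `non_expressed` and not
#' tested.
#'
#' @param ref_reps,test_reps FPKM replicate values (>= 2 each).
#' @param alpha rejection level of the t-test.
#' @param nonexpr_threshold reference mean FPKM at or below which the gene
#'   counts as non-expressed (default 0.1, the floor of the lowest
#'   expression bin).
#' @param scale `"log2"` (test on log2(x + 1)) or `"linear"`.
#' @return One-row data frame: `class`, `t_stat`, `p`, `mean_ref`,
#'   `mean_test`, `expected_test`, `degenerate`. When both sides have zero
#'   variance the class is decided by the sign of the difference without a
#'   p-value and flagged degenerate.
#' @export
classify_one_dose_gene <- function(ref_reps, test_reps, alpha = 0.05,
                                   nonexpr_threshold = 0.1,
                                   scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (length(ref_reps) < 2 || length(test_reps) < 2)
    stop("need at least 2 replicates on each side")
  mean_ref <- mean(ref_reps)
  mean_test <- mean(test_reps)
  expected <- mean_ref / 2
  row <- function(class, t_stat = NA_real_, p = NA_real_,
                  degenerate = FALSE) {
    data.frame(class = class, t_stat = t_stat, p = p,
               mean_ref = mean_ref, mean_test = mean_test,
               expected_test = expected, degenerate = degenerate,
               stringsAsFactors = FALSE)
  }
  if (mean_ref <= nonexpr_threshold) return(row("non_expressed"))
  x <- test_reps
  y <- ref_reps / 2
  if (scale == "log2") {
    x <- log2(x + 1)
    y <- log2(y + 1)
  }
  tt <- welch_t(x, y)
  if (tt$degenerate) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(row("non_compensated", degenerate = TRUE))
    cls <- if (mean_test > expected) "compensated" else "anti_compensated"
    return(row(cls, degenerate = TRUE))
  }
  if (tt$p >= alpha) return(row("non_compensated", tt$statistic, tt$p))
  cls <- if (mean_test > expected) "compensated" else "anti_compensated"
  row(cls, tt$statistic, tt$p)
}

#' Classify all one-dose genes on a monosomic chromosome
#'
#' Applies the halved-expression test of [classify_one_dose_gene()] to every
#' annotated gene on `chromosome`, and attaches the expression bin of the
#' reference mean. With `method = "moderated"` (the default) the per-gene
#' variance is moderated across genes (limma, trend) before testing —
#' at n = 3 the per-gene Welch t is otherwise underpowered; `"welch"` gives
#' the plain per-gene test.
#'
#' @param expr FPKM matrix.
#' @param genes gene annotation.
#' @param samples sample sheet.
#' @param test group carrying the monosomic chromosome.
#' @param reference euploid reference group.
#' @param chromosome the dosage-reduced chromosome.
#' @param alpha rejection level.
#' @param nonexpr_threshold see [classify_one_dose_gene()].
#' @param method `"moderated"` or `"welch"`.
#' @return Data frame: `gene_id`, `class`, `t_stat`, `p`, `mean_ref`,
#'   `mean_test`, `expected_test`, `bin`, `degenerate`.
#' @export
classify_compensation <- function(expr, genes, samples, test, reference,
                                  chromosome, alpha = 0.05,
                                  nonexpr_threshold = 0.1,
                                  method = c("moderated", "welch")) {
  method <- match.arg(method)
  validate_genes(genes)
  if (!chromosome %in% genes$chromosome)
    stop("chromosome absent from annotation: ", chromosome)
  ids <- intersect(rownames(expr),
                   genes$gene_id[genes$chromosome == chromosome])
  test_ids <- group_samples(samples, test)
  ref_ids <- group_samples(samples, reference)
  if (length(test_ids) < 2 || length(ref_ids) < 2)
    stop("both groups need at least 2 replicates")
  tst <- expr[ids, test_ids, drop = FALSE]
  ref <- expr[ids, ref_ids, drop = FALSE]
  mean_ref <- rowMeans(ref)
  mean_test <- rowMeans(tst)
  if (method == "welch") {
    calls <- do.call(rbind, lapply(seq_along(ids), function(i)
      classify_one_dose_gene(ref[i, ], tst[i, ], alpha = alpha,
                             nonexpr_threshold = nonexpr_threshold)))
  } else {
    tested <- mean_ref > nonexpr_threshold
    cls <- rep("non_expressed", length(ids))
    tval <- rep(NA_real_, length(ids))
    pval <- rep(NA_real_, length(ids))
    if (any(tested)) {
      y <- cbind(log2(tst[tested, , drop = FALSE] + 1),
                 log2(ref[tested, , drop = FALSE] / 2 + 1))
      design <- cbind(Intercept = 1,
                      test = rep(c(1, 0), c(length(test_ids),
                                            length(ref_ids))))
      fit <- limma::eBayes(limma::lmFit(y, design), trend = TRUE)
      pv <- fit$p.value[, "test"]
      tv <- fit$t[, "test"]
      above <- mean_test[tested] > mean_ref[tested] / 2
      cls[tested] <- ifelse(pv >= alpha, "non_compensated",
                            ifelse(above, "compensated",
                                   "anti_compensated"))
      tval[tested] <- tv
      pval[tested] <- pv
    }
    calls <- data.frame(class = cls, t_stat = tval, p = pval,
                        mean_ref = mean_ref, mean_test = mean_test,
                        expected_test = mean_ref / 2,
                        degenerate = FALSE, stringsAsFactors = FALSE)
  }
  calls <- cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE), calls)
  calls$bin <- as.character(assign_bins(calls$mean_ref))
  rownames(calls) <- NULL
  calls
}

#' Cross-tabulate compensation classes by expression level
#'
#' Counts and row percentages of (non_compensated, compensated,
#' anti_compensated) within the low / medium / high reference-expression
#' bins, a per-row equal-proportion chi-square of
#' (compensated + anti_compensated) versus non_compensated, and the
#' genome-level class proportions over all classified genes (including
#' non_expressed).
#'
#' @param calls result of [classify_compensation()] (needs `class` and
#'   `bin`).
#' @return A `compensation_crosstab` list: `counts` (bins x classes matrix),
#'   `row_pct`, `row_bias` (named list of `aneu_test`), `overall_counts`,
#'   `overall_pct`.
#' @export
compensation_crosstab <- function(calls) {
  classes <- c("non_compensated", "compensated", "anti_compensated")
  bins <- c("low", "medium", "high")
  if (nrow(calls) == 0) {
    counts <- matrix(0L, 0, length(classes),
                     dimnames = list(character(), classes))
    return(structure(list(counts = counts, row_pct = counts,
                          row_bias = list(),
                          overall_counts = integer(), overall_pct = numeric()),
                     class = "compensation_crosstab"))
  }
  in_tab <- calls$class %in% classes & calls$bin %in% bins
  counts <- matrix(0L, length(bins), length(classes),
                   dimnames = list(bins, classes))
  tab <- table(factor(calls$bin[in_tab], levels = bins),
               factor(calls$class[in_tab], levels = classes))
  counts[] <- as.integer(tab)
  row_tot <- rowSums(counts)
  row_pct <- counts
  row_pct[] <- ifelse(row_tot > 0, round(100 * counts / row_tot, 2), NA)
  row_bias <- lapply(bins, function(b) {
    comp_anti <- counts[b, "compensated"] + counts[b, "anti_compensated"]
    non <- counts[b, "non_compensated"]
    if (comp_anti + non > 0) chisq_gof(c(comp_anti, non)) else NULL
  })
  names(row_bias) <- bins
  overall <- table(factor(calls$class, levels = compensation_classes()))
  overall_counts <- as.integer(overall)
  names(overall_counts) <- compensation_classes()
  overall_pct <- round(100 * overall_counts / sum(overall_counts), 2)
  structure(
    list(counts = counts, row_pct = row_pct, row_bias = row_bias,
         overall_counts = overall_counts, overall_pct = overall_pct),
    class = "compensation_crosstab"
  )
}

#' @export
print.compensation_crosstab <- function(x, ...) {
  cat("Compensation by expression level (counts):\n")
  print(x$counts)
  if (length(x$overall_counts) > 0) {
    cat("Overall class proportions (%):\n")
    print(x$overall_pct)
  }
  invisible(x)
}
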