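#' Per-gene log2 expression ratios along one chromosome
#'
#' For genes on the chromosome whose mean FPKM is positive in both groups
#' (the "expressed genes, FPKM > 0" filter), returns
#' log2(mean_test / mean_reference). Genes expressed in only one group are
#' excluded (log of zero is undefined); [scan_dosage()] counts them
#' separately.
#'
#' @param expr FPKM matrix.
#' @param genes gene annotation.
#' @param samples sample sheet.
#' @param test,reference group names.
#' @param chromosome chromosome name.
#' @return Named numeric vector of log2 ratios.
#' @export
chromosome_log2_ratios <- function(expr, genes, samples, test, reference,
                                   chromosome) {
  validate_genes(genes)
  if (!chromosome %in% genes$chromosome)
    stop("chromosome absent from annotation: ", chromosome)
  mt <- mean_group_expression(expr, samples, test)
  mr <- mean_group_expression(expr, samples, reference)
  on_chrom <- genes$gene_id[genes$chromosome == chromosome]
  on_chrom <- intersect(rownames(expr), on_chrom)
  use <- on_chrom[mt[on_chrom] > 0 & mr[on_chrom] > 0]
  log2(mt[use] / mr[use])
}

#' Scan chromosomes for dosage changes
#'
#' For every chromosome, takes the median per-gene log2 expression ratio of
#' the test group over the euploid reference and calls the copy number whose
#' log2 centre (log2(c/2), c in 1..3) is nearest: reduced (1 copy), normal
#' (2) or gained (3). A Wilcoxon signed-rank p of the ratios against zero is
#' reported as supporting evidence but plays no part in the call. Chromosomes
#' with fewer than `min_genes` usable genes — including alien chromosomes
#' with no reference expression, for which a ratio is undefined — get
#' `no_call` and are described by their test-only expression instead.
#'
#' @inheritParams chromosome_log2_ratios
#' @param min_genes minimum number of two-group expressed genes for a call
#'   (>= 10).
#' @return Data frame with one row per chromosome: `chromosome`,
#'   `n_genes_used`, `n_test_only`, `mean_test_fpkm`, `median_log2_ratio`,
#'   `wilcoxon_p`, `estimated_copies`, `call`.
#' @export
scan_dosage <- function(expr, genes, samples, test, reference,
                        min_genes = 10) {
  if (min_genes < 10) stop("min_genes must be >= 10")
  validate_genes(genes)
  mt <- mean_group_expression(expr, samples, test)
  mr <- mean_group_expression(expr, samples, reference)
  chroms <- unique(genes$chromosome)
  centers <- log2(c(1, 2, 3) / 2)
  calls <- c("reduced", "normal", "gained")
  out <- lapply(chroms, function(ch) {
    ids <- intersect(rownames(expr), genes$gene_id[genes$chromosome == ch])
    both <- ids[mt[ids] > 0 & mr[ids] > 0]
    test_only <- ids[mt[ids] > 0 & mr[ids] == 0]
    n <- length(both)
    if (n < min_genes) {
      return(data.frame(
        chromosome = ch, n_genes_used = n, n_test_only = length(test_only),
        mean_test_fpkm = if (length(test_only) > 0)
          mean(mt[test_only]) else 0,
        median_log2_ratio = NA_real_, wilcoxon_p = NA_real_,
        estimated_copies = NA_integer_, call = "no_call",
        stringsAsFactors = FALSE
      ))
    }
    ratios <- log2(mt[both] / mr[both])
    m <- stats::median(ratios)
    copies <- which.min(abs(m - centers))
    data.frame(
      chromosome = ch, n_genes_used = n, n_test_only = length(test_only),
      mean_test_fpkm = mean(mt[ids]),
      median_log2_ratio = m,
      wilcoxon_p = wilcoxon_signed_rank(ratios)$p,
      estimated_copies = copies, call = calls[copies],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Box-plot of per-gene log2 FPKM along chromosomes
#'
#' Visual analogue of the dosage scan: distributions of log2 FPKM of
#' expressed genes (FPKM > 0) per chromosome and group. A monosomic
#' chromosome shows a roughly one-unit downward shift in the test group.
#'
#' @inheritParams chromosome_log2_ratios
#' @param groups groups to display; default all.
#' @return A ggplot object.
#' @export
plot_dosage_boxplot <- function(expr, genes, samples, groups = NULL) {
  validate_genes(genes)
  if (is.null(groups)) groups <- unique(samples$group)
  dat <- do.call(rbind, lapply(groups, function(g) {
    m <- mean_group_expression(expr, samples, g)
    keep <- m > 0
    data.frame(
      chromosome = genes$chromosome[match(names(m)[keep], genes$gene_id)],
      log2_fpkm = log2(m[keep]), group = g, stringsAsFactors = FALSE
    )
  }))
  dat <- dat[!is.na(dat$chromosome), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chromosome,
                                    y = .data$log2_fpkm,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "log2 mean FPKM (expressed genes)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
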