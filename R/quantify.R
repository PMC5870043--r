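#' @keywords internal
validate_genes <- function(genes) {
  needed <- c("gene_id", "chromosome", "start", "end", "exonic_length")
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0)
    stop("gene annotation lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in annotation: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start > genes$end))
    stop("gene with start > end: ",
         genes$gene_id[genes$start > genes$end][1])
  if (any(genes$exonic_length <= 0))
    stop("exonic_length must be positive")
  invisible(genes)
}

#' @keywords internal
validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene ids as rownames and sample ids as colnames")
  if (anyNA(counts)) stop("count matrix has missing cells")
  if (any(counts < 0)) stop("counts must be non-negative")
  invisible(counts)
}

#' @keywords internal
group_samples <- function(samples, group) {
  ids <- samples$sample[samples$group == group]
  if (length(ids) == 0) stop("unknown group: ", group)
  ids
}

#' FPKM from a gene-level count matrix
#'
#' \eqn{FPKM(g,s) = count(g,s) \cdot 10^9 / (L_g \cdot N_s)} where \eqn{L_g}
#' is the gene's exonic length in bp and \eqn{N_s} the column sum of the
#' count matrix. Using the column sum (rather than an external mapped-read
#' total) makes the transform exactly invertible, which the tests exploit.
#'
#' @param counts genes x samples matrix of non-negative integers, gene ids as
#'   rownames.
#' @param genes gene annotation `data.frame` with `gene_id` and
#'   `exonic_length` (bp).
#' @return Matrix of FPKM values, same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, genes) {
  validate_counts(counts)
  validate_genes(genes)
  idx <- match(rownames(counts), genes$gene_id)
  if (anyNA(idx))
    stop("genes missing from annotation: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 3), collapse = ", "))
  len <- genes$exonic_length[idx]
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  counts * 1e9 / outer(len, totals)
}

#' Per-gene mean expression within a sample group
#'
#' @param expr genes x samples expression matrix (FPKM).
#' @param samples sample sheet `data.frame` with columns `sample`, `group`.
#' @param group group name.
#' @return Named numeric vector of per-gene means across the group's
#'   replicates.
#' @export
mean_group_expression <- function(expr, samples, group) {
  ids <- group_samples(samples, group)
  missing <- setdiff(ids, colnames(expr))
  if (length(missing) > 0)
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "))
  rowMeans(expr[, ids, drop = FALSE])
}

#' Between-sample normalization of an FPKM matrix
#'
#' Total-count FPKM is confounded by library composition: a strong
#' expression change on a high-abundance gene shifts the per-sample total
#' and with it every other gene's FPKM. `median_ratio` rescales each sample
#' by the median ratio of its values to a per-gene geometric-mean reference
#' (computed over genes positive in all samples), with factors standardised
#' to geometric mean 1 — the same estimator DESeq-style count models use.
#' Run once, genome-wide, before differential tests; applying it to a small
#' or mostly-perturbed gene subset would normalise real signal away.
#'
#' @param expr FPKM matrix.
#' @param method `"median_ratio"` or `"none"`.
#' @return The rescaled matrix, with the per-sample factors in attribute
#'   `norm_factors`.
#' @export
normalize_fpkm <- function(expr, method = c("median_ratio", "none")) {
  method <- match.arg(method)
  if (method == "none") {
    attr(expr, "norm_factors") <- stats::setNames(rep(1, ncol(expr)),
                                                  colnames(expr))
    return(expr)
  }
  pos <- rowSums(expr <= 0) == 0
  if (sum(pos) < 10)
    stop("median-ratio normalization needs at least 10 genes expressed ",
         "in every sample")
  ref <- exp(rowMeans(log(expr[pos, , drop = FALSE])))
  fac <- apply(expr[pos, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
  fac <- fac / exp(mean(log(fac)))
  out <- sweep(expr, 2, fac, "/")
  attr(out, "norm_factors") <- fac
  out
}

#' Expression bin labels, in increasing order
#' @export
expression_bins <- function() {
  c("non_expressed", "sub_threshold", "low", "medium", "high")
}

#' Assign reference-expression bins
#'
#' Bins partition \[0, Inf): 0 is `non_expressed`, (0, 0.1\] `sub_threshold`,
#' (0.1, 10\] `low`, (10, 100\] `medium`, (100, Inf) `high`. Interval edges
#' are closed on the right so every non-negative value maps to exactly one
#' bin (e.g. 10 is `low`).
#'
#' @param mean_ref_fpkm non-negative per-gene mean FPKM in the reference
#'   group.
#' @return Factor with levels [expression_bins()].
#' @export
assign_bins <- function(mean_ref_fpkm) {
  if (anyNA(mean_ref_fpkm) || any(mean_ref_fpkm < 0))
    stop("mean FPKM values must be non-negative and non-missing")
  cut(mean_ref_fpkm,
      breaks = c(-Inf, 0, 0.1, 10, 100, Inf),
      labels = expression_bins(),
      right = TRUE)
}
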