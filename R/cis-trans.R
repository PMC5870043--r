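#' Chromosomes whose copy number differs between two karyotypes
#'
#' @param test_karyotype,reference_karyotype named integer vectors
#'   (chromosome -> copies) over the same chromosome universe.
#' @return Character vector of copy-number-altered chromosomes.
#' @export
altered_chromosomes <- function(test_karyotype, reference_karyotype) {
  if (!setequal(names(test_karyotype), names(reference_karyotype)))
    stop("karyotypes must cover the same chromosome universe")
  ch <- names(test_karyotype)
  sort(ch[test_karyotype[ch] != reference_karyotype[ch]])
}

#' Partition DEGs into cis and trans effects
#'
#' A DEG is cis iff its gene lies on a copy-number-altered chromosome
#' (including an alien chromosome's own genes); all other located DEGs are
#' trans. Reports the trans percentage, the equal-proportion chi-square bias
#' test on (trans up, trans down) and the number of dosage-opposing genes
#' (up-regulated DEGs on reduced chromosomes).
#'
#' @param degs result of [call_degs()] (only rows with `is_deg` are used),
#'   or any data frame with `gene_id`, `direction`, `is_deg`.
#' @param genes gene annotation.
#' @param altered character vector of copy-number-altered chromosomes.
#' @param reduced chromosomes with reduced copy number, used for the
#'   dosage-opposing count; defaults to `altered`.
#' @param name comparison label.
#' @return A `cis_trans_partition` list: `name`, `altered`, `cis`, `trans`
#'   (DEG data frames with a `chromosome` column), `n_cis`, `n_trans`,
#'   `pct_trans`, `trans_bias` (`aneu_test` or NULL), `cis_up_count`,
#'   `n_unlocated`.
#' @export
partition_degs <- function(degs, genes, altered, reduced = altered,
                           name = "comparison") {
  validate_genes(genes)
  d <- degs[degs$is_deg, , drop = FALSE]
  d$chromosome <- genes$chromosome[match(d$gene_id, genes$gene_id)]
  unlocated <- is.na(d$chromosome)
  if (any(unlocated)) {
    warning(sum(unlocated), " DEG(s) not present in the annotation were ",
            "excluded from the cis/trans partition")
    d <- d[!unlocated, , drop = FALSE]
  }
  is_cis <- d$chromosome %in% altered
  cis <- d[is_cis, , drop = FALSE]
  trans <- d[!is_cis, , drop = FALSE]
  n_cis <- nrow(cis)
  n_trans <- nrow(trans)
  up <- sum(trans$direction == "up")
  down <- n_trans - up
  structure(
    list(name = name, altered = altered,
         cis = cis, trans = trans,
         n_cis = n_cis, n_trans = n_trans,
         pct_trans = if (n_cis + n_trans > 0)
           round(100 * n_trans / (n_cis + n_trans), 2) else NA_real_,
         trans_bias = if (n_trans > 0) chisq_gof(c(up, down)) else NULL,
         cis_up_count = sum(cis$direction == "up" &
                              cis$chromosome %in% reduced),
         n_unlocated = sum(unlocated)),
    class = "cis_trans_partition"
  )
}

#' @export
print.cis_trans_partition <- function(x, ...) {
  cat(x$name, ": ", x$n_cis, " cis / ", x$n_trans, " trans DEGs (",
      x$pct_trans, "% trans); altered: ",
      paste(x$altered, collapse = ", "), "\n", sep = "")
  if (!is.null(x$trans_bias))
    cat("  trans direction bias p =", format(x$trans_bias$p), "\n")
  invisible(x)
}

#' Per-chromosome susceptibility to trans effects
#'
#' For each disomic chromosome, a 2x2 chi-square (uncorrected) of
#' (DEG, non-DEG) x (this chromosome, all other disomic chromosomes), BH
#' corrected across chromosomes. Altered chromosomes are excluded.
#'
#' @param degs DEG data frame (rows with `is_deg` are used).
#' @param expressed_gene_ids ids of all expressed genes (the test universe).
#' @param genes gene annotation.
#' @param altered copy-number-altered chromosomes, excluded from the table.
#' @return Data frame: `chromosome`, `n_expressed`, `n_deg`, `expected_deg`,
#'   `chi2`, `p`, `q`.
#' @export
chromosome_susceptibility <- function(degs, expressed_gene_ids, genes,
                                      altered = character()) {
  validate_genes(genes)
  deg_ids <- degs$gene_id[degs$is_deg]
  chrom_of <- function(ids) genes$chromosome[match(ids, genes$gene_id)]
  exp_ch <- chrom_of(expressed_gene_ids)
  deg_ch <- chrom_of(deg_ids)
  keep <- !is.na(exp_ch) & !(exp_ch %in% altered)
  exp_ch <- exp_ch[keep]
  deg_ch <- deg_ch[!is.na(deg_ch) & !(deg_ch %in% altered)]
  chroms <- sort(unique(exp_ch))
  n_deg_tot <- length(deg_ch)
  n_exp_tot <- length(exp_ch)
  rows <- lapply(chroms, function(ch) {
    n_exp <- sum(exp_ch == ch)
    n_deg <- sum(deg_ch == ch)
    expected <- n_exp * n_deg_tot / n_exp_tot
    tab <- matrix(c(n_deg, n_exp - n_deg,
                    n_deg_tot - n_deg,
                    (n_exp_tot - n_exp) - (n_deg_tot - n_deg)), 2, 2)
    if (n_deg_tot == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      chi2 <- 0
      p <- 1
    } else {
      ct <- chisq_contingency(tab, correction = FALSE)
      chi2 <- ct$statistic
      p <- ct$p
    }
    data.frame(chromosome = ch, n_expressed = n_exp, n_deg = n_deg,
               expected_deg = expected, chi2 = chi2, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Direction-aware Venn overlaps of DEG lists
#'
#' Partitions the union of 2 or 3 named DEG lists into Venn regions by
#' gene id. Every gene belongs to exactly one region (the set of lists
#' containing it), so region counts always sum to the union size. With
#' `direction_aware = TRUE` each region is further split by direction:
#' `up`/`down` when the gene has the same direction in every containing
#' list, `mixed` otherwise — so e.g. the count of DEGs shared by two
#' comparisons with consistent down-regulation is the (both-region, down)
#' row.
#'
#' @param deg_lists named list (2 or 3 entries) of DEG data frames with
#'   `gene_id` and `direction`, or of plain gene-id vectors
#'   (`direction_aware` then must be FALSE).
#' @param direction_aware split regions by direction consistency.
#' @return Data frame: `region` (list names joined by `&`), optional
#'   `direction`, `n`.
#' @export
overlap_degs <- function(deg_lists, direction_aware = FALSE) {
  if (length(deg_lists) < 2 || length(deg_lists) > 3)
    stop("overlap_degs takes 2 or 3 named DEG lists")
  if (is.null(names(deg_lists)) || any(names(deg_lists) == ""))
    stop("deg_lists must be named")
  ids <- lapply(names(deg_lists), function(nm) {
    x <- deg_lists[[nm]]
    g <- if (is.data.frame(x)) x$gene_id else x
    if (anyDuplicated(g))
      stop("duplicate gene within list '", nm, "': ",
           g[duplicated(g)][1])
    g
  })
  names(ids) <- names(deg_lists)
  union_ids <- unique(unlist(ids))
  member <- sapply(ids, function(g) union_ids %in% g)
  if (length(union_ids) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL,
                                                               names(ids)))
  region <- apply(member, 1, function(m)
    paste(names(deg_lists)[m], collapse = "&"))
  # all possible regions, so empty ones are reported as zero
  combos <- unlist(lapply(seq_along(deg_lists), function(k)
    utils::combn(names(deg_lists), k, paste, collapse = "&")))
  if (!direction_aware) {
    n <- vapply(combos, function(r) sum(region == r), integer(1))
    return(data.frame(region = combos, n = unname(n),
                      stringsAsFactors = FALSE))
  }
  dirs <- sapply(names(deg_lists), function(nm) {
    x <- deg_lists[[nm]]
    if (!is.data.frame(x) || is.null(x$direction))
      stop("direction_aware overlap needs data frames with a direction ",
           "column")
    x$direction[match(union_ids, x$gene_id)]
  })
  if (length(union_ids) == 1) dirs <- matrix(dirs, nrow = 1)
  gene_dir <- vapply(seq_along(union_ids), function(i) {
    d <- unique(dirs[i, member[i, ]])
    if (length(d) == 1) d else "mixed"
  }, character(1))
  out <- do.call(rbind, lapply(combos, function(r) {
    data.frame(region = r,
               direction = c("up", "down", "mixed"),
               n = vapply(c("up", "down", "mixed"), function(dd)
                 sum(region == r & gene_dir == dd), integer(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
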