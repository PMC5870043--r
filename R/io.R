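#' Read a gene-level count matrix from TSV
#'
#' Expects a header row of sample ids with the first column holding gene
#' ids, tab-separated, no quoting. Cells must be non-negative integers.
#'
#' @param path file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  dat <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "", fill = FALSE)
  if (ncol(dat) < 2) stop("count file needs a gene id column and at least ",
                          "one sample column")
  ids <- dat[[1]]
  dup <- duplicated(ids)
  if (any(dup))
    stop("duplicate gene id '", ids[dup][1], "' at line ",
         which(dup)[1] + 1)
  vals <- as.matrix(dat[, -1, drop = FALSE])
  bad <- !grepl("^[0-9]+$", vals)
  if (any(bad)) {
    w <- arrayInd(which(bad)[1], dim(vals))
    stop("non-integer count '", vals[w[1], w[2]], "' for gene ", ids[w[1]],
         ", sample ", colnames(vals)[w[2]])
  }
  m <- matrix(as.integer(vals), nrow = nrow(vals),
              dimnames = list(ids, colnames(vals)))
  m
}

#' Write a count matrix as TSV
#' @param counts integer matrix with dimnames.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (GFF3 or flat TSV)
#'
#' GFF3 (by file extension `.gff`/`.gff3`): features of type `gene` with
#' attributes `ID`, `exonic_length` and `subgenome`. Flat TSV: columns
#' `gene_id`, `chromosome`, `start`, `end`, `exonic_length`, `subgenome`.
#' Coordinates are 1-based inclusive in both encodings. A missing
#' `exonic_length` falls back to the span length with a warning.
#'
#' @param path file path.
#' @return Gene annotation data frame.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      stop("GFF3 gene feature without an ID attribute")
    el <- suppressWarnings(as.numeric(gr$exonic_length))
    genes <- data.frame(
      gene_id = as.character(ids),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      exonic_length = el,
      subgenome = if (!is.null(gr$subgenome)) as.character(gr$subgenome)
        else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    genes <- utils::read.table(path, sep = "\t", header = TRUE,
                               quote = "", comment.char = "",
                               stringsAsFactors = FALSE)
    needed <- c("gene_id", "chromosome", "start", "end")
    missing <- setdiff(needed, names(genes))
    if (length(missing) > 0)
      stop("annotation TSV lacks column(s): ",
           paste(missing, collapse = ", "))
    if (is.null(genes$exonic_length))
      genes$exonic_length <- NA_real_
    if (is.null(genes$subgenome)) genes$subgenome <- NA_character_
  }
  no_len <- is.na(genes$exonic_length)
  if (any(no_len)) {
    warning(sum(no_len), " gene(s) without exonic_length; using the ",
            "genomic span instead")
    genes$exonic_length[no_len] <-
      genes$end[no_len] - genes$start[no_len] + 1
  }
  genes$exonic_length <- as.integer(genes$exonic_length)
  validate_genes(genes)
  genes[, c("gene_id", "chromosome", "start", "end", "exonic_length",
            "subgenome")]
}

#' Write gene annotation as flat TSV
#' @param genes annotation data frame.
#' @param path file path.
#' @export
write_annotation_tsv <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write gene annotation as GFF3
#' @param genes annotation data frame.
#' @param path file path.
#' @export
write_annotation_gff3 <- function(genes, path) {
  validate_genes(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    type = "gene",
    source = "aneuploidr",
    ID = genes$gene_id,
    exonic_length = genes$exonic_length,
    subgenome = genes$subgenome
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write the sample sheet
#'
#' TSV with columns `sample`, `group`, `replicate`; sample ids must be
#' unique.
#'
#' @param path file path.
#' @return Sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  needed <- c("sample", "group", "replicate")
  missing <- setdiff(needed, names(s))
  if (length(missing) > 0)
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(s$sample))
    stop("duplicate sample id: ", s$sample[duplicated(s$sample)][1])
  s
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write per-group karyotypes
#'
#' TSV with columns `group`, `chromosome`, `copies`.
#'
#' @param path file path.
#' @return Named list of named integer copy-number vectors.
#' @export
read_karyotypes <- function(path) {
  k <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  needed <- c("group", "chromosome", "copies")
  missing <- setdiff(needed, names(k))
  if (length(missing) > 0)
    stop("karyotype file lacks column(s): ", paste(missing, collapse = ", "))
  lapply(split(k, k$group), function(d)
    stats::setNames(as.integer(d$copies), d$chromosome))
}

#' @rdname read_karyotypes
#' @param karyotypes named list of named copy-number vectors.
#' @export
write_karyotypes <- function(karyotypes, path) {
  df <- do.call(rbind, lapply(names(karyotypes), function(g)
    data.frame(group = g, chromosome = names(karyotypes[[g]]),
               copies = as.integer(karyotypes[[g]]),
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the simulation ground-truth table
#' @param path file path.
#' @return Gene-truth data frame (long format, one row per gene x group).
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_truth
#' @param gene_truth gene-truth data frame.
#' @export
write_truth <- function(gene_truth, path) {
  utils::write.table(gene_truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write every output of a simulated experiment
#'
#' Writes `counts.tsv`, `genes.tsv`, `genes.gff3`, `samples.tsv`,
#' `karyotypes.tsv` and `truth.tsv` into `dir`.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "aneu_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    genes = file.path(dir, "genes.tsv"),
    gff3 = file.path(dir, "genes.gff3"),
    samples = file.path(dir, "samples.tsv"),
    karyotypes = file.path(dir, "karyotypes.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(sim$counts, paths["counts"])
  write_annotation_tsv(sim$genes, paths["genes"])
  write_annotation_gff3(sim$genes, paths["gff3"])
  write_sample_sheet(sim$samples, paths["samples"])
  write_karyotypes(sim$truth$karyotypes, paths["karyotypes"])
  write_truth(sim$truth$gene_truth, paths["truth"])
  invisible(paths)
}

#' @keywords internal
default_run_config <- function() {
  list(counts = NULL, annotation = NULL, samples = NULL, karyotypes = NULL,
       out_dir = NULL, reference_group = NULL,
       fc_threshold = 2, q_threshold = 0.05, alpha = 0.05,
       min_genes = 10, pseudocount = 1, de_method = "moderated",
       seed = 1)
}

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' errors (a silently ignored typo in a threshold is the main operational
#' hazard this guards against). Numeric values are converted.
#'
#' @param path file path.
#' @return Run-configuration list, defaults filled in.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- default_run_config()
  numeric_keys <- c("fc_threshold", "q_threshold", "alpha", "min_genes",
                    "pseudocount", "seed")
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (key %in% numeric_keys) as.numeric(val) else val
  }
  cfg
}

#' @keywords internal
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' quantify -> dosage scan (every non-reference group vs the euploid
#' reference) -> DEG calling (all pairwise group comparisons) -> cis/trans
#' partition, susceptibility and overlaps -> compensation (for every group
#' with a chromosome at one copy where the reference has two). Writes one
#' TSV per stage table and a single `summary.json`; any stage error aborts
#' with a stage-named message and no partial outputs are left behind.
#'
#' @param config run-configuration list (see [read_run_config()]) or path to
#'   a flat key-value config file.
#' @return Invisibly, the summary list mirrored to `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(),
                           config[!vapply(config, is.null, logical(1))])
  for (key in c("counts", "annotation", "samples", "karyotypes", "out_dir"))
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)

  counts <- run_stage("read_counts", read_counts(cfg$counts))
  genes <- run_stage("read_annotation", read_annotation(cfg$annotation))
  samples <- run_stage("read_samples", read_sample_sheet(cfg$samples))
  karyotypes <- run_stage("read_karyotypes", read_karyotypes(cfg$karyotypes))

  groups <- names(karyotypes)
  ref <- cfg$reference_group
  if (is.null(ref)) ref <- groups[1]
  if (!ref %in% groups) stop("reference_group '", ref,
                             "' has no karyotype")
  message("aneuploidr pipeline: reference = ", ref,
          ", fc_threshold = ", cfg$fc_threshold,
          ", q_threshold = ", cfg$q_threshold,
          ", alpha = ", cfg$alpha,
          ", min_genes = ", cfg$min_genes,
          ", pseudocount = ", cfg$pseudocount,
          ", de_method = ", cfg$de_method,
          ", seed = ", cfg$seed)

  expr <- run_stage("quantify", {
    raw <- compute_fpkm(counts, genes)
    normalize_fpkm(raw, method = "median_ratio")
  })

  dosage <- run_stage("dosage_scan", {
    out <- lapply(setdiff(groups, ref), function(g)
      scan_dosage(expr, genes, samples, g, ref,
                  min_genes = cfg$min_genes))
    names(out) <- setdiff(groups, ref)
    out
  })

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  # the euploid reference goes first within a pair; otherwise keep the
  # declared group order (earlier group acts as the comparison baseline)
  pairs <- lapply(pairs, function(p) if (p[2] == ref) rev(p) else p)
  comp_names <- vapply(pairs, function(p) paste(p[1], "vs", p[2], sep = "_"),
                       character(1))

  degs <- run_stage("diffexpr", {
    out <- lapply(pairs, function(p)
      call_degs(expr, samples, test = p[2], reference = p[1],
                fc_threshold = cfg$fc_threshold,
                q_threshold = cfg$q_threshold,
                pseudocount = cfg$pseudocount,
                method = cfg$de_method))
    names(out) <- comp_names
    out
  })
  deg_summaries <- lapply(comp_names, function(nm)
    summarize_comparison(nm, degs[[nm]]))
  names(deg_summaries) <- comp_names

  cis_trans <- run_stage("cis_trans", {
    out <- list()
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      altered <- altered_chromosomes(karyotypes[[p[2]]], karyotypes[[p[1]]])
      reduced <- altered[karyotypes[[p[2]]][altered] <
                           karyotypes[[p[1]]][altered]]
      part <- partition_degs(degs[[i]], genes, altered, reduced,
                             name = comp_names[i])
      susc <- chromosome_susceptibility(degs[[i]], degs[[i]]$gene_id,
                                        genes, altered)
      out[[comp_names[i]]] <- list(partition = part, susceptibility = susc)
    }
    out
  })

  overlaps <- NULL
  trans_overlaps <- NULL
  if (length(degs) >= 2 && length(degs) <= 3) {
    overlaps <- run_stage("overlap", {
      lists <- lapply(degs, function(d) d[d$is_deg, , drop = FALSE])
      overlap_degs(lists, direction_aware = TRUE)
    })
    trans_overlaps <- run_stage("overlap_trans", {
      lists <- lapply(cis_trans, function(ct) ct$partition$trans)
      if (all(vapply(lists, nrow, integer(1)) > 0))
        overlap_degs(lists, direction_aware = TRUE) else NULL
    })
  }

  compensation <- run_stage("compensation", {
    out <- list()
    for (g in setdiff(groups, ref)) {
      monos <- names(karyotypes[[g]])[karyotypes[[g]] == 1L &
                                        karyotypes[[ref]] == 2L]
      for (ch in monos) {
        calls <- classify_compensation(expr, genes, samples, g, ref, ch,
                                       alpha = cfg$alpha,
                                       method = cfg$de_method)
        out[[paste(g, ch, sep = "_")]] <-
          list(group = g, chromosome = ch, calls = calls,
               crosstab = compensation_crosstab(calls))
      }
    }
    out
  })

  summary <- list(
    thresholds = cfg[c("fc_threshold", "q_threshold", "alpha", "min_genes",
                       "pseudocount", "de_method", "seed")],
    reference_group = ref,
    norm_factors = as.list(attr(expr, "norm_factors")),
    dosage_calls = lapply(dosage, function(d)
      d[, c("chromosome", "n_genes_used", "median_log2_ratio",
            "wilcoxon_p", "estimated_copies", "call")]),
    deg_summaries = lapply(deg_summaries, function(s)
      list(n_deg = s$n_deg, n_up = s$n_up, n_down = s$n_down,
           pct_up = s$pct_up, pct_down = s$pct_down,
           bias_chi2 = if (!is.null(s$bias)) s$bias$statistic else NA,
           bias_p = if (!is.null(s$bias)) s$bias$p else NA)),
    cis_trans = lapply(cis_trans, function(ct) {
      p <- ct$partition
      list(altered = p$altered, n_cis = p$n_cis, n_trans = p$n_trans,
           pct_trans = p$pct_trans,
           trans_bias_chi2 = if (!is.null(p$trans_bias))
             p$trans_bias$statistic else NA,
           trans_bias_p = if (!is.null(p$trans_bias))
             p$trans_bias$p else NA,
           cis_up_count = p$cis_up_count)
    }),
    venn = overlaps,
    venn_trans = trans_overlaps,
    compensation = lapply(compensation, function(cc)
      list(group = cc$group, chromosome = cc$chromosome,
           counts = cc$crosstab$counts,
           overall_counts = cc$crosstab$overall_counts,
           overall_pct = cc$crosstab$overall_pct))
  )

  run_stage("write_outputs", {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    on_fail <- function(e) {
      unlink(written)
      stop(conditionMessage(e), call. = FALSE)
    }
    tryCatch({
      put <- function(df, name) {
        p <- file.path(cfg$out_dir, name)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <<- c(written, p)
      }
      for (g in names(dosage)) put(dosage[[g]], paste0("dosage_", g, ".tsv"))
      for (nm in comp_names) {
        put(degs[[nm]], paste0("degs_", nm, ".tsv"))
        ct <- cis_trans[[nm]]
        lab <- rbind(
          cbind(ct$partition$cis, effect = "cis"),
          cbind(ct$partition$trans, effect = "trans"))
        put(lab, paste0("cis_trans_", nm, ".tsv"))
        put(ct$susceptibility, paste0("susceptibility_", nm, ".tsv"))
      }
      for (nm in names(compensation))
        put(compensation[[nm]]$calls, paste0("compensation_", nm, ".tsv"))
      json_path <- file.path(cfg$out_dir, "summary.json")
      jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
      written <- c(written, json_path)
    }, error = on_fail)
  })

  invisible(summary)
}
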