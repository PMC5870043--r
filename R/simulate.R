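#' @keywords internal
stage_seed <- function(seed, k) {
  (abs(seed) + 104729L * k) %% 2147483629L
}

#' Default chromosome names for a two-subgenome genome
#' @param n_chrom_A,n_chrom_C chromosome counts per subgenome.
#' @return Character vector, A chromosomes then C chromosomes.
#' @export
default_chromosomes <- function(n_chrom_A = 10, n_chrom_C = 9) {
  c(sprintf("A%02d", seq_len(n_chrom_A)), sprintf("C%02d", seq_len(n_chrom_C)))
}

#' Default karyotypes of the three study groups
#'
#' `RBR` is the euploid A-subgenome diploid (all A chromosomes at 2 copies, C
#' chromosomes absent), `C1` the monosomic alien addition carrying one extra
#' C01, and `Cs1` the substitution line with one A01 replaced by C01
#' (A01 = 1, C01 = 1).
#'
#' @param chromosomes chromosome universe.
#' @return Named list of named integer copy-number vectors.
#' @export
default_karyotypes <- function(chromosomes = default_chromosomes()) {
  euploid <- stats::setNames(ifelse(startsWith(chromosomes, "A"), 2L, 0L),
                             chromosomes)
  addition <- euploid
  addition["C01"] <- 1L
  substitution <- euploid
  substitution["A01"] <- 1L
  substitution["C01"] <- 1L
  list(RBR = euploid, C1 = addition, Cs1 = substitution)
}

#' Simulation configuration
#'
#' Defaults mirror the three-group study design the package targets: a
#' 10 + 9 chromosome two-subgenome genome, three replicates per group, an
#' euploid reference plus an alien-addition and a substitution karyotype,
#' log-normal baseline expression, NB counts with
#' variance = mean + dispersion * mean^2, a small fraction of trans-effect
#' DEGs on disomic chromosomes, and a compensation-class mixture on one-dose
#' chromosomes.
#'
#' @param n_chrom_A,n_chrom_C chromosomes per subgenome.
#' @param genes_per_chrom genes simulated on every chromosome.
#' @param replicates_per_group biological replicates per group (>= 2).
#' @param base_expression_law mean and sd of per-gene baseline log2 FPKM.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param library_size expected fragments per sample.
#' @param karyotypes named list of per-group copy-number vectors; the first
#'   is not required to be the reference, see `reference_group`.
#' @param reference_group euploid group all comparisons are made against.
#' @param dosage_multipliers optional named list (group -> named vector of
#'   per-chromosome multipliers) overriding the copy-number-derived
#'   copies / 2 factor.
#' @param trans_effect_fraction fraction of eligible disomic-chromosome genes
#'   planted as trans-effect DEGs in each non-reference group.
#' @param trans_effect_log2fc_sd sd of the planted log2 fold change, which is
#'   drawn from Normal(0, sd) truncated to
#'   |log2FC| >= `trans_effect_min_log2fc`.
#' @param trans_effect_min_log2fc truncation bound, default 1 (twofold).
#' @param trans_effect_min_fpkm trans-DEG genes are planted only on genes
#'   with baseline FPKM at or above this floor; below ~2 FPKM a twofold
#'   change cannot pass the pseudocounted fold-change gate even in
#'   expectation, so planted truth there would be unmeasurable.
#' @param compensation_mix proportions of (non_compensated, compensated,
#'   anti_compensated) among genes on one-dose chromosomes; must sum to 1.
#' @param compensated_factor_range,anti_factor_range optional 2-vectors
#'   overriding the default uniform draws of [apply_compensation_factor()].
#' @param seed integer master seed; per-stage substreams are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chrom_A = 10,
                       n_chrom_C = 9,
                       genes_per_chrom = 200,
                       replicates_per_group = 3,
                       base_expression_law = c(meanlog2 = 2.5, sdlog2 = 2.2),
                       nb_dispersion = 0.05,
                       library_size = 1e7,
                       karyotypes = NULL,
                       reference_group = "RBR",
                       dosage_multipliers = NULL,
                       trans_effect_fraction = 0.05,
                       trans_effect_log2fc_sd = 1.5,
                       trans_effect_min_log2fc = 1,
                       trans_effect_min_fpkm = 2,
                       compensation_mix = c(non_compensated = 0.64,
                                            compensated = 0.08,
                                            anti_compensated = 0.28),
                       compensated_factor_range = NULL,
                       anti_factor_range = NULL,
                       seed = 1) {
  chromosomes <- default_chromosomes(n_chrom_A, n_chrom_C)
  if (is.null(karyotypes)) karyotypes <- default_karyotypes(chromosomes)
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (library_size <= 0) stop("library_size must be positive")
  if (replicates_per_group < 2) stop("replicates_per_group must be >= 2")
  if (abs(sum(compensation_mix) - 1) > 1e-8)
    stop("compensation_mix must sum to 1")
  if (!all(c("non_compensated", "compensated", "anti_compensated") %in%
           names(compensation_mix)))
    stop("compensation_mix must name non_compensated, compensated, ",
         "anti_compensated")
  if (!reference_group %in% names(karyotypes))
    stop("reference_group must be one of the karyotype groups")
  for (g in names(karyotypes)) {
    kt <- karyotypes[[g]]
    if (!setequal(names(kt), chromosomes))
      stop("karyotype for group ", g,
           " must cover the chromosome universe")
    if (!all(kt %in% 0:3))
      stop("copy numbers must be in 0..3")
  }
  if (!is.null(dosage_multipliers)) {
    for (g in names(dosage_multipliers)) {
      if (any(dosage_multipliers[[g]] <= 0))
        stop("dosage multipliers must be positive")
    }
  }
  if (trans_effect_fraction < 0 || trans_effect_fraction > 1)
    stop("trans_effect_fraction must lie in [0, 1]")
  if (trans_effect_log2fc_sd <= 0)
    stop("trans_effect_log2fc_sd must be positive")
  structure(
    list(n_chrom_A = n_chrom_A, n_chrom_C = n_chrom_C,
         chromosomes = chromosomes,
         genes_per_chrom = genes_per_chrom,
         replicates_per_group = replicates_per_group,
         base_expression_law = base_expression_law,
         nb_dispersion = nb_dispersion,
         library_size = library_size,
         karyotypes = karyotypes,
         reference_group = reference_group,
         dosage_multipliers = dosage_multipliers,
         trans_effect_fraction = trans_effect_fraction,
         trans_effect_log2fc_sd = trans_effect_log2fc_sd,
         trans_effect_min_log2fc = trans_effect_min_log2fc,
         trans_effect_min_fpkm = trans_effect_min_fpkm,
         compensation_mix = compensation_mix,
         compensated_factor_range = compensated_factor_range,
         anti_factor_range = anti_factor_range,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Compensation factor for a one-dose gene
#'
#' Given the pure dosage factor of a monosomic chromosome (0.5), returns the
#' realised expression factor for a gene of the given compensation class:
#' `non_compensated` keeps the dosage factor exactly, `compensated` draws
#' uniformly in (base_factor, 1\], `anti_compensated` uniformly in
#' \[0.1 * base_factor, base_factor). Vectorised over `class`.
#'
#' @param class character vector of compensation classes.
#' @param base_factor pure dosage factor (0.5 for monosomy).
#' @param compensated_range,anti_range optional 2-vectors overriding the
#'   default draw ranges.
#' @return Numeric vector of positive factors.
#' @export
apply_compensation_factor <- function(class, base_factor = 0.5,
                                      compensated_range = NULL,
                                      anti_range = NULL) {
  known <- c("non_compensated", "compensated", "anti_compensated")
  if (!all(class %in% known))
    stop("unknown compensation class: ",
         paste(setdiff(class, known), collapse = ", "))
  if (base_factor <= 0 || base_factor >= 1)
    stop("base_factor must lie in (0, 1)")
  if (is.null(compensated_range)) compensated_range <- c(base_factor, 1)
  if (is.null(anti_range)) anti_range <- c(0.1 * base_factor, base_factor)
  n <- length(class)
  out <- rep(base_factor, n)
  is_c <- class == "compensated"
  is_a <- class == "anti_compensated"
  out[is_c] <- stats::runif(sum(is_c), compensated_range[1],
                            compensated_range[2])
  out[is_a] <- stats::runif(sum(is_a), anti_range[1], anti_range[2])
  out
}

#' @keywords internal
rtrunc_lfc <- function(n, sd, min_abs) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), 0, sd)
    ok <- abs(draw) >= min_abs
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate a dosage-perturbed RNA-seq experiment
#'
#' Generates a gene annotation, an NB count matrix, a sample sheet and a
#' ground-truth table for the configured groups. Per-sample expected totals
#' equal `library_size`: the expected count of gene g is
#' `library_size * w_g / sum(w)` with weight
#' `w_g = baseline_fpkm * exonic_kb * dosage * trans * compensation`.
#' Identical seeds give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A list of class `aneu_sim` with elements `genes`, `counts`,
#'   `samples`, `truth` (list: `karyotypes`, `gene_truth` long data frame)
#'   and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- config$chromosomes
  gpc <- config$genes_per_chrom
  ng <- length(chroms) * gpc
  groups <- names(config$karyotypes)
  ref <- config$reference_group

  # stage 1: gene models
  set.seed(stage_seed(config$seed, 1L))
  chrom_of <- rep(chroms, each = gpc)
  gene_id <- sprintf("g%s_%04d", chrom_of, rep(seq_len(gpc), length(chroms)))
  exonic_length <- as.integer(round(exp(stats::runif(ng, log(300),
                                                     log(10000)))))
  span <- as.integer(round(exonic_length * stats::runif(ng, 1, 2.5)))
  gap <- as.integer(round(stats::runif(ng, 200, 2000)))
  start <- integer(ng)
  for (ch in chroms) {
    i <- which(chrom_of == ch)
    start[i] <- cumsum(c(1L, (span[i] + gap[i])[-length(i)]))
  }
  genes <- data.frame(
    gene_id = gene_id, chromosome = chrom_of,
    start = start, end = start + span - 1L,
    exonic_length = exonic_length,
    subgenome = substr(chrom_of, 1, 1),
    stringsAsFactors = FALSE
  )

  # stage 2: baseline expression
  set.seed(stage_seed(config$seed, 2L))
  law <- config$base_expression_law
  baseline_fpkm <- 2^stats::rnorm(ng, law[["meanlog2"]], law[["sdlog2"]])

  # per-group dosage factor (copies / 2, with optional overrides)
  dosage_factor <- sapply(groups, function(g) {
    kt <- config$karyotypes[[g]][chrom_of]
    f <- kt / 2
    ov <- config$dosage_multipliers[[g]]
    if (!is.null(ov)) {
      hit <- chrom_of %in% names(ov)
      f[hit] <- ov[chrom_of[hit]]
    }
    f
  })
  rownames(dosage_factor) <- gene_id

  # stage 3: trans-effect DEGs on shared disomic chromosomes
  set.seed(stage_seed(config$seed, 3L))
  trans_lfc <- matrix(0, ng, length(groups),
                      dimnames = list(gene_id, groups))
  ref_kt <- config$karyotypes[[ref]]
  for (g in setdiff(groups, ref)) {
    kt <- config$karyotypes[[g]]
    disomic <- names(kt)[kt == 2L & ref_kt == 2L]
    eligible <- which(chrom_of %in% disomic &
                        baseline_fpkm >= config$trans_effect_min_fpkm)
    n_de <- round(config$trans_effect_fraction * length(eligible))
    if (n_de > 0) {
      picked <- sample(eligible, n_de)
      trans_lfc[picked, g] <- rtrunc_lfc(n_de, config$trans_effect_log2fc_sd,
                                         config$trans_effect_min_log2fc)
    }
  }

  # stage 4: compensation classes on one-dose chromosomes
  set.seed(stage_seed(config$seed, 4L))
  comp_class <- matrix(NA_character_, ng, length(groups),
                       dimnames = list(gene_id, groups))
  comp_factor <- matrix(1, ng, length(groups),
                        dimnames = list(gene_id, groups))
  mix <- config$compensation_mix
  for (g in groups) {
    kt <- config$karyotypes[[g]]
    monosomic <- names(kt)[kt == 1L]
    idx <- which(chrom_of %in% monosomic)
    if (length(idx) == 0) next
    cls <- sample(names(mix), length(idx), replace = TRUE, prob = mix)
    base_f <- dosage_factor[idx, g]
    fac <- vapply(seq_along(idx), function(i) {
      apply_compensation_factor(cls[i], base_f[i],
                                config$compensated_factor_range,
                                config$anti_factor_range)
    }, numeric(1))
    comp_class[idx, g] <- cls
    # the compensation factor replaces the pure dosage factor
    comp_factor[idx, g] <- fac / base_f
  }

  # stage 5: counts
  set.seed(stage_seed(config$seed, 5L))
  len_kb <- genes$exonic_length / 1000
  n_rep <- config$replicates_per_group
  samples <- data.frame(
    sample = unlist(lapply(groups, function(g) paste(g, seq_len(n_rep),
                                                     sep = "_"))),
    group = rep(groups, each = n_rep),
    replicate = rep(seq_len(n_rep), length(groups)),
    stringsAsFactors = FALSE
  )
  mu_group <- sapply(groups, function(g) {
    w <- baseline_fpkm * len_kb * dosage_factor[, g] *
      2^trans_lfc[, g] * comp_factor[, g]
    config$library_size * w / sum(w)
  })
  counts <- matrix(0L, ng, nrow(samples),
                   dimnames = list(gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- mu_group[, samples$group[j]]
    counts[, j] <- as.integer(stats::rnbinom(ng, mu = mu,
                                             size = 1 / config$nb_dispersion))
  }

  gene_truth <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      gene_id = gene_id, group = g,
      chromosome = chrom_of,
      baseline_fpkm = baseline_fpkm,
      dosage_factor = dosage_factor[, g],
      true_mean_count = mu_group[, g],
      is_trans_deg = trans_lfc[, g] != 0,
      true_log2fc = trans_lfc[, g],
      compensation_class = comp_class[, g],
      stringsAsFactors = FALSE
    )
  }))
  rownames(gene_truth) <- NULL

  structure(
    list(genes = genes, counts = counts, samples = samples,
         truth = list(karyotypes = config$karyotypes,
                      gene_truth = gene_truth),
         config = config),
    class = "aneu_sim"
  )
}

#' @export
print.aneu_sim <- function(x, ...) {
  cat("Simulated aneuploid experiment:",
      nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      length(x$truth$karyotypes), "groups\n")
  invisible(x)
}
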