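euploid_pair_config <- function(...) {
  # two euploid A-genome groups: a global null unless overridden
  chroms <- default_chromosomes()
  kt <- setNames(ifelse(startsWith(chroms, "A"), 2L, 0L), chroms)
  sim_config(karyotypes = list(g1 = kt, g2 = kt), reference_group = "g1",
             trans_effect_fraction = 0, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(library_size = -1), "library_size")
  expect_error(sim_config(replicates_per_group = 1), "replicates")
  expect_error(sim_config(compensation_mix = c(non_compensated = 0.5,
                                               compensated = 0.2,
                                               anti_compensated = 0.2)),
               "sum to 1")
  expect_error(sim_config(dosage_multipliers = list(Cs1 = c(A01 = 0))),
               "positive")
  expect_error(sim_config(trans_effect_fraction = 1.5), "\\[0, 1\\]")
})

test_that("compensation factors honour their class-specific ranges", {
  expect_equal(apply_compensation_factor("non_compensated", 0.5), 0.5)
  set.seed(8)
  fc <- apply_compensation_factor(rep("compensated", 200), 0.5)
  expect_true(all(fc > 0.5 & fc <= 1))
  fa <- apply_compensation_factor(rep("anti_compensated", 200), 0.5)
  expect_true(all(fa >= 0.05 & fa < 0.5))
  # custom ranges
  fr <- apply_compensation_factor(rep("anti_compensated", 50), 0.5,
                                  anti_range = c(0.05, 0.25))
  expect_true(all(fr >= 0.05 & fr <= 0.25))
  expect_error(apply_compensation_factor("sideways", 0.5), "unknown")
})

test_that("a fixed seed reproduces the simulation bit for bit", {
  a <- simulate_experiment(sim_config(genes_per_chrom = 40, seed = 42))
  b <- simulate_experiment(sim_config(genes_per_chrom = 40, seed = 42))
  expect_identical(a$counts, b$counts)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth$gene_truth, b$truth$gene_truth)
  c <- simulate_experiment(sim_config(genes_per_chrom = 40, seed = 43))
  expect_false(identical(a$counts, c$counts))
})

test_that("under the null configuration group means agree within sampling
           error for almost all genes", {
  sim <- simulate_experiment(euploid_pair_config(genes_per_chrom = 200,
                                                 seed = 9))
  tr <- sim$truth$gene_truth
  mu <- tr$true_mean_count[tr$group == "g1"]
  expressed <- mu > 0
  m1 <- rowMeans(sim$counts[, sim$samples$sample[sim$samples$group == "g1"]])
  m2 <- rowMeans(sim$counts[, sim$samples$sample[sim$samples$group == "g2"]])
  # model-based standard error of the difference of two 3-replicate means
  se <- sqrt(2 * (mu + sim$config$nb_dispersion * mu^2) / 3)
  ok <- abs(m2 - m1)[expressed] < 3 * se[expressed]
  expect_gte(mean(ok), 0.99)
})

test_that("a 0.5 dosage multiplier halves mean counts on the targeted
           chromosome", {
  cfg <- euploid_pair_config(genes_per_chrom = 200, seed = 10,
                             dosage_multipliers = list(g2 = c(A01 = 0.5)))
  sim <- simulate_experiment(cfg)
  a01 <- sim$genes$gene_id[sim$genes$chromosome == "A01"]
  m1 <- rowSums(sim$counts[a01, sim$samples$sample[sim$samples$group == "g1"]])
  m2 <- rowSums(sim$counts[a01, sim$samples$sample[sim$samples$group == "g2"]])
  expect_gt(sum(m2) / sum(m1), 0.45)
  expect_lt(sum(m2) / sum(m1), 0.57)
  # monotonicity of the scan statistic under a known scaling
  expr <- compute_fpkm(sim$counts, sim$genes)
  sc <- scan_dosage(expr, sim$genes, sim$samples, "g2", "g1")
  expr2 <- expr
  tst <- sim$samples$sample[sim$samples$group == "g2"]
  expr2[a01, tst] <- expr2[a01, tst] * 1.5
  sc2 <- scan_dosage(expr2, sim$genes, sim$samples, "g2", "g1")
  expect_equal(sc2$median_log2_ratio[sc2$chromosome == "A01"],
               sc$median_log2_ratio[sc$chromosome == "A01"] + log2(1.5))
})

test_that("per-sample totals land within five model standard errors of the
           configured library size", {
  cfg <- sim_config(genes_per_chrom = 100, seed = 12)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth$gene_truth
  for (g in unique(sim$samples$group)) {
    mu <- tr$true_mean_count[tr$group == g]
    se_total <- sqrt(sum(mu + cfg$nb_dispersion * mu^2))
    tot <- colSums(sim$counts[, sim$samples$sample[sim$samples$group == g],
                              drop = FALSE])
    expect_true(all(abs(tot - cfg$library_size) < 5 * se_total))
  }
})

test_that("monosomic non-compensated genes show a median twofold count
           reduction", {
  for (seed in 1:3) {
    sim <- simulate_experiment(sim_config(genes_per_chrom = 250,
                                          seed = seed))
    tr <- sim$truth$gene_truth
    nc <- tr$gene_id[tr$group == "Cs1" & tr$chromosome == "A01" &
                       !is.na(tr$compensation_class) &
                       tr$compensation_class == "non_compensated"]
    mcs <- rowMeans(sim$counts[nc, sim$samples$sample[
      sim$samples$group == "Cs1"]])
    mrb <- rowMeans(sim$counts[nc, sim$samples$sample[
      sim$samples$group == "RBR"]])
    keep <- mcs > 0 & mrb > 0
    expect_gt(sum(keep), 100)
    med <- median(log2(mcs[keep] / mrb[keep]))
    expect_lt(abs(med - (-1)), 0.15)
  }
})

test_that("ground truth is internally consistent with the karyotypes", {
  sim <- simulate_experiment(sim_config(genes_per_chrom = 60, seed = 13))
  tr <- sim$truth$gene_truth
  kts <- sim$truth$karyotypes
  ref_kt <- kts[[sim$config$reference_group]]
  for (g in names(kts)) {
    tg <- tr[tr$group == g, ]
    copies <- kts[[g]][tg$chromosome]
    # compensation class iff the gene sits on a one-copy chromosome
    expect_identical(!is.na(tg$compensation_class), unname(copies == 1L))
    # trans-DEG flags only on chromosomes disomic in both group and
    # reference
    flagged <- tg$chromosome[tg$is_trans_deg]
    expect_true(all(kts[[g]][flagged] == 2L & ref_kt[flagged] == 2L))
    # planted effects respect the truncation bound
    expect_true(all(abs(tg$true_log2fc[tg$is_trans_deg]) >=
                      sim$config$trans_effect_min_log2fc))
  }
})
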