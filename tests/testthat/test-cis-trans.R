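euploid_kt <- function() {
  chroms <- default_chromosomes()
  setNames(ifelse(startsWith(chroms, "A"), 2L, 0L), chroms)
}

test_that("altered chromosomes are exactly those whose copy number
           changes", {
  eu <- euploid_kt()
  addition <- eu
  addition["C01"] <- 1L
  substitution <- eu
  substitution["A01"] <- 1L
  substitution["C01"] <- 1L
  expect_equal(altered_chromosomes(addition, eu), "C01")
  expect_equal(altered_chromosomes(substitution, eu), c("A01", "C01"))
  expect_equal(altered_chromosomes(eu, eu), character(0))
  bad <- eu[-1]
  expect_error(altered_chromosomes(bad, eu), "universe")
})

test_that("the cis/trans partition reproduces published proportions and
           trans bias from constructed DEG sets", {
  # 2706 trans + 625 cis, as in an addition-line comparison
  degs <- fake_degs(950 + 300, 1756 + 325)
  n <- nrow(degs)
  genes <- tiny_genes(n, chromosomes = character(n))
  genes$gene_id <- degs$gene_id
  # trans genes on disomic A chromosomes, cis genes on C01
  trans_idx <- c(1:950, (950 + 300) + 1:1756)
  genes$chromosome <- "C01"
  genes$chromosome[trans_idx] <- "A02"
  part <- partition_degs(degs, genes, altered = "C01")
  expect_equal(part$n_trans, 2706)
  expect_equal(part$n_cis, 625)
  expect_equal(part$pct_trans, 81.24)
  expect_equal(part$trans_bias$p, 2 * pnorm(-sqrt(part$trans_bias$statistic)))
  # substitution-style trans direction bias: (2586 up, 2852 down)
  degs2 <- fake_degs(2586, 2852)
  genes2 <- tiny_genes(nrow(degs2), chromosomes = rep("A03", nrow(degs2)))
  genes2$gene_id <- degs2$gene_id
  part2 <- partition_degs(degs2, genes2, altered = "A01")
  expect_equal(signif(part2$trans_bias$p, 3), 3.10e-4)
  # all DEGs on altered chromosomes: degenerate partition
  part3 <- partition_degs(degs2, genes2, altered = "A03")
  expect_equal(part3$n_trans, 0)
  expect_equal(part3$pct_trans, 0)
})

test_that("the partition is order-invariant, counts dosage-opposing genes
           and excludes unlocated genes with a warning", {
  degs <- fake_degs(4, 6)
  genes <- tiny_genes(10, chromosomes = c(rep("A01", 5), rep("A02", 5)))
  genes$gene_id <- degs$gene_id
  p1 <- partition_degs(degs, genes, altered = "A01", reduced = "A01")
  # up-regulated DEGs on the reduced chromosome oppose the dosage loss
  expect_equal(p1$cis_up_count, sum(degs$direction[1:5] == "up"))
  shuffle <- sample(nrow(degs))
  p2 <- partition_degs(degs[shuffle, ], genes[sample(10), ],
                       altered = "A01", reduced = "A01")
  expect_equal(p2$n_cis, p1$n_cis)
  expect_equal(p2$n_trans, p1$n_trans)
  expect_equal(sort(p2$trans$gene_id), sort(p1$trans$gene_id))
  # a DEG absent from the annotation is dropped, with a warning
  orphan <- degs
  orphan$gene_id[1] <- "missing_gene"
  expect_warning(p3 <- partition_degs(orphan, genes, altered = "A01"),
                 "excluded")
  expect_equal(p3$n_cis + p3$n_trans, 9)
})

test_that("on simulated substitution data every true trans-DEG lands in the
           trans partition", {
  sim <- simulate_experiment(sim_config(genes_per_chrom = 100, seed = 26))
  expr <- compute_fpkm(sim$counts, sim$genes)
  degs <- call_degs(expr, sim$samples, "Cs1", "RBR")
  alt <- altered_chromosomes(sim$truth$karyotypes$Cs1,
                             sim$truth$karyotypes$RBR)
  part <- partition_degs(degs, sim$genes, alt)
  tr <- sim$truth$gene_truth
  true_trans <- tr$gene_id[tr$group == "Cs1" & tr$is_trans_deg]
  called <- degs$gene_id[degs$is_deg]
  expect_true(all(intersect(true_trans, called) %in% part$trans$gene_id))
})

test_that("chromosome susceptibility flags an enriched chromosome and stays
           flat under proportional DEG placement", {
  genes <- tiny_genes(300, chromosomes = rep(c("A01", "A02", "A03"),
                                             each = 100))
  expressed <- genes$gene_id
  # proportional: 10 DEGs per 100 expressed genes on each chromosome
  prop <- data.frame(gene_id = genes$gene_id[c(1:10, 101:110, 201:210)],
                     is_deg = TRUE, stringsAsFactors = FALSE)
  tab <- chromosome_susceptibility(prop, expressed, genes)
  expect_true(all(tab$q >= 0.05))
  expect_equal(tab$n_deg, rep(10L, 3))
  # one chromosome at three times the genome-wide DEG rate
  enr <- data.frame(gene_id = genes$gene_id[c(1:30, 101:110, 201:210)],
                    is_deg = TRUE, stringsAsFactors = FALSE)
  tab2 <- chromosome_susceptibility(enr, expressed, genes)
  expect_equal(tab2$chromosome[which.min(tab2$q)], "A01")
  # oracle: hand 2x2 chi-square for the enriched chromosome
  a <- 30; b <- 70; c <- 20; d <- 180
  n <- a + b + c + d
  chi_hand <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(tab2$chi2[tab2$chromosome == "A01"], chi_hand,
               tolerance = 1e-10)
  # empty DEG list: zero counts, p = 1 everywhere
  none <- data.frame(gene_id = character(), is_deg = logical(),
                     stringsAsFactors = FALSE)
  tab3 <- chromosome_susceptibility(none, expressed, genes)
  expect_equal(tab3$n_deg, rep(0L, 3))
  expect_equal(tab3$p, rep(1, 3))
  # altered chromosomes are excluded from the table
  tab4 <- chromosome_susceptibility(enr, expressed, genes, altered = "A01")
  expect_false("A01" %in% tab4$chromosome)
})

test_that("Venn overlaps match brute-force set algebra and always sum to
           the union size", {
  a <- fake_degs(3, 2)
  b <- a
  b$gene_id <- paste0("other", seq_len(nrow(b)))
  ov <- overlap_degs(list(A = a, B = b))
  expect_equal(ov$n[ov$region == "A&B"], 0L)
  ov2 <- overlap_degs(list(A = a, B = a))
  expect_equal(ov2$n[ov2$region == "A&B"], nrow(a))
  expect_equal(ov2$n[ov2$region %in% c("A", "B")], c(0L, 0L))
  # random three-way case against independent set operations
  set.seed(27)
  pool <- sprintf("r%03d", 1:60)
  ids <- lapply(1:3, function(i) sample(pool, 30))
  names(ids) <- c("X", "Y", "Z")
  ov3 <- overlap_degs(ids)
  only_x <- setdiff(ids$X, union(ids$Y, ids$Z))
  xy <- setdiff(intersect(ids$X, ids$Y), ids$Z)
  xyz <- Reduce(intersect, ids)
  expect_equal(ov3$n[ov3$region == "X"], length(only_x))
  expect_equal(ov3$n[ov3$region == "X&Y"], length(xy))
  expect_equal(ov3$n[ov3$region == "X&Y&Z"], length(xyz))
  expect_equal(sum(ov3$n), length(unique(unlist(ids))))
  dup <- c(ids$X, ids$X[1])
  expect_error(overlap_degs(list(A = dup, B = ids$Y)), "duplicate")
})

test_that("direction-aware overlaps split shared genes by directional
           agreement", {
  mk <- function(ids, dirs) data.frame(gene_id = ids, direction = dirs,
                                       is_deg = TRUE,
                                       stringsAsFactors = FALSE)
  a <- mk(c("g1", "g2", "g3", "g4"), c("down", "down", "up", "up"))
  b <- mk(c("g1", "g2", "g3", "g5"), c("down", "down", "down", "up"))
  ov <- overlap_degs(list(A = a, B = b), direction_aware = TRUE)
  shared_down <- ov$n[ov$region == "A&B" & ov$direction == "down"]
  shared_up <- ov$n[ov$region == "A&B" & ov$direction == "up"]
  mixed <- ov$n[ov$region == "A&B" & ov$direction == "mixed"]
  expect_equal(shared_down, 2L)   # g1, g2 down in both
  expect_equal(shared_up, 0L)
  expect_equal(mixed, 1L)         # g3 disagrees
  expect_equal(sum(ov$n), 5L)     # regions still partition the union
})
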