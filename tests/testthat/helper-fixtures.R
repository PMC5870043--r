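# small deterministic fixtures shared across test files

tiny_genes <- function(n = 6, chromosomes = rep("A01", n)) {
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    chromosome = chromosomes,
    start = seq(1, by = 5000, length.out = n),
    end = seq(1, by = 5000, length.out = n) + 2999,
    exonic_length = rep(1000L, n),
    subgenome = substr(chromosomes, 1, 1),
    stringsAsFactors = FALSE
  )
}

tiny_samples <- function(groups = c("ref", "tst"), n_rep = 3) {
  data.frame(
    sample = unlist(lapply(groups, function(g) paste(g, seq_len(n_rep),
                                                     sep = "_"))),
    group = rep(groups, each = n_rep),
    replicate = rep(seq_len(n_rep), length(groups)),
    stringsAsFactors = FALSE
  )
}

# expression matrix with given per-gene group means and multiplicative
# replicate jitter (deterministic via seed)
expr_matrix <- function(means_by_group, samples, jitter = 0.05, seed = 1) {
  set.seed(seed)
  genes <- rownames(means_by_group)
  m <- matrix(0, nrow(means_by_group), nrow(samples),
              dimnames = list(genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- means_by_group[, samples$group[j]]
    m[, j] <- mu * exp(rnorm(length(mu), 0, jitter))
  }
  m
}

# a DEG data frame with given numbers of up/down calls, optionally placed
# on given chromosomes
fake_degs <- function(n_up, n_down, chrom_up = NULL, chrom_down = NULL) {
  n <- n_up + n_down
  data.frame(
    gene_id = sprintf("fg%05d", seq_len(n)),
    log2fc = c(rep(2, n_up), rep(-2, n_down)),
    p = rep(1e-6, n), q = rep(1e-5, n),
    direction = c(rep("up", n_up), rep("down", n_down)),
    is_deg = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

# brute-force two-sided exact signed-rank p by enumeration of all 2^n
# sign assignments (independent of the package implementation)
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# direct step-up BH evaluation (independent re-implementation)
direct_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * n / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(n)
  out[o] <- q_sorted
  out
}
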