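# Shared fixtures and independent oracles.

# Adjusted Rand index between two partitions (closed form on the
# contingency table); independent of any clustering code in the package.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- si * sj / comb2(n)
  maximum <- (si + sj) / 2
  if (maximum == expected) return(1)
  (sij - expected) / (maximum - expected)
}

# Brute-force Benjamini-Hochberg step-up oracle: walk ranks from largest to
# smallest, carrying the running minimum of p * m / rank.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# Small hand-buildable assays ------------------------------------------------

toy_dna <- function(barcodes = c("c1", "c2", "c3"), n_var = 2,
                    af = 50, ngt = 1, gq = 99, dp = 50) {
  n <- length(barcodes)
  mk <- function(x) matrix(x, n, n_var)
  dna_variant_assay(mk(af), mk(ngt), mk(gq), mk(dp), barcodes,
                    sprintf("chr1:%d:A/G", seq_len(n_var) * 100))
}

toy_counts <- function(barcodes = c("c1", "c2", "c3"), n_feat = 2,
                       value = 5, prefix = "F") {
  assay_matrix(matrix(value, length(barcodes), n_feat), barcodes,
               paste0(prefix, seq_len(n_feat)), units = "count")
}

toy_sample <- function(barcodes = c("c1", "c2", "c3"), n_var = 2,
                       n_cnv = 2, n_prot = 2) {
  build_sample(toy_dna(barcodes, n_var),
               toy_counts(barcodes, n_cnv, prefix = "AMP"),
               toy_counts(barcodes, n_prot, prefix = "P"),
               name = "toy")
}

# A random but always-valid synthetic configuration, for property tests.
random_config <- function(seed, max_clones = 3) {
  set.seed(seed * 7919)
  g <- sample(max_clones, 1)
  n_var <- sample(3:8, 1)
  n_amp <- sample(2:6, 1)
  n_prot <- sample(2:5, 1)
  clones <- lapply(seq_len(g), function(i)
    clone_spec(n_cells = sample(3:10, 1),
               genotype = sample(0:2, n_var, replace = TRUE),
               copy_number = sample(1:4, n_amp, replace = TRUE),
               protein_means = stats::runif(n_prot, 10, 200)))
  synthetic_config(clones = clones, seed = seed)
}

# The well-separated 3-clone world used for exact clone recovery: three
# clones of 100 cells whose genotype profiles differ at >= 10 variants
# (>= 0.4 apart per differing coordinate in scaled-VAF space), VAF noise
# sd 2 percent, no dropout.
separated_config <- function(seed = 42, n_cells = 100) {
  n_var <- 30
  g1 <- rep(0L, n_var); g1[1:10] <- 1L
  g2 <- rep(0L, n_var); g2[11:20] <- 2L
  g3 <- rep(0L, n_var); g3[21:30] <- 1L
  cn <- rep(2L, 10)
  pm <- rep(50, 4)
  synthetic_config(
    clones = list(clone_spec(n_cells, g1, cn, pm),
                  clone_spec(n_cells, g2, cn, pm),
                  clone_spec(n_cells, g3, cn, pm)),
    vaf_noise_sd = 2, dropout_rate = 0, seed = seed)
}
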