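test_that("clr_normalize matches closed-form cases", {
  a <- assay_matrix(rbind(c(0, 0, 0), c(4, 4, 4), c(9, 99, 0)),
                    c("c1", "c2", "c3"), c("P1", "P2", "P3"))
  y <- clr_normalize(a)$values
  expect_equal(unname(y[1, ]), c(0, 0, 0))        # ln(1) = 0 throughout
  expect_equal(unname(y[2, ]), c(0, 0, 0))        # centering kills constants

  # two-protein cell (9, 99): y = +-(ln 100 - ln 10) / 2
  b <- assay_matrix(matrix(c(9, 99), 1, 2), "c1", c("P1", "P2"))
  yb <- clr_normalize(b)$values
  expect_equal(unname(yb[1, ]),
               c(log(10) - (log(10) + log(100)) / 2,
                 log(100) - (log(10) + log(100)) / 2),
               tolerance = 1e-9)
  expect_equal(unname(yb[1, 2]), 1.1512925, tolerance = 1e-6)

  expect_error(clr_normalize(assay_matrix(matrix(3, 2, 1), c("c1", "c2"),
                                          "P1")),
               "at least 2 proteins")
})

test_that("every CLR row sums to zero on random count matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:40, 1)
    p <- sample(2:12, 1)
    a <- assay_matrix(matrix(rnbinom(n * p, mu = 60, size = 3), n, p),
                      sprintf("c%03d", 1:n), paste0("P", 1:p))
    y <- clr_normalize(a)$values
    expect_lt(max(abs(rowSums(y))), 1e-9)
  }
})

test_that("pca embedding preserves rank-2 geometry and matches an eigen oracle", {
  # rank-2 data: pairwise distances survive projection exactly
  set.seed(14)
  scores <- matrix(rnorm(60), 30, 2)
  load <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  X <- scores %*% t(load)
  a <- assay_matrix(X, sprintf("c%02d", 1:30), paste0("P", 1:5),
                    units = "normalized")
  emb <- reduce_dim(a, method = "pca")
  Xc <- scale(X, scale = FALSE)
  expect_equal(unname(as.matrix(dist(emb$coords))),
               unname(as.matrix(dist(Xc))), tolerance = 1e-8)

  # independent eigendecomposition oracle on a 20 x 5 random matrix
  set.seed(15)
  Y <- matrix(rnorm(100), 20, 5)
  b <- assay_matrix(Y, sprintf("c%02d", 1:20), paste0("P", 1:5),
                    units = "normalized")
  emb2 <- reduce_dim(b, method = "pca")$coords
  ev <- eigen(stats::cov(Y))
  W <- ev$vectors[, 1:2]
  for (k in 1:2) if (W[which.max(abs(W[, k])), k] < 0) W[, k] <- -W[, k]
  oracle <- scale(Y, scale = FALSE) %*% W
  expect_equal(unname(emb2), unname(oracle), tolerance = 1e-8)
})

test_that("stochastic embeddings are deterministic under a fixed seed", {
  set.seed(2)
  a <- assay_matrix(matrix(rnorm(400), 80, 5), sprintf("c%02d", 1:80),
                    paste0("P", 1:5), units = "normalized")
  u1 <- reduce_dim(a, method = "umap", seed = 7)
  u2 <- reduce_dim(a, method = "umap", seed = 7)
  expect_identical(u1$coords, u2$coords)
  expect_equal(u1$seed, 7L)
  expect_equal(ncol(u1$coords), 2)

  t1 <- reduce_dim(a, method = "tsne", seed = 7)
  t2 <- reduce_dim(a, method = "tsne", seed = 7)
  expect_identical(t1$coords, t2$coords)

  expect_error(reduce_dim(a, method = "pcoa"))
  small <- assay_matrix(matrix(1, 2, 2), c("c1", "c2"), c("P1", "P2"),
                        units = "normalized")
  expect_error(reduce_dim(small, method = "pca"), "at least 3 cells")
})

test_that("welch_tests agrees with stats::t.test", {
  set.seed(33)
  x <- matrix(rnorm(40 * 3, mean = 1), 40, 3)
  y <- matrix(rnorm(25 * 3, sd = 2), 25, 3)
  got <- tapomics:::welch_tests(x, y)
  for (j in 1:3) {
    ref <- stats::t.test(x[, j], y[, j])
    expect_equal(got$t_statistic[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df[j], unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p_value[j], ref$p.value, tolerance = 1e-10)
  }
  # degenerate zero-variance columns
  z1 <- matrix(c(1, 1, 1), 3, 1)
  z2 <- matrix(c(1, 1), 2, 1)
  same <- tapomics:::welch_tests(z1, z2)
  expect_equal(same$p_value, 1)
  diff <- tapomics:::welch_tests(z1, z2 + 1)
  expect_equal(diff$p_value, 0)
})

test_that("BH adjustment matches the hand example and the step-up oracle", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  for (seed in 1:50) {
    set.seed(seed)
    p <- runif(sample(3:20, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), bh_stepup(p),
                 tolerance = 1e-12)
  }
})

test_that("find_signature ranks a spiked protein first with small p_adjusted", {
  set.seed(44)
  n1 <- 50; n2 <- 150
  p <- 8
  vals <- matrix(rnorm((n1 + n2) * p, sd = 0.5), n1 + n2, p)
  vals[seq_len(n1), 5] <- vals[seq_len(n1), 5] + 3  # +3 CLR units in target
  a <- assay_matrix(vals, sprintf("c%03d", seq_len(n1 + n2)),
                    paste0("P", 1:p), units = "normalized")
  labels <- c(rep(2L, n1), rep(1L, n2))
  sig <- find_signature(a, labels, target_clone = 2)
  expect_equal(sig$protein_id[1], "P5")
  expect_lt(sig$p_adjusted[1], 0.01)
  expect_gt(sig$difference[1], 2.5)
  # table invariants
  expect_equal(nrow(sig), p)
  expect_true(all(diff(sig$p_adjusted) >= 0))
  expect_true(all(sig$p_adjusted >= sig$p_value))
  expect_true(all(sig$p_value >= 0 & sig$p_adjusted <= 1))
  expect_equal(sig$difference, sig$mean_target - sig$mean_rest)
})

test_that("find_signature excludes noise cells and is permutation-symmetric", {
  set.seed(55)
  n <- 60
  vals <- matrix(rnorm(n * 4), n, 4)
  labels <- rep(c(1L, 2L, 0L), each = 20)
  a <- assay_matrix(vals, sprintf("c%03d", 1:n), paste0("P", 1:4),
                    units = "normalized")
  sig <- find_signature(a, labels, target_clone = 1)
  # identical to dropping the noise cells outright
  keep <- labels > 0
  sig_ref <- find_signature(
    assay_matrix(vals[keep, ], sprintf("c%03d", 1:n)[keep],
                 paste0("P", 1:4), units = "normalized"),
    labels[keep], target_clone = 1)
  expect_equal(sig, sig_ref)

  # label-preserving row permutation leaves the table unchanged
  perm <- sample(n)
  sig_perm <- find_signature(
    assay_matrix(vals[perm, ], sprintf("c%03d", 1:n)[perm],
                 paste0("P", 1:4), units = "normalized"),
    labels[perm], target_clone = 1)
  expect_equal(sig, sig_perm)

  expect_error(find_signature(a, rep(1L, n), target_clone = 2), "has 0 cells")
  expect_error(find_signature(a, rep(1L, n), target_clone = 1),
               "outside the target clone")
})
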