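test_that("call_validity_mask matches a hand-enumerated truth table", {
  # single calls at default thresholds
  one <- function(dp, gq, ngt, af)
    call_validity_mask(toy_dna("c1", 1, af = af, ngt = ngt, gq = gq,
                               dp = dp))[1, 1]
  expect_true(one(50, 99, 1, 45))
  expect_false(one(9, 99, 0, 0))   # fails depth alone

  # exhaustive boundary grid: DP in {9,10}, GQ in {29,30}, NGT in {0,1,3},
  # AF in {19,20}; oracle applies each rule independently per call
  grid <- expand.grid(dp = c(9, 10), gq = c(29, 30), ngt = c(0, 1, 3),
                      af = c(19, 20))
  n <- nrow(grid)
  dna <- dna_variant_assay(
    AF = matrix(grid$af, n, 1), NGT = matrix(grid$ngt, n, 1),
    GQ = matrix(grid$gq, n, 1), DP = matrix(grid$dp, n, 1),
    cell_barcodes = sprintf("c%02d", seq_len(n)),
    variant_ids = "chr1:1:A/G")
  got <- call_validity_mask(dna)[, 1]
  oracle <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    if (grid$ngt[i] == 3) ok <- FALSE
    if (grid$dp[i] < 10) ok <- FALSE
    if (grid$gq[i] < 30) ok <- FALSE
    if (grid$ngt[i] %in% c(1, 2) && grid$af[i] < 20) ok <- FALSE
    oracle[i] <- ok
  }
  expect_identical(unname(got), oracle)
})

test_that("filter_variants applies the cells-then-variants contract", {
  # 6 cells x 4 variants; validity controlled through DP (0 = invalid),
  # mutation status through NGT. Thresholds (0.5, 0.5, 0.1).
  # v1 valid everywhere, mutated in 3 cells           -> kept
  # v2 valid in 2/5 remaining cells (0.4 < 0.5)       -> removed (validity)
  # v3 valid everywhere but never mutated             -> removed (mutation)
  # v4 valid everywhere, mutated in 1/5 (0.2 >= 0.1)  -> kept
  # cell 6 valid only at v1 (0.25 < 0.5)              -> removed
  DP <- rbind(c(50, 50, 50, 50),
              c(50,  0, 50, 50),
              c(50,  0, 50, 50),
              c(50,  0, 50, 50),
              c(50, 50, 50, 50),
              c(50,  0,  0,  0))
  NGT <- rbind(c(1, 1, 0, 1),
               c(1, 0, 0, 0),
               c(1, 0, 0, 0),
               c(0, 0, 0, 0),
               c(0, 1, 0, 0),
               c(0, 0, 0, 0))
  AF <- ifelse(NGT > 0, 50, 0)
  GQ <- matrix(99, 6, 4)
  bcs <- paste0("c", 1:6)
  vids <- sprintf("chr1:%d:A/G", 1:4 * 10)
  s <- build_sample(dna_variant_assay(AF, NGT, GQ, DP, bcs, vids),
                    toy_counts(bcs, 3, prefix = "AMP"),
                    toy_counts(bcs, 2, prefix = "P"))
  qc <- qc_thresholds(cell_min_valid_fraction = 0.5,
                      variant_min_valid_fraction = 0.5,
                      variant_min_mutated_fraction = 0.1)
  res <- filter_variants(s, qc)
  expect_equal(res$report$cells_after, 5)
  expect_equal(res$report$variants_after, 2)
  expect_identical(res$sample$dna$variant_ids, vids[c(1, 4)])
  expect_identical(res$sample$dna$cell_barcodes, bcs[1:5])
  expect_equal(res$report$removed$cells_low_valid_fraction, 1)
  expect_equal(res$report$removed$variants_low_valid_fraction, 1)
  expect_equal(res$report$removed$variants_low_mutated_fraction, 1)
  # CNV / protein feature axes untouched; shared cell axis shrunk
  expect_equal(length(res$sample$cnv$feature_ids), 3)
  expect_equal(length(res$sample$protein$feature_ids), 2)
  expect_equal(n_cells(res$sample), 5)
  expect_true(res$sample$status$dna_filtered)
  expect_error(filter_variants(res$sample, qc), "already filtered")
})

test_that("filter_variants keeps everything when every call passes", {
  s <- toy_sample(sprintf("c%02d", 1:10), n_var = 3)  # all het, DP 50, GQ 99
  res <- filter_variants(s)
  expect_equal(res$report$cells_after, 10)
  expect_equal(res$report$variants_after, 3)
  expect_equal(res$report$invalid_call_fraction, 0)
})

test_that("filter_variants errors when a threshold removes everything", {
  s <- toy_sample(sprintf("c%02d", 1:4), n_var = 2)
  expect_error(filter_variants(s, qc_thresholds(min_depth = 1000)),
               "all 4 cells removed")
  # all calls valid but nothing mutated
  s$dna$NGT[] <- 0
  expect_error(filter_variants(s), "all 2 variants removed")
})

test_that("tightening any single threshold never grows the output", {
  cfg <- synthetic_config(seed = 77, dropout_rate = 0.15, mean_depth = 30,
                          depth_dispersion = 3)
  s <- simulate_sample(cfg)$sample
  base_qc <- qc_thresholds()
  base <- filter_variants(s, base_qc)$report
  tighter <- list(
    list(min_depth = 14), list(min_depth = 20),
    list(min_gq = 99), list(min_af_mutated = 40),
    list(cell_min_valid_fraction = 0.7),
    list(cell_min_valid_fraction = 0.9),
    list(variant_min_valid_fraction = 0.7),
    list(variant_min_mutated_fraction = 0.1))
  for (delta in tighter) {
    qc <- do.call(qc_thresholds, utils::modifyList(
      unclass(base_qc)[names(formals(qc_thresholds))], delta))
    # an all-removed error counts as zero retained for monotonicity
    rep <- tryCatch(filter_variants(s, qc)$report,
                    error = function(e) list(cells_after = 0,
                                             variants_after = 0))
    expect_lte(rep$cells_after, base$cells_after)
    expect_lte(rep$variants_after, base$variants_after)
  }
})

test_that("identify_clones recovers separated clones exactly and handles degeneracy", {
  sim <- simulate_sample(separated_config(seed = 42))
  filtered <- filter_variants(sim$sample)$sample
  s <- identify_clones(filtered, cluster_params(min_points = 10,
                                                epsilon = 0.2))
  expect_equal(ari(s$clone_labels, sim$truth$true_labels), 1.0)
  expect_equal(max(s$clone_labels), 3)
  expect_equal(sum(s$clone_labels == 0), 0)

  # identical AF rows: one clone, no noise
  flat <- toy_sample(sprintf("c%02d", 1:20), n_var = 3)
  flat$status$dna_filtered <- TRUE
  f <- identify_clones(flat, cluster_params(min_points = 5, epsilon = 0.1))
  expect_identical(f$clone_labels, rep(1L, 20))

  suppressWarnings(expect_error(
    identify_clones(toy_sample(), cluster_params(min_points = 10)),
    "cells < min_points"))
  expect_warning(
    identify_clones(toy_sample(sprintf("c%02d", 1:12), n_var = 2),
                    cluster_params(min_points = 5, epsilon = 0.1)),
    "not been QC-filtered")
})

test_that("identify_clones auto-estimates and logs epsilon when absent", {
  sim <- simulate_sample(separated_config(seed = 7))
  filtered <- filter_variants(sim$sample)$sample
  expect_message(
    s <- identify_clones(filtered, cluster_params(min_points = 10)),
    "auto-estimated epsilon")
  expect_equal(ari(s$clone_labels, sim$truth$true_labels), 1.0)
})

test_that("identify_clones is invariant to cell order", {
  sim <- simulate_sample(separated_config(seed = 13, n_cells = 40))
  s <- filter_variants(sim$sample)$sample
  s1 <- identify_clones(s, cluster_params(min_points = 8, epsilon = 0.2))
  set.seed(5)
  perm <- sample(n_cells(s))
  s2 <- s
  s2$dna <- tapomics:::subset_dna(s$dna, cells = perm)
  s2$cnv <- tapomics:::subset_assay_cells(s$cnv, perm)
  s2$protein <- tapomics:::subset_assay_cells(s$protein, perm)
  s2 <- identify_clones(s2, cluster_params(min_points = 8, epsilon = 0.2))
  # same partition: identical noise set, clusters equal up to relabelling
  # (equal-size clusters make the size-based numbering order-dependent)
  expect_identical(s2$clone_labels == 0L, (s1$clone_labels == 0L)[perm])
  expect_equal(ari(s2$clone_labels, s1$clone_labels[perm]), 1.0)
})

test_that("clone_sorted_matrix sorts by (label, barcode) and conserves rows", {
  m <- matrix(1:6, 3, 2)
  res <- clone_sorted_matrix(m, labels = c(2, 1, 1),
                             cell_barcodes = c("a", "b", "c"))
  expect_identical(res$annotation$barcode, c("b", "c", "a"))
  expect_identical(res$annotation$clone, c(1L, 1L, 2L))
  expect_identical(res$values, m[c(2, 3, 1), ])

  # equal labels fall back to barcode-lexicographic order
  res2 <- clone_sorted_matrix(m, labels = c(1, 1, 1),
                              cell_barcodes = c("z", "x", "y"))
  expect_identical(res2$annotation$barcode, c("x", "y", "z"))

  # permutation property: output rows are a permutation of input rows
  set.seed(3)
  mm <- matrix(rnorm(40), 10, 4)
  lab <- sample(0:2, 10, replace = TRUE)
  res3 <- clone_sorted_matrix(mm, lab,
                              cell_barcodes = sprintf("c%02d", 1:10))
  expect_equal(mm[res3$order, ], res3$values)
  expect_setequal(apply(res3$values, 1, paste, collapse = ","),
                  apply(mm, 1, paste, collapse = ","))

  expect_error(clone_sorted_matrix(m, labels = c(1, 2)), "labels for 3 rows")
})

test_that("feature_overlay joins values to coordinates in cell order", {
  coords <- matrix(c(0, 1, 2, 5, 6, 7), 3, 2)
  ov <- feature_overlay(coords, c(0, 50, 100), "chr1:100:A/G")
  expect_equal(ov$value, c(0, 50, 100))
  expect_equal(ov$x, c(0, 1, 2))
  expect_equal(unique(ov$feature), "chr1:100:A/G")

  ov2 <- feature_overlay(coords, rep(7, 3))
  expect_true(all(ov2$value == 7))

  # values taken from an AF column map through unchanged
  s <- toy_sample(paste0("c", 1:3), n_var = 2)
  s$dna$AF[, 2] <- c(10, 20, 30)
  ov3 <- feature_overlay(coords, s$dna$AF[, 2], s$dna$variant_ids[2])
  expect_equal(ov3$value, c(10, 20, 30))

  expect_error(feature_overlay(coords, 1:4), "4 values for 3")
  expect_error(feature_overlay(matrix(1, 3, 3), 1:3), "exactly 2 columns")
})

test_that("annotate_variants parses ids and honours the provider contract", {
  expect_equal(nrow(annotate_variants(character(0))), 0)

  tab <- data.frame(
    variant_id = c("chr1:100:A/G", "chr2:200:C/T", "chrX:42:G/A"),
    gene = c("G1", "G2", "G3"),
    protein_change = c("p.A1B", "p.C2D", "p.E3F"),
    function_class = c("missense", "nonsense", "synonymous"),
    stringsAsFactors = FALSE)
  prov <- tsv_annotation_provider(tab)
  res <- annotate_variants(c("chr2:200:C/T", "chrX:42:G/A", "chr1:100:A/G"),
                           provider = prov)
  expect_equal(res$gene, c("G2", "G3", "G1"))     # input order preserved
  expect_equal(res$pos, c(200L, 42L, 100L))

  # provider miss: NA row, not an error
  miss <- annotate_variants("chr9:9:T/C", provider = prov)
  expect_true(is.na(miss$gene))

  expect_error(annotate_variants("chr:notanumber:A/T"), "malformed")

  # bundled synthetic lookup table works end to end
  res2 <- annotate_variants("chr2:25234373:C/T")
  expect_equal(res2$gene, "DNMT3A")
})
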