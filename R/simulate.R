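#' Describe one simulated clone
#'
#' @param n_cells number of cells in the clone.
#' @param genotype integer vector over variants with codes 0 (wild-type),
#'   1 (heterozygous), 2 (homozygous alternate).
#' @param copy_number non-negative integer vector over CNV amplicons
#'   (2 = diploid).
#' @param protein_means positive mean antibody counts over proteins.
#' @return a list describing the clone, for [synthetic_config()].
#' @export
clone_spec <- function(n_cells, genotype, copy_number, protein_means) {
  stopifnot(n_cells >= 1, all(genotype %in% 0:2),
            all(copy_number >= 0), all(copy_number == round(copy_number)),
            all(protein_means > 0))
  list(n_cells = as.integer(n_cells), genotype = as.integer(genotype),
       copy_number = as.integer(copy_number),
       protein_means = as.numeric(protein_means))
}

default_clones <- function() {
  # Three well-separated clones (>= 0.4 apart in scaled-VAF space), with
  # copy-number profiles whose mean stays 2 so total-count normalization
  # is unbiased, and one marker protein per clone.
  base_prot <- c(50, 50, 50, 50, 50, 50, 50, 50)
  p1 <- base_prot; p1[1] <- 250
  p2 <- base_prot; p2[2] <- 300
  p3 <- base_prot; p3[3] <- 350
  g0 <- rep(0L, 30)
  g1 <- g0; g1[1:10] <- 1L
  g2 <- g0; g2[11:20] <- 2L
  g3 <- g0; g3[21:30] <- 1L; g3[1:5] <- 2L
  cn1 <- rep(2L, 20)
  cn2 <- cn1; cn2[1:5] <- 3L; cn2[6:10] <- 1L
  cn3 <- cn1; cn3[11:13] <- 4L; cn3[14:16] <- 0L
  list(clone_spec(150, g1, cn1, p1),
       clone_spec(100, g2, cn2, p2),
       clone_spec(50, g3, cn3, p3))
}

#' Configuration for the synthetic sample generator
#'
#' The generator emulates the structure of a droplet single-cell multiomics
#' run: clone-structured genotypes read out as noisy VAF, Poisson amplicon
#' counts scaled by copy number with multiplicative per-cell (droplet
#' depth) and per-amplicon (primer efficiency) factors, and overdispersed
#' negative-binomial antibody counts.
#'
#' @param clones list of [clone_spec()]s; all clones must agree on the
#'   number of variants, amplicons and proteins. The default is a
#'   well-separated 3-clone mixture (150/100/50 cells, 30 variants,
#'   20 amplicons, 8 proteins) whose largest clone is diploid everywhere.
#' @param vaf_noise_sd Gaussian noise (percent) around the genotype VAF
#'   centres 0/50/100; clipped to `[0, 100]`.
#' @param mean_depth mean read depth (DP) per call.
#' @param depth_dispersion gamma shape for the per-cell depth factor
#'   (mean 1); larger = more uniform cells.
#' @param gq_valid genotype quality assigned to non-dropout calls.
#' @param cnv_mean_depth mean CNV reads per amplicon at copy number 2.
#' @param cnv_cell_sd,cnv_amplicon_sd log-normal sigma of the per-cell and
#'   per-amplicon multiplicative factors on CNV counts.
#' @param protein_dispersion negative-binomial size for antibody counts
#'   (smaller = more overdispersed).
#' @param dropout_rate fraction of calls set missing (NGT 3, GQ 0, DP 0).
#' @param seed master seed (required); sub-seeds are derived from it per
#'   assay, so adding draws in one assay never perturbs another.
#' @return an object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(clones = default_clones(), vaf_noise_sd = 2,
                             mean_depth = 80, depth_dispersion = 10,
                             gq_valid = 99, cnv_mean_depth = 60,
                             cnv_cell_sd = 0.15, cnv_amplicon_sd = 0.15,
                             protein_dispersion = 5, dropout_rate = 0.01,
                             seed) {
  if (missing(seed)) stop("synthetic_config: seed is required", call. = FALSE)
  stopifnot(length(clones) >= 1, vaf_noise_sd >= 0, mean_depth > 0,
            depth_dispersion > 0, gq_valid >= 0, cnv_mean_depth > 0,
            protein_dispersion > 0, dropout_rate >= 0, dropout_rate <= 1)
  dims <- vapply(clones, function(cl)
    c(length(cl$genotype), length(cl$copy_number),
      length(cl$protein_means)), numeric(3))
  if (any(dims != dims[, 1]))
    stop("synthetic_config: clones disagree on variant/amplicon/protein counts",
         call. = FALSE)
  structure(list(clones = clones, vaf_noise_sd = vaf_noise_sd,
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 gq_valid = gq_valid, cnv_mean_depth = cnv_mean_depth,
                 cnv_cell_sd = cnv_cell_sd, cnv_amplicon_sd = cnv_amplicon_sd,
                 protein_dispersion = protein_dispersion,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Simulate a clone-structured multiomic sample with ground truth
#'
#' Draws one sample per the configuration: per cell of clone g, AF is
#' centred at 0/50/100 by genotype code with Gaussian noise clipped to
#' `[0, 100]`; DP is Poisson around `mean_depth` times a gamma per-cell
#' factor; GQ equals `gq_valid`; dropout calls get NGT 3, GQ 0, DP 0, AF 0.
#' CNV counts are Poisson with rate
#' `cnv_mean_depth * cell_factor * cn(g, j) / 2 * amplicon_factor`, and
#' protein counts are negative binomial with the clone's means. A single
#' master seed drives everything through per-assay sub-seeds.
#'
#' @param config a [synthetic_config()].
#' @return a list with `sample` (a `MultiomicSample`, clone labels set and
#'   renumbered by decreasing size) and `truth` (a `GroundTruth`:
#'   `true_labels`, `true_copy_number`, `true_protein_means` — rows indexed
#'   by the renumbered clone labels — and `signature_proteins`).
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  clones <- config$clones
  sizes <- vapply(clones, `[[`, integer(1), "n_cells")
  n <- sum(sizes)
  n_var <- length(clones[[1]]$genotype)
  n_amp <- length(clones[[1]]$copy_number)
  n_prot <- length(clones[[1]]$protein_means)
  G <- length(clones)
  raw_labels <- rep(seq_len(G), sizes)
  barcodes <- sprintf("cell_%05d", seq_len(n))
  variant_ids <- sprintf("chr1:%d:A/G", 1000L + 100L * seq_len(n_var))
  amplicon_ids <- sprintf("AMPL%03d", seq_len(n_amp))
  protein_ids <- sprintf("protein_%02d", seq_len(n_prot))

  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  # --- DNA ---
  set.seed(sub_seeds[1])
  geno <- do.call(rbind, lapply(seq_len(G), function(g)
    matrix(clones[[g]]$genotype, nrow = sizes[g], ncol = n_var,
           byrow = TRUE)))
  af <- c(0, 50, 100)[geno + 1L] +
    stats::rnorm(n * n_var, 0, config$vaf_noise_sd)
  af <- matrix(pmin(pmax(af, 0), 100), n, n_var)
  cell_depth <- stats::rgamma(n, shape = config$depth_dispersion,
                              rate = config$depth_dispersion)
  dp <- matrix(stats::rpois(n * n_var, config$mean_depth * cell_depth),
               n, n_var)
  gq <- matrix(config$gq_valid, n, n_var)
  ngt <- geno
  dropout <- matrix(stats::runif(n * n_var) < config$dropout_rate, n, n_var)
  ngt[dropout] <- 3L
  gq[dropout] <- 0
  dp[dropout] <- 0L
  af[dropout] <- 0
  dna <- dna_variant_assay(af, ngt, gq, dp, barcodes, variant_ids)

  # --- CNV ---
  set.seed(sub_seeds[2])
  cn <- do.call(rbind, lapply(seq_len(G), function(g)
    matrix(clones[[g]]$copy_number, nrow = sizes[g], ncol = n_amp,
           byrow = TRUE)))
  cell_factor <- stats::rlnorm(n, 0, config$cnv_cell_sd)
  amp_factor <- stats::rlnorm(n_amp, 0, config$cnv_amplicon_sd)
  lambda <- config$cnv_mean_depth * (cn / 2) * cell_factor *
    rep(amp_factor, each = n)
  cnv_counts <- matrix(stats::rpois(n * n_amp, lambda), n, n_amp)
  cnv <- assay_matrix(cnv_counts, barcodes, amplicon_ids, units = "count")

  # --- protein ---
  set.seed(sub_seeds[3])
  prot_mu <- do.call(rbind, lapply(seq_len(G), function(g)
    matrix(clones[[g]]$protein_means, nrow = sizes[g], ncol = n_prot,
           byrow = TRUE)))
  prot_counts <- matrix(
    stats::rnbinom(n * n_prot, mu = prot_mu,
                   size = config$protein_dispersion), n, n_prot)
  protein <- assay_matrix(prot_counts, barcodes, protein_ids,
                          units = "count")

  sample <- build_sample(dna, cnv, protein,
                         name = sprintf("synthetic_seed%d", config$seed))
  sample <- set_clone_labels(sample, raw_labels)

  # ground truth in renumbered clone order (1 = largest clone)
  final_of_raw <- integer(G)
  final_of_raw[order(-sizes, seq_len(G))] <- seq_len(G)
  raw_of_final <- order(final_of_raw)
  true_cn <- do.call(rbind, lapply(raw_of_final, function(g)
    clones[[g]]$copy_number))
  true_pm <- do.call(rbind, lapply(raw_of_final, function(g)
    clones[[g]]$protein_means))
  rownames(true_cn) <- rownames(true_pm) <- as.character(seq_len(G))
  colnames(true_cn) <- amplicon_ids
  colnames(true_pm) <- protein_ids
  grand <- colMeans(true_pm)
  signature_proteins <- lapply(seq_len(G), function(k)
    protein_ids[true_pm[k, ] != grand])
  names(signature_proteins) <- as.character(seq_len(G))

  truth <- structure(list(true_labels = sample$clone_labels,
                          true_copy_number = true_cn,
                          true_protein_means = true_pm,
                          signature_proteins = signature_proteins),
                     class = "GroundTruth")
  list(sample = sample, truth = truth)
}

#' Write a synthetic sample to disk as an HDF5 fixture with sidecars
#'
#' Simulates a sample and writes `<prefix>.h5` plus plain-text ground-truth
#' sidecars: `<prefix>.labels.tsv` (barcode, clone) and
#' `<prefix>.cnv_truth.tsv` (clone-by-amplicon copy numbers).
#'
#' @param config a [synthetic_config()].
#' @param prefix output path prefix.
#' @return invisibly, a named list of the three file paths.
#' @export
write_fixture <- function(config, prefix) {
  sim <- simulate_sample(config)
  paths <- list(h5 = paste0(prefix, ".h5"),
                labels = paste0(prefix, ".labels.tsv"),
                cnv_truth = paste0(prefix, ".cnv_truth.tsv"))
  write_h5(sim$sample, paths$h5)
  utils::write.table(
    data.frame(barcode = sim$sample$dna$cell_barcodes,
               clone = sim$truth$true_labels),
    paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(clone = rownames(sim$truth$true_copy_number),
               sim$truth$true_copy_number, check.names = FALSE),
    paths$cnv_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
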