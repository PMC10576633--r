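#' QC thresholds for variant-call filtering
#'
#' Defaults follow common practice for targeted single-cell DNA panels:
#' calls need read depth >= 10 and genotype quality >= 30; mutant calls
#' (NGT 1 or 2) additionally need at least 20% allele frequency; cells and
#' variants must each have at least 50% valid calls; and a variant must be
#' mutated in at least 1% of the cells where it was validly called.
#'
#' @param min_depth minimum read depth (DP) for a valid call.
#' @param min_gq minimum genotype quality (GQ) for a valid call.
#' @param min_af_mutated minimum allele frequency (percent) for a valid
#'   mutant call (NGT 1 or 2); wild-type calls are exempt.
#' @param cell_min_valid_fraction keep a cell only if at least this fraction
#'   of its calls across variants is valid.
#' @param variant_min_valid_fraction keep a variant only if at least this
#'   fraction of its calls across retained cells is valid.
#' @param variant_min_mutated_fraction keep a variant only if at least this
#'   fraction of its valid calls is mutated (NGT 1 or 2).
#' @return an object of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_depth = 10, min_gq = 30, min_af_mutated = 20,
                          cell_min_valid_fraction = 0.5,
                          variant_min_valid_fraction = 0.5,
                          variant_min_mutated_fraction = 0.01) {
  qc <- structure(
    list(min_depth = min_depth, min_gq = min_gq,
         min_af_mutated = min_af_mutated,
         cell_min_valid_fraction = cell_min_valid_fraction,
         variant_min_valid_fraction = variant_min_valid_fraction,
         variant_min_mutated_fraction = variant_min_mutated_fraction),
    class = "QCThresholds")
  with(qc, stopifnot(
    min_depth >= 0, min_gq >= 0,
    min_af_mutated >= 0, min_af_mutated <= 100,
    cell_min_valid_fraction >= 0, cell_min_valid_fraction <= 1,
    variant_min_valid_fraction >= 0, variant_min_valid_fraction <= 1,
    variant_min_mutated_fraction >= 0, variant_min_mutated_fraction <= 1))
  qc
}

#' Per-call validity mask
#'
#' A call (cell i, variant j) is valid iff it is not missing (`NGT != 3`),
#' has sufficient depth and genotype quality, and — when it is a mutant call
#' — sufficient allele frequency:
#' `NGT != 3 & DP >= min_depth & GQ >= min_gq & (NGT == 0 | AF >= min_af_mutated)`.
#'
#' @param dna a `DnaVariantAssay`.
#' @param qc a [qc_thresholds()] object.
#' @return a logical `n_cells x n_variants` matrix, `TRUE` for valid calls.
#' @export
call_validity_mask <- function(dna, qc = qc_thresholds()) {
  validate_dna_assay(dna)
  dna$NGT != 3 &
    dna$DP >= qc$min_depth &
    dna$GQ >= qc$min_gq &
    (dna$NGT == 0 | dna$AF >= qc$min_af_mutated)
}

#' QC-filter the DNA variant calls of a sample
#'
#' Three steps, applied in a fixed, documented order:
#' 1. compute the per-call validity mask ([call_validity_mask()]);
#' 2. drop every cell whose fraction of valid calls across variants is below
#'    `cell_min_valid_fraction` — dropped cells are removed from all three
#'    assays, since the sample shares one cell axis;
#' 3. on the remaining cells, keep variant j only if its fraction of valid
#'    calls is at least `variant_min_valid_fraction` and the fraction of
#'    mutant calls (NGT 1 or 2) among its valid calls is at least
#'    `variant_min_mutated_fraction`.
#'
#' Cells are filtered before variants so that low-quality cells cannot doom
#' otherwise usable variants. Invalid calls that survive filtering remain in
#' the matrices but are recorded in the sample's `dna$valid_mask` and treated
#' as missing by downstream VAF consumers.
#'
#' @param sample a `MultiomicSample` with `status$dna_filtered == FALSE`.
#' @param qc a [qc_thresholds()] object.
#' @return a list with `sample` (filtered, `dna_filtered = TRUE`) and
#'   `report` (a `FilterReport`).
#' @export
filter_variants <- function(sample, qc = qc_thresholds()) {
  validate_sample(sample)
  if (isTRUE(sample$status$dna_filtered))
    stop("filter_variants: sample is already filtered", call. = FALSE)

  mask <- call_validity_mask(sample$dna, qc)
  n_cell0 <- nrow(mask)
  n_var0 <- ncol(mask)
  invalid_call_fraction <- mean(!mask)

  keep_cells <- rowMeans(mask) >= qc$cell_min_valid_fraction
  if (!any(keep_cells))
    stop("filter_variants: all ", n_cell0, " cells removed at ",
         "cell_min_valid_fraction = ", qc$cell_min_valid_fraction,
         call. = FALSE)
  mask2 <- mask[keep_cells, , drop = FALSE]
  ngt2 <- sample$dna$NGT[keep_cells, , drop = FALSE]

  valid_frac <- colMeans(mask2)
  mutated <- (ngt2 == 1 | ngt2 == 2) & mask2
  n_valid <- colSums(mask2)
  mutated_frac <- ifelse(n_valid > 0, colSums(mutated) / n_valid, 0)
  pass_valid <- valid_frac >= qc$variant_min_valid_fraction
  pass_mut <- mutated_frac >= qc$variant_min_mutated_fraction
  keep_vars <- pass_valid & pass_mut
  if (!any(keep_vars))
    stop("filter_variants: all ", n_var0, " variants removed at ",
         "variant_min_valid_fraction = ", qc$variant_min_valid_fraction,
         ", variant_min_mutated_fraction = ", qc$variant_min_mutated_fraction,
         call. = FALSE)

  cell_idx <- which(keep_cells)
  sample$dna <- subset_dna(sample$dna, cells = cell_idx,
                           variants = which(keep_vars))
  sample$dna$valid_mask <- mask2[, keep_vars, drop = FALSE]
  sample$cnv <- subset_assay_cells(sample$cnv, cell_idx)
  sample$protein <- subset_assay_cells(sample$protein, cell_idx)
  if (!is.null(sample$clone_labels))
    sample$clone_labels <- renumber_labels(sample$clone_labels[cell_idx])
  sample$status$dna_filtered <- TRUE
  validate_sample(sample)

  report <- structure(
    list(cells_before = n_cell0, cells_after = sum(keep_cells),
         variants_before = n_var0, variants_after = sum(keep_vars),
         invalid_call_fraction = invalid_call_fraction,
         removed = list(cells_low_valid_fraction = sum(!keep_cells),
                        variants_low_valid_fraction = sum(!pass_valid),
                        variants_low_mutated_fraction = sum(!pass_mut))),
    class = "FilterReport")
  list(sample = sample, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.FilterReport <- function(x, ...) {
  c(sprintf("cells: %d -> %d (removed %d below cell valid-call fraction)",
            x$cells_before, x$cells_after,
            x$removed$cells_low_valid_fraction),
    sprintf("variants: %d -> %d (%d below valid-call fraction, %d below mutated fraction)",
            x$variants_before, x$variants_after,
            x$removed$variants_low_valid_fraction,
            x$removed$variants_low_mutated_fraction),
    sprintf("invalid call fraction before filtering: %.4f",
            x$invalid_call_fraction))
}
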