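#' Assemble a multiomic sample from its three assays
#'
#' Builds the per-sample container holding the DNA variant assay, the CNV
#' amplicon count assay and the protein (antibody) count assay. The three
#' assays may disagree on their cell barcodes (droplets can drop out of
#' individual assays); the sample is restricted to the intersection of the
#' three barcode sets and all assays are reordered to one canonical
#' (lexicographic) cell order, so that a clone label derived from DNA indexes
#' the same cell's row in every assay. Dropped barcodes are reported in the
#' `drop_report` element and in a message.
#'
#' @param dna a [dna_variant_assay()].
#' @param cnv an [assay_matrix()] with `units = "count"` of CNV amplicon
#'   read counts.
#' @param protein an [assay_matrix()] with `units = "count"` of antibody
#'   read counts.
#' @param name sample name.
#' @return an object of class `MultiomicSample` with elements `name`, `dna`,
#'   `cnv`, `protein`, `clone_labels` (NULL until assigned), `status` (flags
#'   `dna_filtered`, `cnv_normalized`, `protein_normalized`) and
#'   `drop_report` (dropped-barcode count per assay).
#' @export
build_sample <- function(dna, cnv, protein, name = "sample") {
  validate_dna_assay(dna)
  validate_assay_matrix(cnv)
  validate_assay_matrix(protein)

  common <- intersect(intersect(dna$cell_barcodes, cnv$cell_barcodes),
                      protein$cell_barcodes)
  if (length(common) == 0L)
    stop("build_sample: empty barcode intersection (dna: ",
         length(dna$cell_barcodes), ", cnv: ", length(cnv$cell_barcodes),
         ", protein: ", length(protein$cell_barcodes), " barcodes)",
         call. = FALSE)
  common <- sort(common)

  drop_report <- list(
    dna = length(dna$cell_barcodes) - length(common),
    cnv = length(cnv$cell_barcodes) - length(common),
    protein = length(protein$cell_barcodes) - length(common))
  if (any(unlist(drop_report) > 0))
    message("build_sample: dropped barcodes outside intersection (dna: ",
            drop_report$dna, ", cnv: ", drop_report$cnv,
            ", protein: ", drop_report$protein, ")")

  sample <- structure(
    list(name = as.character(name),
         dna = subset_dna(dna, cells = match(common, dna$cell_barcodes)),
         cnv = subset_assay_cells(cnv, match(common, cnv$cell_barcodes)),
         protein = subset_assay_cells(protein,
                                      match(common, protein$cell_barcodes)),
         clone_labels = NULL,
         status = list(dna_filtered = FALSE, cnv_normalized = FALSE,
                       protein_normalized = FALSE),
         drop_report = drop_report),
    class = "MultiomicSample")
  validate_sample(sample)
  sample
}

validate_sample <- function(sample) {
  stopifnot(inherits(sample, "MultiomicSample"))
  bc <- sample$dna$cell_barcodes
  if (!identical(bc, sample$cnv$cell_barcodes) ||
      !identical(bc, sample$protein$cell_barcodes))
    stop("MultiomicSample: assays disagree on cell barcodes or order",
         call. = FALSE)
  if (!is.null(sample$clone_labels) &&
      length(sample$clone_labels) != length(bc))
    stop("MultiomicSample: clone labels length ", length(sample$clone_labels),
         " != ", length(bc), " cells", call. = FALSE)
  invisible(sample)
}

#' Number of cells in a sample
#' @param sample a `MultiomicSample`.
#' @export
n_cells <- function(sample) length(sample$dna$cell_barcodes)

#' Summary statistics for a multiomic sample
#'
#' @param sample a `MultiomicSample`.
#' @return an object of class `SummaryStats` with the four assay dimensions
#'   (`n_cells`, `n_variants`, `n_cnv_amplicons`, `n_proteins`) and the
#'   processing-status flags.
#' @export
summarize_sample <- function(sample) {
  validate_sample(sample)
  structure(
    list(name = sample$name,
         n_cells = n_cells(sample),
         n_variants = length(sample$dna$variant_ids),
         n_cnv_amplicons = length(sample$cnv$feature_ids),
         n_proteins = length(sample$protein$feature_ids),
         status = sample$status),
    class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat("Multiomic sample '", x$name, "'\n", sep = "")
  cat(sprintf("  %d cells, %d variants, %d CNV amplicons, %d proteins\n",
              x$n_cells, x$n_variants, x$n_cnv_amplicons, x$n_proteins))
  cat(sprintf("  status: dna_filtered=%s cnv_normalized=%s protein_normalized=%s\n",
              x$status$dna_filtered, x$status$cnv_normalized,
              x$status$protein_normalized))
  invisible(x)
}

#' @export
print.MultiomicSample <- function(x, ...) {
  print(summarize_sample(x))
  if (!is.null(x$clone_labels)) {
    k <- max(0L, x$clone_labels)
    cat(sprintf("  clone labels: %d clones, %d noise/unassigned cells\n",
                k, sum(x$clone_labels == 0L)))
  }
  invisible(x)
}

# Renumber positive labels 1..K by decreasing clone size; ties broken by
# the smaller original label. 0 (noise/unassigned) is preserved.
renumber_labels <- function(labels) {
  labels <- as.integer(labels)
  pos <- labels[labels > 0L]
  if (length(pos) == 0L) return(labels)
  tab <- table(pos)
  orig <- as.integer(names(tab))
  ord <- order(-as.integer(tab), orig)
  map <- integer(max(orig))
  map[orig[ord]] <- seq_along(ord)
  out <- labels
  out[labels > 0L] <- map[labels[labels > 0L]]
  out
}

#' Assign per-cell clone labels
#'
#' Stores an integer clone assignment on the sample. Label 0 means
#' unassigned/noise; positive labels are renumbered `1..K` by decreasing
#' clone size (ties broken by the smaller original label), so that "clone 1"
#' is always the largest clone regardless of how the labels were produced.
#'
#' @param sample a `MultiomicSample`.
#' @param labels integer vector of length `n_cells(sample)`, entries >= 0.
#' @return the sample with `clone_labels` set.
#' @export
set_clone_labels <- function(sample, labels) {
  validate_sample(sample)
  if (length(labels) != n_cells(sample))
    stop("set_clone_labels: ", length(labels), " labels for ",
         n_cells(sample), " cells", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("set_clone_labels: labels must be non-negative integers",
         call. = FALSE)
  sample$clone_labels <- renumber_labels(labels)
  sample
}
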