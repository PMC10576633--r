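#' Generic cell-by-feature assay matrix
#'
#' The basic container for a single assay: a numeric matrix with cells as
#' rows and features (CNV amplicons, antibodies, ...) as columns, plus the
#' cell barcodes, feature identifiers, and a units tag describing what the
#' values are.
#'
#' @param values numeric matrix, `n_cells x n_features`.
#' @param cell_barcodes character vector of unique cell barcodes, one per row.
#' @param feature_ids character vector of unique feature identifiers, one per
#'   column.
#' @param units one of `"count"` (non-negative integers), `"percent"`
#'   (0-100), `"normalized"` or `"ploidy"`.
#' @return an object of class `AssayMatrix`.
#' @export
assay_matrix <- function(values, cell_barcodes, feature_ids,
                         units = c("count", "percent", "normalized", "ploidy")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  x <- structure(
    list(values = values,
         cell_barcodes = as.character(cell_barcodes),
         feature_ids = as.character(feature_ids),
         units = units),
    class = "AssayMatrix")
  validate_assay_matrix(x)
  x
}

validate_assay_matrix <- function(x) {
  stopifnot(inherits(x, "AssayMatrix"))
  if (nrow(x$values) != length(x$cell_barcodes))
    stop("AssayMatrix: ", nrow(x$values), " rows but ",
         length(x$cell_barcodes), " cell barcodes", call. = FALSE)
  if (ncol(x$values) != length(x$feature_ids))
    stop("AssayMatrix: ", ncol(x$values), " columns but ",
         length(x$feature_ids), " feature ids", call. = FALSE)
  if (anyDuplicated(x$cell_barcodes))
    stop("AssayMatrix: duplicated cell barcodes", call. = FALSE)
  if (anyDuplicated(x$feature_ids))
    stop("AssayMatrix: duplicated feature ids", call. = FALSE)
  if (x$units == "count") {
    v <- x$values
    if (any(v < 0, na.rm = TRUE) || any(v != round(v), na.rm = TRUE))
      stop("AssayMatrix: units 'count' requires non-negative integers",
           call. = FALSE)
  }
  invisible(x)
}

#' @export
print.AssayMatrix <- function(x, ...) {
  cat(sprintf("AssayMatrix: %d cells x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  invisible(x)
}

#' @export
dim.AssayMatrix <- function(x) dim(x$values)

subset_assay_cells <- function(x, idx) {
  x$values <- x$values[idx, , drop = FALSE]
  x$cell_barcodes <- x$cell_barcodes[idx]
  x
}

#' DNA variant-call assay
#'
#' Holds the four aligned cell-by-variant layers produced by single-cell
#' amplicon variant calling: `AF` (variant allele frequency in percent,
#' 0-100), `NGT` (genotype code: 0 wild-type, 1 heterozygous, 2 homozygous
#' alternate, 3 missing), `GQ` (genotype quality) and `DP` (read depth).
#' Variant identifiers use the canonical `"CHROM:POS:REF/ALT"` form with
#' 1-based positions.
#'
#' @param AF,NGT,GQ,DP numeric matrices of identical shape
#'   (`n_cells x n_variants`).
#' @param cell_barcodes unique cell barcodes, one per row.
#' @param variant_ids unique variant identifiers, one per column.
#' @return an object of class `DnaVariantAssay`.
#' @export
dna_variant_assay <- function(AF, NGT, GQ, DP, cell_barcodes, variant_ids) {
  layers <- list(AF = as.matrix(AF), NGT = as.matrix(NGT),
                 GQ = as.matrix(GQ), DP = as.matrix(DP))
  for (nm in names(layers)) storage.mode(layers[[nm]]) <- "double"
  x <- structure(
    c(layers,
      list(cell_barcodes = as.character(cell_barcodes),
           variant_ids = as.character(variant_ids),
           valid_mask = NULL)),
    class = "DnaVariantAssay")
  validate_dna_assay(x)
  x
}

validate_dna_assay <- function(x) {
  stopifnot(inherits(x, "DnaVariantAssay"))
  d <- dim(x$AF)
  for (nm in c("NGT", "GQ", "DP"))
    if (!identical(dim(x[[nm]]), d))
      stop("DnaVariantAssay: layer ", nm, " shape (",
           paste(dim(x[[nm]]), collapse = "x"),
           ") differs from AF (", paste(d, collapse = "x"), ")",
           call. = FALSE)
  if (d[1] != length(x$cell_barcodes))
    stop("DnaVariantAssay: ", d[1], " rows but ",
         length(x$cell_barcodes), " cell barcodes", call. = FALSE)
  if (d[2] != length(x$variant_ids))
    stop("DnaVariantAssay: ", d[2], " columns but ",
         length(x$variant_ids), " variant ids", call. = FALSE)
  if (anyDuplicated(x$cell_barcodes))
    stop("DnaVariantAssay: duplicated cell barcodes", call. = FALSE)
  if (anyDuplicated(x$variant_ids))
    stop("DnaVariantAssay: duplicated variant ids", call. = FALSE)
  if (any(x$AF < 0 | x$AF > 100))
    stop("DnaVariantAssay: AF outside [0, 100]", call. = FALSE)
  if (!all(x$NGT %in% c(0, 1, 2, 3)))
    stop("DnaVariantAssay: NGT codes outside {0,1,2,3}", call. = FALSE)
  if (any(x$GQ < 0))
    stop("DnaVariantAssay: negative GQ", call. = FALSE)
  if (any(x$DP < 0) || any(x$DP != round(x$DP)))
    stop("DnaVariantAssay: DP must be non-negative integers", call. = FALSE)
  invisible(x)
}

#' @export
dim.DnaVariantAssay <- function(x) dim(x$AF)

#' @export
print.DnaVariantAssay <- function(x, ...) {
  cat(sprintf("DnaVariantAssay: %d cells x %d variants (layers AF, NGT, GQ, DP)\n",
              nrow(x$AF), ncol(x$AF)))
  invisible(x)
}

subset_dna <- function(x, cells = NULL, variants = NULL) {
  if (!is.null(cells)) {
    for (nm in c("AF", "NGT", "GQ", "DP"))
      x[[nm]] <- x[[nm]][cells, , drop = FALSE]
    if (!is.null(x$valid_mask))
      x$valid_mask <- x$valid_mask[cells, , drop = FALSE]
    x$cell_barcodes <- x$cell_barcodes[cells]
  }
  if (!is.null(variants)) {
    for (nm in c("AF", "NGT", "GQ", "DP"))
      x[[nm]] <- x[[nm]][, variants, drop = FALSE]
    if (!is.null(x$valid_mask))
      x$valid_mask <- x$valid_mask[, variants, drop = FALSE]
    x$variant_ids <- x$variant_ids[variants]
  }
  x
}
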