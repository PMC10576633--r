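#' Normalize CNV amplicon read counts
#'
#' Two-step normalization removing the dominant technical variation in
#' amplicon counting:
#' 1. *row (cell) step*: each cell's counts are divided by its total and
#'    rescaled by the median cell total, correcting per-droplet sequencing
#'    depth: `r(i,j) = c(i,j) / T(i) * median(T)`;
#' 2. *column (amplicon) step*: each amplicon is divided by its median over
#'    cells, correcting primer/amplification efficiency:
#'    `n(i,j) = r(i,j) / median_i(r(i,j))`.
#'
#' Medians are used so that large aneuploid clones do not drag the scaling.
#' Cells with zero total counts and amplicons with zero median are dropped
#' with a warning. When a `MultiomicSample` is given, dropped cells are
#' removed from all assays and `status$cnv_normalized` is set.
#'
#' @param counts an `AssayMatrix` with `units = "count"`, or a
#'   `MultiomicSample` whose `cnv` assay should be normalized in place.
#' @return the normalized `AssayMatrix` (`units = "normalized"`), or the
#'   updated sample.
#' @export
normalize_cnv <- function(counts) {
  if (inherits(counts, "MultiomicSample")) {
    sample <- counts
    norm <- normalize_cnv(sample$cnv)
    keep <- match(norm$cell_barcodes, sample$cnv$cell_barcodes)
    if (length(keep) < n_cells(sample)) {
      sample$dna <- subset_dna(sample$dna, cells = keep)
      sample$protein <- subset_assay_cells(sample$protein, keep)
      if (!is.null(sample$clone_labels))
        sample$clone_labels <- renumber_labels(sample$clone_labels[keep])
    }
    sample$cnv <- norm
    sample$status$cnv_normalized <- TRUE
    validate_sample(sample)
    return(sample)
  }

  validate_assay_matrix(counts)
  if (counts$units != "count")
    stop("normalize_cnv: expected units 'count', got '", counts$units, "'",
         call. = FALSE)
  v <- counts$values
  if (nrow(v) < 1L || ncol(v) < 1L)
    stop("normalize_cnv: need at least 1 cell and 1 amplicon", call. = FALSE)

  totals <- rowSums(v)
  zero_cells <- totals == 0
  if (any(zero_cells)) {
    warning("normalize_cnv: dropping ", sum(zero_cells),
            " cell(s) with zero total counts", call. = FALSE)
    v <- v[!zero_cells, , drop = FALSE]
    totals <- totals[!zero_cells]
  }
  if (nrow(v) == 0L)
    stop("normalize_cnv: no cells with non-zero counts", call. = FALSE)
  r <- v / totals * stats::median(totals)

  med <- apply(r, 2L, stats::median)
  zero_amps <- med == 0
  if (all(zero_amps))
    stop("normalize_cnv: all amplicons have zero median counts",
         call. = FALSE)
  if (any(zero_amps)) {
    warning("normalize_cnv: dropping ", sum(zero_amps),
            " amplicon(s) with zero median counts", call. = FALSE)
    r <- r[, !zero_amps, drop = FALSE]
    med <- med[!zero_amps]
  }
  n <- sweep(r, 2L, med, "/")

  assay_matrix(n,
               cell_barcodes = counts$cell_barcodes[!zero_cells],
               feature_ids = counts$feature_ids[!zero_amps],
               units = "normalized")
}

#' Per-amplicon ploidy against a diploid reference clone
#'
#' Converts normalized CNV counts into ploidy by designating one clone as
#' diploid: with `mu(j)` the mean normalized count of amplicon j over
#' reference-clone cells, each cell's ploidy is
#' `p(i,j) = 2 * n(i,j) / mu(j)`, and clone-level ploidy is the mean of cell
#' ploidies within each clone (noise cells, label 0, are excluded). By
#' construction the reference clone's clone-level ploidy is exactly 2 at
#' every amplicon.
#'
#' @param normalized an `AssayMatrix` with `units = "normalized"` (from
#'   [normalize_cnv()]), or a `MultiomicSample` with `cnv_normalized` status.
#' @param labels integer clone labels (ignored when a sample carrying labels
#'   is given).
#' @param reference_clone positive clone label taken to be diploid.
#' @param min_reference_cells minimum number of cells required in the
#'   reference clone; a mean over fewer cells is too noisy to anchor the
#'   other clones.
#' @return an object of class `PloidyResult`: `cell_ploidy`
#'   (cells x amplicons), `clone_ploidy` (clones x amplicons, rows named by
#'   clone label), `reference_clone`, and `tidy` — (clone, amplicon, ploidy)
#'   triples ready for scatter plotting.
#' @export
calculate_ploidy <- function(normalized, labels = NULL, reference_clone = 1L,
                             min_reference_cells = 10L) {
  if (inherits(normalized, "MultiomicSample")) {
    sample <- normalized
    if (!isTRUE(sample$status$cnv_normalized))
      stop("calculate_ploidy: run normalize_cnv() first", call. = FALSE)
    if (is.null(labels)) labels <- sample$clone_labels
    if (is.null(labels))
      stop("calculate_ploidy: sample has no clone labels", call. = FALSE)
    normalized <- sample$cnv
  }
  validate_assay_matrix(normalized)
  if (normalized$units != "normalized")
    stop("calculate_ploidy: expected units 'normalized', got '",
         normalized$units, "'", call. = FALSE)
  v <- normalized$values
  labels <- as.integer(labels)
  if (length(labels) != nrow(v))
    stop("calculate_ploidy: ", length(labels), " labels for ",
         nrow(v), " cells", call. = FALSE)
  reference_clone <- as.integer(reference_clone)
  if (reference_clone < 1L)
    stop("calculate_ploidy: reference_clone must be a positive label",
         call. = FALSE)
  ref <- labels == reference_clone
  if (sum(ref) < min_reference_cells)
    stop("calculate_ploidy: reference clone ", reference_clone, " has ",
         sum(ref), " cells, fewer than min_reference_cells = ",
         min_reference_cells, call. = FALSE)

  mu <- colMeans(v[ref, , drop = FALSE])
  if (any(mu == 0))
    stop("calculate_ploidy: zero reference mean at amplicon(s): ",
         paste(normalized$feature_ids[mu == 0], collapse = ", "),
         call. = FALSE)
  cell_ploidy <- 2 * sweep(v, 2L, mu, "/")
  dimnames(cell_ploidy) <- list(normalized$cell_barcodes,
                                normalized$feature_ids)

  clones <- sort(unique(labels[labels > 0L]))
  clone_ploidy <- do.call(rbind, lapply(clones, function(g) {
    colMeans(cell_ploidy[labels == g, , drop = FALSE])
  }))
  dimnames(clone_ploidy) <- list(as.character(clones),
                                 normalized$feature_ids)

  tidy <- data.frame(
    clone = rep(clones, each = ncol(v)),
    amplicon = rep(normalized$feature_ids, times = length(clones)),
    ploidy = as.vector(t(clone_ploidy)),
    stringsAsFactors = FALSE)

  structure(list(cell_ploidy = cell_ploidy, clone_ploidy = clone_ploidy,
                 reference_clone = reference_clone, tidy = tidy),
            class = "PloidyResult")
}

#' @export
print.PloidyResult <- function(x, ...) {
  cat(sprintf("PloidyResult: %d cells x %d amplicons, %d clones (reference clone %d)\n",
              nrow(x$cell_ploidy), ncol(x$cell_ploidy),
              nrow(x$clone_ploidy), x$reference_clone))
  invisible(x)
}
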