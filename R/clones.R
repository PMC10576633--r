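#' Parameters for density-based clone identification
#'
#' @param min_points minimum number of points (self included) within
#'   `epsilon` for a point to be a core point; also the `k` used for the
#'   k-nearest-neighbour curve when `epsilon` is auto-estimated.
#' @param epsilon neighbourhood radius in scaled-VAF space (allele
#'   frequencies divided by `af_scale`, so coordinates lie in `[0, 1]`).
#'   When `NULL` it is chosen as the maximum-curvature knee of the sorted
#'   k-NN distance curve and reported in a message.
#' @param af_scale constant the AF matrix is divided by before clustering;
#'   100 maps percent AF onto `[0, 1]`.
#' @return an object of class `ClusterParams`.
#' @export
cluster_params <- function(min_points = 10L, epsilon = NULL,
                           af_scale = 100) {
  stopifnot(min_points >= 1, is.null(epsilon) || epsilon > 0, af_scale > 0)
  structure(list(min_points = as.integer(min_points), epsilon = epsilon,
                 af_scale = af_scale),
            class = "ClusterParams")
}

# Plain DBSCAN on a points-in-rows matrix. minPts counts the point itself,
# matching the usual convention. Returns integer labels, 0 = noise.
dbscan_labels <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nbrs) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0L) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      for (k in nbrs[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

# Knee of the ascending sorted k-NN distance curve: the point with maximum
# perpendicular distance to the chord joining the curve's endpoints.
knee_epsilon <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  kdist <- apply(D, 1L, function(d) sort(d)[min(k, n)])
  y <- sort(kdist)
  if (y[n] - y[1] < .Machine$double.eps) return(max(y[n], 1e-6))
  x <- seq_len(n)
  # perpendicular distance of (x, y) to the chord (1, y1)-(n, yn)
  dx <- n - 1
  dy <- y[n] - y[1]
  num <- abs(dy * (x - 1) - dx * (y - y[1]))
  knee <- which.max(num / sqrt(dx^2 + dy^2))
  max(y[knee], 1e-6)
}

#' Identify cell clones from variant allele frequencies
#'
#' Clusters cells with DBSCAN on the AF matrix divided by `af_scale`
#' (Euclidean metric). Density-based clustering needs no preset clone count
#' and labels ambient/low-density cells as noise (label 0). Clusters are
#' renumbered `1..K` by decreasing size. Invalid calls recorded in the
#' sample's `valid_mask` are treated as missing and imputed with the
#' per-variant mean over valid calls before clustering.
#'
#' When `epsilon` is not supplied it is auto-estimated from the knee of the
#' sorted `min_points`-nearest-neighbour distance curve and logged, so a run
#' is reproducible from its log.
#'
#' @param sample a `MultiomicSample`, normally after [filter_variants()]
#'   (a warning is emitted otherwise).
#' @param params a [cluster_params()] object.
#' @return the sample with `clone_labels` set (see [set_clone_labels()]).
#' @export
identify_clones <- function(sample, params = cluster_params()) {
  validate_sample(sample)
  if (!isTRUE(sample$status$dna_filtered))
    warning("identify_clones: sample has not been QC-filtered; ",
            "clustering on unfiltered variant calls", call. = FALSE)
  if (n_cells(sample) < params$min_points)
    stop("identify_clones: ", n_cells(sample), " cells < min_points = ",
         params$min_points, call. = FALSE)

  X <- sample$dna$AF / params$af_scale
  if (!is.null(sample$dna$valid_mask)) {
    mask <- sample$dna$valid_mask
    for (j in seq_len(ncol(X))) {
      bad <- !mask[, j]
      if (any(bad)) {
        mu <- if (all(bad)) 0 else mean(X[!bad, j])
        X[bad, j] <- mu
      }
    }
  }

  eps <- params$epsilon
  if (is.null(eps)) {
    eps <- knee_epsilon(X, params$min_points)
    message(sprintf(
      "identify_clones: auto-estimated epsilon = %.6g (knee of %d-NN distance curve)",
      eps, params$min_points))
  }
  labels <- dbscan_labels(X, eps, params$min_points)
  set_clone_labels(sample, labels)
}

#' Reorder a matrix by clone label for heatmap display
#'
#' Sorts cells by (clone label ascending, barcode ascending) and returns the
#' permuted matrix together with a per-row annotation, the form heatmap
#' renderers expect. Works on an [assay_matrix()] or any numeric matrix with
#' one row per cell (e.g. an AF layer).
#'
#' @param matrix an `AssayMatrix` or a numeric matrix (rows = cells).
#' @param labels integer clone labels, one per row, or a `MultiomicSample`
#'   whose `clone_labels` should be used.
#' @param cell_barcodes barcodes used as the secondary sort key; taken from
#'   the `AssayMatrix` when available.
#' @return a list with `values` (the reordered matrix), `annotation` (a
#'   data.frame with `barcode` and `clone` per reordered row) and `order`
#'   (the permutation applied).
#' @export
clone_sorted_matrix <- function(matrix, labels, cell_barcodes = NULL) {
  if (inherits(labels, "MultiomicSample")) {
    if (is.null(labels$clone_labels))
      stop("clone_sorted_matrix: sample has no clone labels", call. = FALSE)
    labels <- labels$clone_labels
  }
  if (inherits(matrix, "AssayMatrix")) {
    if (is.null(cell_barcodes)) cell_barcodes <- matrix$cell_barcodes
    matrix <- matrix$values
  }
  matrix <- as.matrix(matrix)
  if (is.null(cell_barcodes))
    cell_barcodes <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  if (length(labels) != nrow(matrix))
    stop("clone_sorted_matrix: ", length(labels), " labels for ",
         nrow(matrix), " rows", call. = FALSE)
  ord <- order(labels, cell_barcodes)
  list(values = matrix[ord, , drop = FALSE],
       annotation = data.frame(barcode = cell_barcodes[ord],
                               clone = as.integer(labels[ord]),
                               stringsAsFactors = FALSE),
       order = ord)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cell feature values on a 2-D embedding
#'
#' Joins one feature's per-cell values (a VAF column, a normalized protein,
#' ...) to embedding coordinates, producing the tidy (x, y, value) table a
#' colour-overlay scatter plot is drawn from. Rendering is left to the
#' caller (any plotting front end takes this data.frame directly).
#'
#' @param embedding an `Embedding` (see [reduce_dim()]) or a 2-column
#'   coordinate matrix.
#' @param values numeric vector, one value per embedded cell, in cell order.
#' @param feature_name name attached to the `feature` column.
#' @return a data.frame with columns `x`, `y`, `value`, `feature`.
#' @export
feature_overlay <- function(embedding, values, feature_name = "feature") {
  coords <- if (inherits(embedding, "Embedding")) embedding$coords
            else as.matrix(embedding)
  if (ncol(coords) != 2L)
    stop("feature_overlay: embedding must have exactly 2 columns",
         call. = FALSE)
  if (length(values) != nrow(coords))
    stop("feature_overlay: ", length(values), " values for ",
         nrow(coords), " embedded cells", call. = FALSE)
  data.frame(x = coords[, 1], y = coords[, 2], value = as.numeric(values),
             feature = feature_name, stringsAsFactors = FALSE)
}
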