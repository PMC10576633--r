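#' Centred log-ratio normalization of antibody counts
#'
#' Antibody-capture counts are compositional: each droplet's total reflects
#' capture efficiency, not biology. The centred log-ratio (CLR) transform is
#' applied per cell across proteins, with a +1 pseudocount on the natural
#' log scale (the usual convention for antibody-derived tags):
#' `y(i,k) = ln(c(i,k) + 1) - mean_m ln(c(i,m) + 1)`.
#' Every transformed row sums to zero. Note that with the pseudocount the
#' transform is not exactly invariant to per-cell scaling of the raw counts;
#' that invariance only holds in the pseudocount-free limit.
#'
#' @param counts an `AssayMatrix` with `units = "count"` and at least two
#'   proteins, or a `MultiomicSample` whose `protein` assay should be
#'   normalized in place (sets `status$protein_normalized`).
#' @return the CLR-transformed `AssayMatrix` (`units = "normalized"`), or
#'   the updated sample.
#' @export
clr_normalize <- function(counts) {
  if (inherits(counts, "MultiomicSample")) {
    sample <- counts
    sample$protein <- clr_normalize(sample$protein)
    sample$status$protein_normalized <- TRUE
    return(sample)
  }
  validate_assay_matrix(counts)
  if (counts$units != "count")
    stop("clr_normalize: expected units 'count', got '", counts$units, "'",
         call. = FALSE)
  if (ncol(counts$values) < 2L)
    stop("clr_normalize: CLR needs at least 2 proteins", call. = FALSE)
  lg <- log1p(counts$values)
  y <- lg - rowMeans(lg)
  assay_matrix(y, counts$cell_barcodes, counts$feature_ids,
               units = "normalized")
}

#' Embed cells in two dimensions
#'
#' Projects normalized protein profiles (or any per-cell feature matrix)
#' onto two dimensions for visualization. `"pca"` is deterministic: the top
#' two principal components, with each component's sign fixed so that its
#' largest-magnitude loading is positive. `"umap"` (default, the usual
#' choice for antibody panels) and `"tsne"` are stochastic; the seed is set
#' before the call and recorded on the returned object.
#'
#' @param matrix an `AssayMatrix` (normally `units = "normalized"`; a
#'   warning is emitted for raw counts) or a `MultiomicSample` whose protein
#'   assay is embedded.
#' @param method one of `"umap"`, `"pca"`, `"tsne"`.
#' @param seed integer seed recorded on the embedding and applied before
#'   stochastic methods.
#' @return an object of class `Embedding` with `coords`
#'   (`n_cells x 2`, rownames = barcodes), `method`, `seed`.
#' @export
reduce_dim <- function(matrix, method = c("umap", "pca", "tsne"),
                       seed = 42L) {
  method <- match.arg(method)
  if (inherits(matrix, "MultiomicSample")) {
    if (!isTRUE(matrix$status$protein_normalized))
      warning("reduce_dim: protein assay has not been normalized",
              call. = FALSE)
    matrix <- matrix$protein
  }
  validate_assay_matrix(matrix)
  if (matrix$units == "count")
    warning("reduce_dim: embedding raw counts; normalize first?",
            call. = FALSE)
  X <- matrix$values
  n <- nrow(X)
  if (n < 3L)
    stop("reduce_dim: need at least 3 cells", call. = FALSE)

  coords <- switch(
    method,
    pca = {
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
      rot <- pc$rotation
      sc <- pc$x
      for (k in seq_len(ncol(rot))) {
        if (rot[which.max(abs(rot[, k])), k] < 0) {
          rot[, k] <- -rot[, k]
          sc[, k] <- -sc[, k]
        }
      }
      if (ncol(sc) < 2L)  # rank-1 input: pad a zero second axis
        sc <- cbind(sc, 0)
      sc[, 1:2, drop = FALSE]
    },
    umap = {
      set.seed(seed)
      uwot::umap(X, n_neighbors = min(15L, n - 1L), n_components = 2L,
                 n_threads = 1L, n_sgd_threads = 1L)
    },
    tsne = {
      set.seed(seed)
      perplexity <- max(1, min(30, floor((n - 1) / 3)))
      Rtsne::Rtsne(X, dims = 2L, perplexity = perplexity,
                   check_duplicates = FALSE, pca = ncol(X) > 50,
                   num_threads = 1L)$Y
    })
  coords <- as.matrix(coords)
  rownames(coords) <- matrix$cell_barcodes
  colnames(coords) <- paste0(toupper(method), 1:2)
  if (any(!is.finite(coords)))
    stop("reduce_dim: non-finite coordinates produced", call. = FALSE)
  structure(list(coords = coords, method = method, seed = as.integer(seed)),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells, method=%s, seed=%d\n",
              nrow(x$coords), x$method, x$seed))
  invisible(x)
}

# Vectorized two-sided Welch t-tests, one per column of x.
# Degenerate zero-variance pairs: equal means give t = 0, p = 1; unequal
# means give t = +-Inf, p = 0.
welch_tests <- function(x_target, x_rest) {
  n1 <- nrow(x_target)
  n2 <- nrow(x_rest)
  m1 <- colMeans(x_target)
  m2 <- colMeans(x_rest)
  v1 <- apply(x_target, 2L, stats::var)
  v2 <- apply(x_rest, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                   ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(is.infinite(t_stat), 0, 2 * stats::pt(-abs(t_stat), df))
  list(mean_target = m1, mean_rest = m2, t_statistic = t_stat,
       df = df, p_value = p)
}

#' One-vs-rest protein signature of a clone
#'
#' For each protein, tests whether its normalized expression in the target
#' clone differs from all other labelled cells using a two-sided Welch
#' (unequal-variance) t-test — clone sizes and variances differ grossly in
#' cell mixtures, so pooled variance is not assumed. P-values are adjusted
#' across the proteins with the Benjamini-Hochberg step-up procedure and the
#' table is sorted by adjusted p-value (ties: raw p-value, then protein id).
#' Noise cells (label 0) are excluded from both groups.
#'
#' @param matrix an `AssayMatrix` with `units = "normalized"` (CLR scale),
#'   or a `MultiomicSample` with normalized protein assay and clone labels.
#' @param labels integer clone labels (taken from the sample if omitted).
#' @param target_clone positive clone label to contrast against the rest.
#' @return a `SignatureTable` data.frame: `protein_id`, `mean_target`,
#'   `mean_rest`, `difference`, `t_statistic`, `p_value`, `p_adjusted`.
#' @export
find_signature <- function(matrix, labels = NULL, target_clone = 1L) {
  if (inherits(matrix, "MultiomicSample")) {
    sample <- matrix
    if (!isTRUE(sample$status$protein_normalized))
      stop("find_signature: run clr_normalize() first", call. = FALSE)
    if (is.null(labels)) labels <- sample$clone_labels
    if (is.null(labels))
      stop("find_signature: sample has no clone labels", call. = FALSE)
    matrix <- sample$protein
  }
  validate_assay_matrix(matrix)
  labels <- as.integer(labels)
  if (length(labels) != nrow(matrix$values))
    stop("find_signature: ", length(labels), " labels for ",
         nrow(matrix$values), " cells", call. = FALSE)
  target_clone <- as.integer(target_clone)
  in_target <- labels == target_clone & labels > 0L
  in_rest <- labels != target_clone & labels > 0L
  if (sum(in_target) < 2L)
    stop("find_signature: target clone ", target_clone, " has ",
         sum(in_target), " cells (need >= 2)", call. = FALSE)
  if (sum(in_rest) < 2L)
    stop("find_signature: only ", sum(in_rest),
         " cells outside the target clone (need >= 2)", call. = FALSE)

  tst <- welch_tests(matrix$values[in_target, , drop = FALSE],
                     matrix$values[in_rest, , drop = FALSE])
  tab <- data.frame(
    protein_id = matrix$feature_ids,
    mean_target = tst$mean_target,
    mean_rest = tst$mean_rest,
    difference = tst$mean_target - tst$mean_rest,
    t_statistic = tst$t_statistic,
    p_value = tst$p_value,
    p_adjusted = stats::p.adjust(tst$p_value, method = "BH"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_adjusted, tab$p_value, tab$protein_id), ]
  rownames(tab) <- NULL
  class(tab) <- c("SignatureTable", "data.frame")
  tab
}
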