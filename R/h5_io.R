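#' On-disk HDF5 layout for multiomic samples
#'
#' Path map for the multi-assay HDF5 layout (Tapestri Pipeline v2-style):
#' each assay lives under `assays/<name>` with 2-D layer datasets in
#' `layers/`, cell barcodes in `ra/barcode` and feature identifiers in
#' `ca/id`. Pass a modified copy to [read_h5()] to read dialects that use
#' different group names.
#'
#' @return a nested list mapping assay roles (`dna`, `cnv`, `protein`) to
#'   group names, layer names and annotation dataset names.
#' @export
h5_layout <- function() {
  list(
    root = "assays",
    dna = list(group = "dna_variants",
               layers = c("AF", "NGT", "GQ", "DP")),
    cnv = list(group = "dna_read_counts", layers = "read_counts"),
    protein = list(group = "protein_read_counts", layers = "read_counts"),
    barcode = "ra/barcode",
    feature = "ca/id",
    label = "ra/label")
}

h5_assay_paths <- function(layout, role) {
  g <- paste(layout$root, layout[[role]]$group, sep = "/")
  list(group = g,
       layers = paste(g, "layers", layout[[role]]$layers, sep = "/"),
       barcode = paste(g, layout$barcode, sep = "/"),
       feature = paste(g, layout$feature, sep = "/"))
}

h5_required_paths <- function(layout = h5_layout()) {
  unlist(lapply(c("dna", "cnv", "protein"), function(role) {
    p <- h5_assay_paths(layout, role)
    c(p$layers, p$barcode, p$feature)
  }), use.names = FALSE)
}

h5_exists <- function(contents, path) {
  path %in% contents
}

# Read one 2-D layer and orient it as cells x features. Orientation on disk
# varies by writer (h5py stores cells-first in C order, which rhdf5 reads
# transposed), so it is detected against the annotation lengths.
h5_read_layer <- function(path, dset, n_cells, n_features) {
  m <- rhdf5::h5read(path, dset)
  m <- as.matrix(m)
  d <- dim(m)
  if (identical(d, c(n_cells, n_features))) {
    m
  } else if (identical(d, c(n_features, n_cells))) {
    t(m)
  } else {
    stop("read_h5: layer '", dset, "' has shape ", d[1], "x", d[2],
         " but annotations imply ", n_cells, " cells x ", n_features,
         " features", call. = FALSE)
  }
}

h5_read_strings <- function(path, dset) {
  x <- as.character(rhdf5::h5read(path, dset))
  enc2utf8(x)
}

#' Read a multiomic sample from an HDF5 file
#'
#' Decodes the three assays (DNA variant layers AF/NGT/GQ/DP, CNV amplicon
#' counts, protein counts) from the multi-assay layout described in
#' [h5_layout()] and assembles them with [build_sample()] (intersecting and
#' lexicographically ordering barcodes). AF values outside `[0, 100]` are
#' clamped, with a message reporting how many entries were affected. If a
#' clone-label dataset is present under the DNA group it is restored via
#' [set_clone_labels()].
#'
#' @param path path to an HDF5 file.
#' @param layout path map, see [h5_layout()].
#' @param name sample name; defaults to the file name.
#' @return a `MultiomicSample`.
#' @export
read_h5 <- function(path, layout = h5_layout(),
                    name = sub("\\.h5$", "", basename(path))) {
  if (!file.exists(path))
    stop("read_h5: no such file: ", path, call. = FALSE)
  ls <- rhdf5::h5ls(path)
  contents <- file.path(sub("^/", "", sub("^/$", "", ls$group)), ls$name)
  contents <- sub("^/", "", contents)
  for (p in h5_required_paths(layout))
    if (!h5_exists(contents, p))
      stop("read_h5: required dataset missing from ", basename(path), ": /",
           p, call. = FALSE)

  read_role <- function(role) {
    p <- h5_assay_paths(layout, role)
    barcodes <- h5_read_strings(path, p$barcode)
    features <- h5_read_strings(path, p$feature)
    layers <- lapply(p$layers, h5_read_layer, path = path,
                     n_cells = length(barcodes),
                     n_features = length(features))
    names(layers) <- layout[[role]]$layers
    list(barcodes = barcodes, features = features, layers = layers)
  }

  dna_raw <- read_role("dna")
  af <- dna_raw$layers$AF
  n_clamped <- sum(af < 0 | af > 100)
  if (n_clamped > 0) {
    message("read_h5: clamped ", n_clamped, " AF entries to [0, 100]")
    af <- pmin(pmax(af, 0), 100)
  }
  dna <- dna_variant_assay(AF = af, NGT = dna_raw$layers$NGT,
                           GQ = dna_raw$layers$GQ, DP = dna_raw$layers$DP,
                           cell_barcodes = dna_raw$barcodes,
                           variant_ids = dna_raw$features)

  cnv_raw <- read_role("cnv")
  cnv <- assay_matrix(cnv_raw$layers$read_counts, cnv_raw$barcodes,
                      cnv_raw$features, units = "count")
  prot_raw <- read_role("protein")
  protein <- assay_matrix(prot_raw$layers$read_counts, prot_raw$barcodes,
                          prot_raw$features, units = "count")

  sample <- build_sample(dna, cnv, protein, name = name)

  label_path <- paste(layout$root, layout$dna$group, layout$label, sep = "/")
  if (h5_exists(contents, label_path)) {
    labels <- as.integer(rhdf5::h5read(path, label_path))
    names(labels) <- dna_raw$barcodes
    sample <- set_clone_labels(sample,
                               labels[sample$dna$cell_barcodes])
  }
  status_path <- paste(layout$root, "status", sep = "/")
  if (h5_exists(contents, status_path)) {
    st <- rhdf5::h5read(path, status_path)
    for (nm in names(sample$status))
      if (nm %in% names(st)) sample$status[[nm]] <- as.logical(st[[nm]])
  }
  sample
}

#' Write a multiomic sample to an HDF5 file
#'
#' Serializes a sample to the layout described in [h5_layout()] so that
#' `read_h5(write_h5(s, f))` reproduces `s` layer by layer. Clone labels and
#' status flags, when present, are stored alongside the assays.
#'
#' @param sample a `MultiomicSample`.
#' @param path output file path (overwritten if it exists).
#' @param layout path map, see [h5_layout()].
#' @return `path`, invisibly.
#' @export
write_h5 <- function(sample, path, layout = h5_layout()) {
  validate_sample(sample)
  if (n_cells(sample) == 0L)
    stop("write_h5: refusing to serialize a sample with 0 cells",
         call. = FALSE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, layout$root)

  write_role <- function(role, barcodes, features, layers) {
    p <- h5_assay_paths(layout, role)
    rhdf5::h5createGroup(path, p$group)
    rhdf5::h5createGroup(path, paste(p$group, "layers", sep = "/"))
    rhdf5::h5createGroup(path, paste(p$group, "ra", sep = "/"))
    rhdf5::h5createGroup(path, paste(p$group, "ca", sep = "/"))
    for (i in seq_along(p$layers))
      rhdf5::h5write(layers[[i]], path, p$layers[i])
    rhdf5::h5write(barcodes, path, p$barcode)
    rhdf5::h5write(features, path, p$feature)
  }

  write_role("dna", sample$dna$cell_barcodes, sample$dna$variant_ids,
             lapply(layout$dna$layers, function(l) sample$dna[[l]]))
  write_role("cnv", sample$cnv$cell_barcodes, sample$cnv$feature_ids,
             list(sample$cnv$values))
  write_role("protein", sample$protein$cell_barcodes,
             sample$protein$feature_ids, list(sample$protein$values))

  if (!is.null(sample$clone_labels))
    rhdf5::h5write(as.integer(sample$clone_labels), path,
                   paste(layout$root, layout$dna$group, layout$label,
                         sep = "/"))
  rhdf5::h5write(lapply(sample$status, as.integer), path,
                 paste(layout$root, "status", sep = "/"))
  invisible(path)
}

#' Validate that an HDF5 file conforms to the expected layout
#'
#' Walks the [h5_layout()] path map and checks that every required dataset
#' exists and that layer shapes agree with their annotations.
#'
#' @param path path to an HDF5 file.
#' @param layout path map, see [h5_layout()].
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_h5_layout <- function(path, layout = h5_layout()) {
  ls <- rhdf5::h5ls(path)
  contents <- sub("^/", "", file.path(sub("^/", "", ls$group), ls$name))
  for (p in h5_required_paths(layout))
    if (!h5_exists(contents, p))
      stop("layout violation: missing /", p, call. = FALSE)
  for (role in c("dna", "cnv", "protein")) {
    p <- h5_assay_paths(layout, role)
    nb <- length(rhdf5::h5read(path, p$barcode))
    nf <- length(rhdf5::h5read(path, p$feature))
    for (l in p$layers) {
      d <- dim(as.matrix(rhdf5::h5read(path, l)))
      if (!identical(d, c(nb, nf)) && !identical(d, c(nf, nb)))
        stop("layout violation: /", l, " shape ", d[1], "x", d[2],
             " vs ", nb, " barcodes / ", nf, " features", call. = FALSE)
    }
  }
  invisible(TRUE)
}
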