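Package: tapomics
Title: Integrative Analysis of Single-Cell DNA and Protein Multiomics from
    Targeted Amplicon Platforms
Version: 0.1.0
Authors@R:
    person("Dev", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reads, quality-filters and analyses multi-assay HDF5 output from
    droplet-based targeted single-cell multiomics platforms (Tapestri-style),
    where each cell carries a DNA variant-call assay (allele frequency,
    genotype, quality and depth layers), a CNV amplicon read-count assay and
    an antibody-capture protein count assay sharing one set of cell barcodes.
    Provides QC filtering of variant calls, density-based identification of
    cell clones from variant allele frequencies, per-amplicon ploidy
    estimation against a diploid reference clone, centred log-ratio
    normalization of protein counts, one-vs-rest differential protein
    testing with Benjamini-Hochberg correction, 2-D embeddings, a synthetic
    clone-structured data generator with ground truth, and a command-line
    pipeline chaining all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    uwot,
    Rtsne,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
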