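#' Configuration for the end-to-end pipeline
#'
#' @param input path to the input HDF5 sample.
#' @param out_prefix prefix for all output files.
#' @param qc [qc_thresholds()] for variant filtering.
#' @param cluster [cluster_params()] for clone identification.
#' @param reference_clone clone label taken as diploid for ploidy.
#' @param embed_method,embed_seed 2-D embedding method and seed.
#' @param target_clones clone label(s) to compute protein signatures for.
#' @param min_reference_cells minimum reference-clone size for ploidy.
#' @return an object of class `PipelineConfig`.
#' @export
pipeline_config <- function(input, out_prefix, qc = qc_thresholds(),
                            cluster = cluster_params(),
                            reference_clone = 1L,
                            embed_method = "umap", embed_seed = 42L,
                            target_clones = 1L,
                            min_reference_cells = 10L) {
  structure(list(input = input, out_prefix = out_prefix, qc = qc,
                 cluster = cluster,
                 reference_clone = as.integer(reference_clone),
                 embed_method = embed_method,
                 embed_seed = as.integer(embed_seed),
                 target_clones = as.integer(target_clones),
                 min_reference_cells = as.integer(min_reference_cells)),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Chains read -> variant QC filter -> clone identification -> CNV
#' normalization + ploidy -> protein CLR + embedding + signatures, writing:
#' `<prefix>.filtered.h5`, `<prefix>.filter_report.txt`,
#' `<prefix>.labels.tsv`, `<prefix>.clone_ploidy.tsv`,
#' `<prefix>.embedding.tsv`, `<prefix>.signature_clone<k>.tsv` and a run log
#' `<prefix>.log` recording every auto-chosen parameter (e.g. the DBSCAN
#' epsilon), so a run is reproducible from its log. A failure in any stage
#' aborts with the stage name; outputs of earlier stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of output paths plus the per-stage
#'   objects (`report`, `ploidy`, `embedding`, `signatures`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!file.exists(config$input))
    stop("run_pipeline: input file not found: ", config$input, call. = FALSE)
  prefix <- config$out_prefix
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  log_path <- paste0(prefix, ".log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("[stage] ", name)
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      message = function(m) {
        writeLines(paste0("  ", trimws(conditionMessage(m))), log_con)
        invokeRestart("muffleMessage")
      })
  }
  outputs <- list(log = log_path)

  log_line("input: ", config$input)
  log_line("qc thresholds: ",
           paste(names(config$qc), unlist(config$qc), sep = "=",
                 collapse = " "))
  log_line("cluster params: min_points=", config$cluster$min_points,
           " epsilon=", config$cluster$epsilon %||% "auto",
           " af_scale=", config$cluster$af_scale)
  log_line("reference_clone=", config$reference_clone,
           " embed=", config$embed_method, " embed_seed=", config$embed_seed,
           " target_clones=", paste(config$target_clones, collapse = ","))

  sample <- stage("read", read_h5(config$input))
  log_line("  read ", n_cells(sample), " cells")

  fr <- stage("filter", filter_variants(sample, config$qc))
  sample <- fr$sample
  outputs$filter_report <- paste0(prefix, ".filter_report.txt")
  writeLines(format(fr$report), outputs$filter_report)

  sample <- stage("clones", identify_clones(sample, config$cluster))
  outputs$labels <- paste0(prefix, ".labels.tsv")
  utils::write.table(
    data.frame(barcode = sample$dna$cell_barcodes,
               clone = sample$clone_labels),
    outputs$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs$filtered_h5 <- paste0(prefix, ".filtered.h5")
  stage("write_filtered", write_h5(sample, outputs$filtered_h5))

  ploidy <- stage("cnv", {
    sample <- normalize_cnv(sample)
    calculate_ploidy(sample, reference_clone = config$reference_clone,
                     min_reference_cells = config$min_reference_cells)
  })
  outputs$clone_ploidy <- paste0(prefix, ".clone_ploidy.tsv")
  utils::write.table(
    data.frame(clone = rownames(ploidy$clone_ploidy),
               ploidy$clone_ploidy, check.names = FALSE),
    outputs$clone_ploidy, sep = "\t", quote = FALSE, row.names = FALSE)

  emb <- stage("protein", {
    sample <- clr_normalize(sample)
    reduce_dim(sample, method = config$embed_method,
               seed = config$embed_seed)
  })
  outputs$embedding <- paste0(prefix, ".embedding.tsv")
  utils::write.table(
    data.frame(barcode = rownames(emb$coords), emb$coords,
               clone = sample$clone_labels, check.names = FALSE),
    outputs$embedding, sep = "\t", quote = FALSE, row.names = FALSE)

  signatures <- list()
  for (k in config$target_clones) {
    sig <- stage(paste0("signature_clone", k),
                 find_signature(sample, target_clone = k))
    p <- paste0(prefix, ".signature_clone", k, ".tsv")
    utils::write.table(sig, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[paste0("signature_clone", k)]] <- p
    signatures[[as.character(k)]] <- sig
  }

  log_line("[done] all stages complete")
  invisible(c(outputs, list(report = fr$report, ploidy = ploidy,
                            embedding = emb, signatures = signatures,
                            sample = sample)))
}
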