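#' Parse canonical variant identifiers
#'
#' Splits `"CHROM:POS:REF/ALT"` identifiers (1-based positions) into their
#' components.
#'
#' @param variant_ids character vector of identifiers.
#' @return a data.frame with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @export
parse_variant_ids <- function(variant_ids) {
  pattern <- "^([^:]+):([0-9]+):([^/]+)/(.+)$"
  ok <- grepl(pattern, variant_ids)
  if (!all(ok))
    stop("parse_variant_ids: malformed variant id(s): ",
         paste(utils::head(variant_ids[!ok], 5), collapse = ", "),
         call. = FALSE)
  data.frame(variant_id = variant_ids,
             chrom = sub(pattern, "\\1", variant_ids),
             pos = as.integer(sub(pattern, "\\2", variant_ids)),
             ref = sub(pattern, "\\3", variant_ids),
             alt = sub(pattern, "\\4", variant_ids),
             stringsAsFactors = FALSE)
}

#' Offline annotation provider backed by a lookup table
#'
#' An annotation provider is any function taking a character vector of
#' variant identifiers and returning a data.frame with one row per id, in
#' input order, with columns `gene`, `protein_change` and `function_class`
#' (NA where unknown). This constructor builds one from a tab-separated
#' lookup table with columns `variant_id`, `gene`, `protein_change`,
#' `function_class`. A provider querying a web annotation service is a
#' documented extension point with the same signature; it is never contacted
#' by this package's tests.
#'
#' @param table a data.frame, or the path of a TSV file to load. Defaults to
#'   the small synthetic lookup bundled with the package.
#' @return a provider function.
#' @export
tsv_annotation_provider <- function(table = NULL) {
  if (is.null(table))
    table <- system.file("extdata", "variant_annotations_synthetic.tsv",
                         package = "tapomics", mustWork = TRUE)
  if (is.character(table))
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  needed <- c("variant_id", "gene", "protein_change", "function_class")
  if (!all(needed %in% names(table)))
    stop("annotation table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  function(ids) {
    hit <- match(ids, table$variant_id)
    data.frame(gene = table$gene[hit],
               protein_change = table$protein_change[hit],
               function_class = table$function_class[hit],
               stringsAsFactors = FALSE)
  }
}

#' Annotate variants via a pluggable provider
#'
#' Validates and parses each identifier, queries the provider, and returns
#' one row per input id in input order. Identifiers the provider does not
#' know yield NA annotation fields, not an error.
#'
#' @param variant_ids character vector of `"CHROM:POS:REF/ALT"` ids.
#' @param provider a provider function (see [tsv_annotation_provider()]).
#' @return a data.frame with the parsed id columns plus the provider's
#'   annotation columns.
#' @export
annotate_variants <- function(variant_ids,
                              provider = tsv_annotation_provider()) {
  parsed <- parse_variant_ids(as.character(variant_ids))
  if (nrow(parsed) == 0L) {
    return(cbind(parsed,
                 data.frame(gene = character(0),
                            protein_change = character(0),
                            function_class = character(0))))
  }
  ann <- provider(parsed$variant_id)
  stopifnot(nrow(ann) == nrow(parsed))
  cbind(parsed, ann)
}
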