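# Tabular artifact I/O. All pipeline tables are written as TSV with a
# header row; readr quotes fields containing delimiters, so free-text
# columns (products with tabs, etc.) round-trip verbatim. List-columns
# (cargo gene lists, cluster tuples) are serialised as ";"-joined strings.

LIST_SEP <- ";"

#' Write a pipeline table as TSV
#'
#' @param records Data frame conforming to `schema`.
#' @param path Output file.
#' @param schema Character vector of required column names (order of the
#'   written file). List-columns are flattened with `";"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema = names(records)) {
  records <- as_tibble(records)
  miss <- setdiff(schema, names(records))
  if (length(miss) > 0) {
    abort(paste0("records are missing column(s): ", paste(miss, collapse = ", ")))
  }
  out <- records[, schema, drop = FALSE]
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- purrr::map_chr(out[[col]], paste, collapse = LIST_SEP)
    }
  }
  readr::write_tsv(out, path, quote = "needed", escape = "double",
                   progress = FALSE)
  invisible(path)
}

#' Read a pipeline table written by [write_table()]
#'
#' @param path TSV file with header.
#' @param list_cols Columns to expand back into list-columns (split on `";"`).
#' @return Tibble.
#' @export
read_table_file <- function(path, list_cols = character()) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(list_cols, names(out))) {
    out[[col]] <- purrr::map(out[[col]], function(x) {
      if (is.na(x) || !nzchar(x)) character() else strsplit(x, LIST_SEP, fixed = TRUE)[[1]]
    })
    names(out[[col]]) <- NULL
  }
  out
}

loci_schema <- function() {
  c("genome_id", "contig_id", "anchor", "closer", "cargo", "n_cargo",
    "span_bp", "element_strand")
}

#' Write / read a hotspot locus table
#'
#' @param loci Locus tibble from [extract_loci()].
#' @param path TSV file.
#' @return `path` (writer) or the locus tibble (reader).
#' @export
write_loci <- function(loci, path) write_table(loci, path, loci_schema())

#' @rdname write_loci
#' @export
read_loci <- function(path) read_table_file(path, list_cols = "cargo")

#' Write / read a cluster assignment table
#'
#' @param clusters Assignment tibble from [greedy_cluster()].
#' @param path TSV file.
#' @return `path` (writer) or the assignment tibble (reader).
#' @export
write_clusters <- function(clusters, path) {
  write_table(clusters, path, c("protein_id", "cluster_id", "representative_id"))
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) read_table_file(path)

#' Write / read an arrangement table
#'
#' @param table An `arrangement_table` from [tally_arrangements()] or
#'   [curate_arrangements()].
#' @param path TSV file.
#' @return `path` (writer) or a plain arrangement tibble (reader).
#' @export
write_arrangements <- function(table, path) {
  write_table(tidy(table), path,
              c("arrangement_id", "cluster_tuple", "count",
                "max_member_protein_aa", "locus_ids"))
}

#' @rdname write_arrangements
#' @export
read_arrangements <- function(path) {
  read_table_file(path, list_cols = c("cluster_tuple", "locus_ids"))
}
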