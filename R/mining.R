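# Anchor mining: find anchor-protein homologs by exact local alignment at a
# stringent E-value, then scan the strand-aware downstream gene window for a
# keyword-annotated closing gene and extract the cargo in between.

#' Mining configuration
#'
#' Parameters of the anchor search and locus extraction. Defaults follow the
#' published procedure: E-value threshold 1e-10, a 10-gene downstream
#' window, an "integrase" keyword for the closing gene, BLOSUM62 with
#' gap open 11 / extend 1, and fixed gapped Karlin-Altschul parameters
#' (lambda = 0.267, K = 0.041).
#'
#' @param evalue_max Maximum E-value for an anchor hit.
#' @param window Number of downstream genes scanned for the closing gene.
#' @param closer_keyword Case-insensitive substring identifying the closing
#'   gene's product annotation (`"integrase"` for the P4-like scenario,
#'   `"replication endonuclease"` for the P2-like one).
#' @param scan_both_directions Scan upstream as well as downstream.
#' @param matrix Substitution matrix name.
#' @param gap_open,gap_extend Affine gap penalties (cost of a gap of length
#'   k is `gap_open + k * gap_extend`).
#' @param karlin_lambda,karlin_K Karlin-Altschul parameters for gapped
#'   BLOSUM62 statistics.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(evalue_max = 1e-10, window = 10,
                          closer_keyword = "integrase",
                          scan_both_directions = FALSE,
                          matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          karlin_lambda = 0.267, karlin_K = 0.041) {
  stopifnot(evalue_max > 0, window >= 1, gap_open >= 0, gap_extend > 0,
            karlin_lambda > 0, karlin_K > 0, nzchar(closer_keyword))
  structure(list(evalue_max = evalue_max, window = as.integer(window),
                 closer_keyword = closer_keyword,
                 scan_both_directions = isTRUE(scan_both_directions),
                 matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K),
            class = "mining_config")
}

#' Find anchor-protein homologs in a corpus
#'
#' Aligns the anchor query against every protein of the corpus and keeps
#' genes whose E-value is at most `config$evalue_max`. The database size for
#' the E-value is the total residue count of the corpus, so the statistics
#' play the role of a blastp search against all proteins.
#'
#' @param corpus List of [genome_annotation()] objects.
#' @param query Anchor protein (single amino-acid string).
#' @param config A [mining_config()].
#' @return Tibble of hits sorted by (genome_id, contig_id, gene_index):
#'   `genome_id`, `contig_id`, `gene_index`, `feature_id`, `raw_score`,
#'   `bit_score`, `evalue`, `query_cov`, `target_cov`, `identity`.
#' @export
find_anchor_hits <- function(corpus, query, config = mining_config()) {
  stopifnot(length(corpus) > 0)
  genes <- corpus_genes(corpus)
  if (nrow(genes) == 0) return(anchor_hits_empty())
  db <- corpus_residues(corpus)
  cutoff <- score_cutoff(nchar(query), db, config)
  scores <- sw_scores(query, genes$protein, config)
  keep <- which(scores >= cutoff)
  if (length(keep) == 0) return(anchor_hits_empty())
  hits <- purrr::map_dfr(keep, function(i) {
    aln <- local_align(query, genes$protein[i], config, db_residues = db,
                       target_id = genes$feature_id[i])
    bind_cols(genes[i, c("genome_id", "contig_id", "gene_index", "feature_id")],
              aln[, c("raw_score", "bit_score", "evalue",
                      "query_cov", "target_cov", "identity")])
  })
  hits <- hits[hits$evalue <= config$evalue_max, , drop = FALSE]
  hits[order(hits$genome_id, hits$contig_id, hits$gene_index), ]
}

anchor_hits_empty <- function() {
  tibble(genome_id = character(), contig_id = character(),
         gene_index = integer(), feature_id = character(),
         raw_score = numeric(), bit_score = numeric(), evalue = numeric(),
         query_cov = numeric(), target_cov = numeric(), identity = numeric())
}

#' Locate the closing gene downstream of an anchor
#'
#' Scans gene offsets `1..window` downstream of the anchor, where
#' "downstream" follows the anchor gene's strand: increasing gene index for
#' a `+` anchor, decreasing for `-`. With `scan_both_directions` both sides
#' are scanned and the nearest match wins (downstream preferred on ties).
#' Returns the gene index of the nearest gene whose product contains the
#' keyword (case-insensitively), or `NA` if absent; attribute `truncated`
#' records whether the window ran off the contig end before completing.
#'
#' @param contig_genes Gene tibble of one contig, in gene-index order
#'   (columns `strand`, `product` used).
#' @param anchor_index Gene index of the anchor on this contig.
#' @param config A [mining_config()].
#' @return Integer gene index or `NA`, with attribute `truncated`.
#' @export
find_closer_gene <- function(contig_genes, anchor_index,
                             config = mining_config()) {
  n <- nrow(contig_genes)
  stopifnot(anchor_index >= 1, anchor_index <= n)
  step_down <- if (contig_genes$strand[anchor_index] == "+") 1L else -1L
  dirs <- if (config$scan_both_directions) c(step_down, -step_down) else step_down
  found <- NA_integer_
  truncated <- FALSE
  for (offset in seq_len(config$window)) {
    for (d in dirs) {
      idx <- anchor_index + d * offset
      if (idx < 1 || idx > n) {
        if (d == step_down) truncated <- TRUE
        next
      }
      if (grepl(config$closer_keyword, contig_genes$product[idx],
                ignore.case = TRUE, fixed = FALSE)) {
        found <- idx
        break
      }
    }
    if (!is.na(found)) break
  }
  structure(found, truncated = truncated && is.na(found))
}

#' Extract hotspot loci from anchor hits
#'
#' For each anchor hit, searches the downstream window for the closing gene
#' and, when found on the same contig, emits one locus with its cargo genes
#' listed in anchor-to-closer order. Hits are otherwise logged as discarded:
#' reason `"contig_end"` when the window ran off the contig end (the
#' cross-contig discard rule) and `"no_closer"` when a full window contained
#' no keyword gene. Duplicate loci (same anchor and closer feature) are
#' deduplicated.
#'
#' @param corpus List of [genome_annotation()] objects.
#' @param hits Tibble from [find_anchor_hits()].
#' @param config A [mining_config()].
#' @return A list with `loci` (tibble: `genome_id`, `contig_id`, `anchor`,
#'   `closer`, `cargo` list-column of feature ids, `n_cargo`, `span_bp`,
#'   `element_strand`) and `discarded` (tibble: `genome_id`, `contig_id`,
#'   `feature_id`, `reason`).
#' @export
extract_loci <- function(corpus, hits, config = mining_config()) {
  genes_by_genome <- setNames(lapply(corpus, function(g) g$genes),
                              purrr::map_chr(corpus, "genome_id"))
  loci <- list()
  discarded <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    genes <- genes_by_genome[[h$genome_id]]
    cg <- genes[genes$contig_id == h$contig_id, , drop = FALSE]
    a_idx <- h$gene_index
    res <- find_closer_gene(cg, a_idx, config)
    if (is.na(res)) {
      reason <- if (isTRUE(attr(res, "truncated"))) "contig_end" else "no_closer"
      discarded[[length(discarded) + 1L]] <- tibble(
        genome_id = h$genome_id, contig_id = h$contig_id,
        feature_id = h$feature_id, reason = reason)
      next
    }
    c_idx <- as.integer(res)
    between <- if (a_idx < c_idx) seq(a_idx + 1L, length.out = c_idx - a_idx - 1L)
               else seq(a_idx - 1L, length.out = a_idx - c_idx - 1L, by = -1L)
    anchor_strand <- cg$strand[a_idx]
    span <- if (a_idx < c_idx) cg$start[c_idx] - cg$end[a_idx] - 1L
            else cg$start[a_idx] - cg$end[c_idx] - 1L
    loci[[length(loci) + 1L]] <- tibble(
      genome_id = h$genome_id, contig_id = h$contig_id,
      anchor = cg$feature_id[a_idx], closer = cg$feature_id[c_idx],
      cargo = list(cg$feature_id[between]),
      n_cargo = length(between),
      span_bp = max(0L, span),
      element_strand = anchor_strand)
  }
  loci <- if (length(loci) > 0) bind_rows(loci) else empty_loci_table()
  if (nrow(loci) > 0) {
    loci <- loci[!duplicated(loci[, c("anchor", "closer")]), , drop = FALSE]
  }
  discarded <- if (length(discarded) > 0) bind_rows(discarded) else
    tibble(genome_id = character(), contig_id = character(),
           feature_id = character(), reason = character())
  list(loci = loci, discarded = discarded)
}

empty_loci_table <- function() {
  tibble(genome_id = character(), contig_id = character(),
         anchor = character(), closer = character(), cargo = list(),
         n_cargo = integer(), span_bp = integer(), element_strand = character())
}
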