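# The in-memory representation of an annotated genome: a contig table plus a
# gene table under one coordinate convention (1-based, inclusive, GenBank
# style; GFF3 needs no shift). Gene order within a contig is by start
# coordinate regardless of strand, and "gene index" elsewhere in the package
# always refers to this order.

#' Construct a genome annotation
#'
#' @param genome_id Genome identifier.
#' @param contigs Tibble with columns `contig_id`, `length` (bp) and
#'   optionally `sequence` (nucleotide string, may be `NA`).
#' @param genes Tibble with columns `feature_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `protein`, `product`.
#' @param source One of `"genbank"`, `"gff3"`, `"synthetic"`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, contigs, genes,
                              source = c("synthetic", "genbank", "gff3")) {
  source <- match.arg(source)
  contigs <- as_tibble(contigs)
  genes <- as_tibble(genes)
  if (!"sequence" %in% names(contigs)) contigs$sequence <- NA_character_
  contigs <- contigs[, c("contig_id", "length", "sequence")]
  contigs[] <- lapply(contigs, unname)
  need <- c("feature_id", "contig_id", "start", "end", "strand",
            "protein", "product")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    abort(paste0("gene table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  genes <- genes[, need]
  obj <- structure(list(genome_id = genome_id,
                        contigs = contigs,
                        genes = genes,
                        source = source),
                   class = "genome_annotation")
  validate_genome_annotation(obj)
}

validate_genome_annotation <- function(x) {
  genes <- x$genes
  contigs <- x$contigs
  if (anyDuplicated(contigs$contig_id)) abort("duplicate contig_id")
  if (nrow(genes) > 0) {
    if (anyDuplicated(genes$feature_id)) {
      abort(paste0("duplicate feature_id: ",
                   genes$feature_id[duplicated(genes$feature_id)][1]))
    }
    if (any(genes$start > genes$end)) abort("gene with start > end")
    if (any(!genes$strand %in% c("+", "-"))) abort("strand must be + or -")
    if (any(nchar(genes$protein) < 1)) abort("empty protein sequence")
    if (any(!genes$contig_id %in% contigs$contig_id)) {
      bad <- setdiff(unique(genes$contig_id), contigs$contig_id)
      abort(paste0("gene references unknown contig: ", bad[1]))
    }
    len <- setNames(contigs$length, contigs$contig_id)
    if (any(genes$start < 1 | genes$end > len[genes$contig_id])) {
      abort("gene coordinates outside contig bounds")
    }
    # canonical order: contig (in contig-table order), then start
    ord <- order(match(genes$contig_id, contigs$contig_id), genes$start,
                 genes$end, genes$feature_id)
    x$genes <- genes[ord, ]
  }
  x
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s (%s): %d contig(s), %d gene(s)\n",
              x$genome_id, x$source, nrow(x$contigs), nrow(x$genes)))
  invisible(x)
}

#' Flatten a corpus into one gene table
#'
#' @param corpus A list of [genome_annotation()] objects.
#' @return Tibble with one row per gene: `genome_id`, `contig_id`,
#'   `gene_index` (order along the contig), `feature_id`, `start`, `end`,
#'   `strand`, `protein`, `product`.
#' @export
corpus_genes <- function(corpus) {
  stopifnot(is.list(corpus))
  purrr::map_dfr(corpus, function(g) {
    if (nrow(g$genes) == 0) return(tibble())
    g$genes |>
      group_by(.data$contig_id) |>
      mutate(gene_index = row_number()) |>
      ungroup() |>
      mutate(genome_id = g$genome_id, .before = 1)
  })
}

#' Total amino-acid residue count of a corpus
#'
#' Used as the effective database size for Karlin-Altschul E-values.
#' @param corpus A list of [genome_annotation()] objects.
#' @return Integer residue count.
#' @export
corpus_residues <- function(corpus) {
  sum(purrr::map_dbl(corpus, ~ sum(nchar(.x$genes$protein))))
}

#' Reverse-complement every contig of a genome annotation
#'
#' Re-derives the annotation in the flipped coordinate system: a gene at
#' `[s, e]` on a contig of length `L` maps to `[L - e + 1, L - s + 1]` with
#' its strand toggled; protein sequences are unchanged. Used to test that
#' hotspot mining is orientation-invariant.
#'
#' @param genome A [genome_annotation()].
#' @return A new `genome_annotation`.
#' @export
revcomp_genome <- function(genome) {
  len <- setNames(genome$contigs$length, genome$contigs$contig_id)
  genes <- genome$genes
  if (nrow(genes) > 0) {
    L <- len[genes$contig_id]
    new_start <- L - genes$end + 1
    new_end <- L - genes$start + 1
    genes$start <- unname(new_start)
    genes$end <- unname(new_end)
    genes$strand <- ifelse(genes$strand == "+", "-", "+")
  }
  contigs <- genome$contigs
  has_seq <- !is.na(contigs$sequence)
  if (any(has_seq)) {
    contigs$sequence[has_seq] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(contigs$sequence[has_seq])))
  }
  genome_annotation(genome$genome_id, contigs, genes, source = genome$source)
}

#' Reverse-complement every genome of a corpus
#'
#' @param corpus A list of [genome_annotation()] objects.
#' @return A list of flipped `genome_annotation` objects.
#' @export
revcomp_corpus <- function(corpus) {
  lapply(corpus, revcomp_genome)
}
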