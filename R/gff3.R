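# GFF3 + genomic FASTA ingestion. GFF3 coordinates are 1-based inclusive,
# the same convention used internally, so no shift is applied. Multi-row CDS
# sharing an ID are treated as one joined CDS (exons concatenated in
# annotation order before translation).

#' Read an annotated genome from GFF3 + genomic FASTA
#'
#' Produces the same semantic content as [read_genbank()] for an equivalent
#' locus: one gene per CDS (rows sharing an `ID` are merged into one joined
#' CDS), proteins translated from the nucleotide spans with genetic code 11,
#' honouring strand and the `phase` column of the first segment.
#'
#' @param gff GFF3 file with CDS rows.
#' @param fasta Genomic FASTA whose sequence names match the GFF3 seqids.
#' @param genome_id Genome identifier; default is the GFF3 file name.
#' @return A [genome_annotation()].
#' @export
read_gff3_fasta <- function(gff, fasta, genome_id = NULL) {
  if (is.null(genome_id)) genome_id <- sub("\\.gff3?$", "", basename(gff))
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff)
  df <- as.data.frame(gr)
  df <- df[df$type == "CDS", , drop = FALSE]
  contigs <- tibble(contig_id = names(seqs),
                    length = Biostrings::width(seqs),
                    sequence = as.character(seqs))
  if (nrow(df) == 0) {
    return(genome_annotation(genome_id, contigs, empty_gene_table(),
                             source = "gff3"))
  }
  bad <- setdiff(unique(as.character(df$seqnames)), names(seqs))
  if (length(bad) > 0) {
    abort(paste0("CDS references contig(s) absent from FASTA: ",
                 paste(bad, collapse = ", ")))
  }
  ids <- as.character(df$ID)
  if (all(is.na(ids) | !nzchar(ids))) ids <- sprintf("cds%04d", seq_len(nrow(df)))
  df$.cds_id <- ids
  gene_rows <- purrr::map_dfr(split(seq_len(nrow(df)), df$.cds_id), function(ix) {
    part <- df[ix, , drop = FALSE]
    part <- part[order(part$start), , drop = FALSE]
    contig <- as.character(part$seqnames[1])
    strand <- as.character(part$strand[1])
    if (!strand %in% c("+", "-")) strand <- "+"
    # first segment in translation order carries the phase
    first <- if (strand == "+") 1L else nrow(part)
    phase <- suppressWarnings(as.integer(as.character(part$phase[first])))
    if (is.na(phase)) phase <- 0L
    loc <- list(spans = tibble(start = part$start, end = part$end),
                complement = strand == "-")
    protein <- translate_cds(as.character(seqs[[contig]]), loc,
                             codon_start = phase + 1L)
    product <- ""
    for (col in c("product", "Name", "Note")) {
      if (col %in% names(part) && !is.na(part[[col]][1])) {
        product <- as.character(part[[col]][1]); break
      }
    }
    fid <- part$.cds_id[1]
    if ("locus_tag" %in% names(part) && !is.na(part$locus_tag[1])) {
      fid <- as.character(part$locus_tag[1])
    }
    tibble(feature_id = fid, contig_id = contig,
           start = min(part$start), end = max(part$end),
           strand = strand, protein = protein, product = product)
  })
  gene_rows <- gene_rows[!is.na(gene_rows$protein) & nzchar(gene_rows$protein), ]
  genome_annotation(genome_id, contigs, gene_rows, source = "gff3")
}
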