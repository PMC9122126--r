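# Small genome fixtures built in code: a two-contig toy locus emitted both
# as GenBank and as GFF3+FASTA, used for reader-equivalence tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-cargo loci whose cluster labels repeat per the given counts,
# e.g. c(A = 7, B = 5) -> 12 loci tallying to arrangements (A):7, (B):5
single_cluster_table <- function(counts) {
  labels <- rep(names(counts), counts)
  n <- length(labels)
  loci <- tibble::tibble(
    genome_id = sprintf("g%02d", seq_len(n)),
    contig_id = sprintf("g%02d_c1", seq_len(n)),
    anchor = sprintf("a%02d", seq_len(n)),
    closer = sprintf("z%02d", seq_len(n)),
    cargo = as.list(sprintf("p%02d", seq_len(n))),
    n_cargo = 1L, span_bp = 500L, element_strand = "+")
  assign <- setNames(labels, sprintf("p%02d", seq_len(n)))
  tally_arrangements(loci, assign)
}

CODON <- c(M = "ATG", K = "AAA", L = "CTG", V = "GTT", N = "AAT", E = "GAA",
           R = "CGT", F = "TTT", G = "GGT", A = "GCT", D = "GAT", S = "TCT",
           T = "ACT", I = "ATT", P = "CCT", Q = "CAA", H = "CAT", W = "TGG",
           Y = "TAT", C = "TGT")

encode_cds <- function(protein) {
  paste0(paste(CODON[strsplit(protein, "", fixed = TRUE)[[1]]],
               collapse = ""), "TAA")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Layout: ctg1 carries geneA (+, 11 aa) and geneB (-, 9 aa, product with an
# "integrase" keyword); ctg2 carries geneC (+, 8 aa). Returns coordinates,
# sequences, and writers for both encodings.
toy_locus_fixture <- function() {
  protA <- "MKLVNERFGA"
  protB <- "MDEHWYQTS"
  protC <- "MGGPAIRC"
  cdsA <- encode_cds(protA)                      # on + strand
  cdsB <- encode_cds(protB)                      # placed as revcomp on ctg1
  cdsC <- encode_cds(protC)
  pad1 <- strrep("A", 9)
  pad2 <- strrep("C", 12)
  pad3 <- strrep("G", 7)
  ctg1 <- paste0(pad1, cdsA, pad2, revcomp_chr(cdsB), pad3)
  startA <- nchar(pad1) + 1L
  endA <- startA + nchar(cdsA) - 1L
  startB <- endA + nchar(pad2) + 1L
  endB <- startB + nchar(cdsB) - 1L
  ctg2 <- paste0(strrep("T", 5), cdsC, strrep("A", 6))
  startC <- 6L
  endC <- startC + nchar(cdsC) - 1L
  genes <- tibble::tibble(
    feature_id = c("geneA", "geneB", "geneC"),
    contig_id = c("ctg1", "ctg1", "ctg2"),
    start = c(startA, startB, startC),
    end = c(endA, endB, endC),
    strand = c("+", "-", "+"),
    protein = c(protA, protB, protC),
    product = c("alpha subunit", "tyrosine integrase", "gamma protein"))
  list(genes = genes,
       contigs = tibble::tibble(contig_id = c("ctg1", "ctg2"),
                                length = c(nchar(ctg1), nchar(ctg2)),
                                sequence = c(ctg1, ctg2)))
}

write_toy_genbank <- function(fx, path, with_translation = TRUE) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(fx$contigs))) {
    cid <- fx$contigs$contig_id[i]
    seqnt <- fx$contigs$sequence[i]
    writeLines(sprintf("LOCUS       %s %d bp DNA linear PHG 01-JAN-1980",
                       cid, nchar(seqnt)), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    g <- fx$genes[fx$genes$contig_id == cid, ]
    for (k in seq_len(nrow(g))) {
      span <- sprintf("%d..%d", g$start[k], g$end[k])
      if (g$strand[k] == "-") span <- sprintf("complement(%s)", span)
      writeLines(sprintf("     CDS             %s", span), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", g$feature_id[k]), con)
      writeLines(sprintf("                     /product=\"%s\"", g$product[k]), con)
      if (with_translation) {
        writeLines(sprintf("                     /translation=\"%s\"", g$protein[k]), con)
      }
    }
    writeLines("ORIGIN", con)
    s <- tolower(seqnt)
    for (p in seq(1, nchar(s), by = 60)) {
      writeLines(sprintf("%9d %s", p, substr(s, p, min(p + 59, nchar(s)))), con)
    }
    writeLines("//", con)
  }
  path
}

write_toy_gff3_fasta <- function(fx, gff_path, fasta_path) {
  rows <- c("##gff-version 3")
  for (k in seq_len(nrow(fx$genes))) {
    g <- fx$genes[k, ]
    rows <- c(rows, sprintf(
      "%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
      g$contig_id, g$start, g$end, g$strand, g$feature_id, g$product))
  }
  writeLines(rows, gff_path)
  writeLines(unlist(lapply(seq_len(nrow(fx$contigs)), function(i) {
    c(paste0(">", fx$contigs$contig_id[i]), fx$contigs$sequence[i])
  })), fasta_path)
  invisible(NULL)
}
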