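# GenBank / GFF3 ingestion, coordinate conventions, translation, and
# table round trips.

test_that("GenBank CDS are parsed with strand-aware translation", {
  fx <- toy_locus_fixture()
  gb <- withr::local_tempfile(fileext = ".gbk")
  write_toy_genbank(fx, gb, with_translation = FALSE)
  ann <- read_genbank(gb, genome_id = "toy")

  expect_equal(nrow(ann$contigs), 2)
  expect_equal(nrow(ann$genes), 3)
  expect_equal(attr(ann, "n_skipped"), 0L)

  g <- ann$genes[match(fx$genes$feature_id, ann$genes$feature_id), ]
  expect_equal(g$start, fx$genes$start)
  expect_equal(g$end, fx$genes$end)
  expect_equal(g$strand, fx$genes$strand)
  expect_equal(g$product, fx$genes$product)

  # minus-strand protein equals translation of the reverse complement
  # (independent Biostrings oracle on the raw span)
  span <- substr(fx$contigs$sequence[1], fx$genes$start[2], fx$genes$end[2])
  oracle <- as.character(Biostrings::translate(
    Biostrings::reverseComplement(Biostrings::DNAString(span)),
    genetic.code = Biostrings::getGeneticCode("11")))
  expect_equal(paste0(g$protein[2], "*"), oracle)
  expect_equal(g$protein, fx$genes$protein)
})

test_that("a contig with no CDS yields an empty gene list, not an error", {
  gb <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       bare 500 bp DNA linear PHG 01-JAN-1980",
               "FEATURES             Location/Qualifiers",
               "     source          1..500",
               "//"), gb)
  ann <- read_genbank(gb)
  expect_equal(nrow(ann$contigs), 1)
  expect_equal(nrow(ann$genes), 0)
})

test_that("GenBank and GFF3+FASTA encodings of one locus are equivalent", {
  fx <- toy_locus_fixture()
  gb <- withr::local_tempfile(fileext = ".gbk")
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fna")
  write_toy_genbank(fx, gb)
  write_toy_gff3_fasta(fx, gff, fa)
  a <- read_genbank(gb, genome_id = "toy")
  b <- read_gff3_fasta(gff, fa, genome_id = "toy")

  expect_equal(as.data.frame(a$genes), as.data.frame(b$genes))
  expect_equal(a$contigs$length, b$contigs$length)
  expect_equal(toupper(a$contigs$sequence), toupper(b$contigs$sequence))
  # genes distributed over both contigs
  expect_equal(sort(unique(b$genes$contig_id)), c("ctg1", "ctg2"))
})

test_that("GFF3 phase offsets the translation start", {
  fx <- toy_locus_fixture()
  # shift geneA: prepend one pad base into the CDS span and set phase=1
  g <- fx$genes[1, ]
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fna")
  writeLines(c("##gff-version 3",
               sprintf("ctg1\ttoy\tCDS\t%d\t%d\t.\t+\t1\tID=geneA;product=x",
                       g$start - 1L, g$end)), gff)
  writeLines(c(">ctg1", fx$contigs$sequence[1]), fa)
  ann <- read_gff3_fasta(gff, fa)
  expect_equal(ann$genes$protein[1], g$protein)
})

test_that("GFF3 referencing a contig missing from the FASTA errors by ID", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fna")
  writeLines(c("##gff-version 3",
               "ghost\ttoy\tCDS\t1\t9\t.\t+\t0\tID=g1"), gff)
  writeLines(c(">real", "ATGAAATAA"), fa)
  expect_error(read_gff3_fasta(gff, fa), "ghost")
})

test_that("synthetic genomes round-trip through GenBank exactly", {
  sim <- generate_corpus(corpus_spec(n_genomes = 4, hotspot_prevalence = 1,
                                     contig_break_prob = 0.5, seed = 11))
  dir <- withr::local_tempdir()
  write_corpus_genbank(sim$corpus, dir)
  back <- read_corpus_genbank(dir)
  for (gid in names(sim$corpus)) {
    a <- sim$corpus[[gid]]$genes
    b <- back[[gid]]$genes
    expect_equal(as.data.frame(a), as.data.frame(b), info = gid)
    expect_equal(sim$corpus[[gid]]$contigs$length, back[[gid]]$contigs$length)
  }
})

test_that("write_table round-trips rows, empties, and embedded tabs", {
  loci <- tibble::tibble(
    genome_id = c("g1", "g2", "g3"), contig_id = c("c1", "c1", "c2"),
    anchor = c("a1", "a2", "a3"), closer = c("z1", "z2", "z3"),
    cargo = list(c("x", "y"), character(), "w"),
    n_cargo = c(2L, 0L, 1L), span_bp = c(1500L, 40L, 900L),
    element_strand = c("+", "-", "+"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_loci(loci, path)
  back <- read_loci(path)
  expect_equal(as.data.frame(back), as.data.frame(loci))

  # empty record list -> header-only file
  write_loci(loci[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_loci(path)), 0L)

  # free text containing a literal tab is escaped and recovered verbatim
  tab_tbl <- tibble::tibble(feature_id = "f1", product = "weird\tproduct")
  write_table(tab_tbl, path)
  expect_equal(read_table_file(path)$product, "weird\tproduct")

  # schema mismatch names the missing column
  expect_error(write_table(tab_tbl[, "feature_id"], path,
                           schema = c("feature_id", "product")), "product")
})
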