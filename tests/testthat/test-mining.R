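# Anchor search specificity/sensitivity, the downstream-window scan, and
# locus extraction with the cross-contig discard rule.

make_contig_genes <- function(products, strands = "+") {
  n <- length(products)
  strands <- rep_len(strands, n)
  tibble::tibble(feature_id = sprintf("f%02d", seq_len(n)),
                 contig_id = "c1",
                 start = seq_len(n) * 1000L,
                 end = seq_len(n) * 1000L + 500L,
                 strand = strands,
                 protein = strrep("A", 50),
                 product = products)
}

test_that("an exact anchor copy among decoys is the only hit", {
  set.seed(301)
  anchor <- synthetic_anchor_protein()
  corpus <- lapply(1:10, function(g) {
    genes <- purrr::map_dfr(1:12, function(i) {
      tibble::tibble(feature_id = sprintf("g%02d_f%02d", g, i),
                     contig_id = sprintf("g%02d_c1", g),
                     start = i * 1000L, end = i * 1000L + 700L,
                     strand = "+", protein = random_protein(180),
                     product = "hypothetical protein")
    })
    if (g == 4) genes$protein[5] <- unname(anchor)
    genome_annotation(sprintf("g%02d", g),
                      tibble::tibble(contig_id = sprintf("g%02d_c1", g),
                                     length = 15000L),
                      genes)
  })
  hits <- find_anchor_hits(corpus, unname(anchor))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$feature_id, "g04_f05")
  expect_lt(hits$evalue, 1e-10)

  # pure decoys: zero hits
  corpus2 <- corpus[-4]
  expect_equal(nrow(find_anchor_hits(corpus2, unname(anchor))), 0)
})

test_that("E-value threshold behaves monotonically on hit sets", {
  sim <- generate_corpus(corpus_spec(n_genomes = 20, seed = 5))
  loose <- find_anchor_hits(sim$corpus, synthetic_anchor_protein(),
                            mining_config(evalue_max = 1e-3))
  strict <- find_anchor_hits(sim$corpus, synthetic_anchor_protein(),
                             mining_config(evalue_max = 1e-30))
  default <- find_anchor_hits(sim$corpus, synthetic_anchor_protein())
  expect_true(all(strict$feature_id %in% default$feature_id))
  expect_true(all(default$feature_id %in% loose$feature_id))
})

test_that("the downstream window is strand-aware and boundary-inclusive", {
  cfg <- mining_config()
  # keyword at offset 10 downstream of a + anchor: found
  g <- make_contig_genes(c("anchor here", rep("hypothetical", 9), "integrase"))
  expect_equal(as.integer(find_closer_gene(g, 1, cfg)), 11L)
  # keyword at offset 11 only: out of window
  g <- make_contig_genes(c("anchor here", rep("hypothetical", 10), "integrase"))
  expect_true(is.na(find_closer_gene(g, 1, cfg)))
  # minus-strand anchor scans decreasing indexes
  g <- make_contig_genes(c("phage integrase", "hypothetical", "hypothetical",
                           "anchor here"), strands = c("+", "+", "+", "-"))
  expect_equal(as.integer(find_closer_gene(g, 4, cfg)), 1L)
  # keyword match is case-insensitive
  g <- make_contig_genes(c("anchor", "Tyrosine INTEGRASE"))
  expect_equal(as.integer(find_closer_gene(g, 1, cfg)), 2L)
  # truncation flag when the window runs off the contig without a match
  g <- make_contig_genes(c("anchor", "hypothetical"))
  res <- find_closer_gene(g, 1, cfg)
  expect_true(is.na(res))
  expect_true(attr(res, "truncated"))
})

test_that("extract_loci yields ordered cargo, spans, and discard reasons", {
  sim <- generate_corpus(corpus_spec(n_genomes = 40, hotspot_prevalence = 1,
                                     contig_break_prob = 0, seed = 9))
  hits <- find_anchor_hits(sim$corpus, synthetic_anchor_protein())
  ext <- extract_loci(sim$corpus, hits)
  expect_equal(nrow(ext$loci), nrow(sim$ledger$loci))
  expect_equal(nrow(ext$discarded), 0)

  # cargo is reported anchor-to-closer even for flipped elements
  led <- sim$ledger$loci
  for (i in seq_len(nrow(led))) {
    rec <- ext$loci[ext$loci$anchor == led$anchor_id[i], ]
    expect_equal(rec$cargo[[1]], led$cargo_ids[[i]])
    expect_equal(rec$element_strand, if (led$flipped[i]) "-" else "+")
  }
  # empty cargo loci carry an empty vector and a small span
  empty <- ext$loci[ext$loci$n_cargo == 0, ]
  if (nrow(empty) > 0) expect_true(all(lengths(empty$cargo) == 0))

  # spans are the anchor-to-closer intergenic stretch, bounded by the
  # planted geometry (gaps 10-200 bp, cargo genes <= 6)
  expect_true(all(ext$loci$span_bp >= 10))
  expect_true(all(ext$loci$span_bp <= 12000))
})

test_that("loci split across contigs are discarded with reason contig_end", {
  sim <- generate_corpus(corpus_spec(n_genomes = 25, hotspot_prevalence = 1,
                                     contig_break_prob = 1, seed = 13))
  hits <- find_anchor_hits(sim$corpus, synthetic_anchor_protein())
  ext <- extract_loci(sim$corpus, hits)
  expect_equal(nrow(ext$loci), 0)
  expect_setequal(ext$discarded$feature_id, sim$ledger$loci$anchor_id)
  expect_true(all(ext$discarded$reason == "contig_end"))
  expect_true(all(sim$ledger$loci$split))
})

test_that("mining is invariant under reverse-complementing every contig", {
  sim <- generate_corpus(corpus_spec(n_genomes = 25, hotspot_prevalence = 0.8,
                                     contig_break_prob = 0, seed = 21))
  fwd <- extract_loci(sim$corpus,
                      find_anchor_hits(sim$corpus, synthetic_anchor_protein()))
  rc <- revcomp_corpus(sim$corpus)
  rev <- extract_loci(rc, find_anchor_hits(rc, synthetic_anchor_protein()))
  f <- fwd$loci[order(fwd$loci$anchor), ]
  r <- rev$loci[order(rev$loci$anchor), ]
  expect_equal(f$anchor, r$anchor)
  expect_equal(f$closer, r$closer)
  expect_equal(f$cargo, r$cargo)
  expect_equal(f$span_bp, r$span_bp)
  expect_equal(f$element_strand, ifelse(r$element_strand == "+", "-", "+"))
})
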