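# Quorum/loner co-localization detection against domain-profile scores.

score_tbl <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(feature_id = r[[1]], profile_name = r[[2]],
                   bit_score = as.numeric(r[[3]]))
  })
}

toy_genome <- function(n_genes = 6, genome_id = "tg") {
  genes <- tibble::tibble(
    feature_id = sprintf("%s_f%02d", genome_id, seq_len(n_genes)),
    contig_id = paste0(genome_id, "_c1"),
    start = seq_len(n_genes) * 1000L,
    end = seq_len(n_genes) * 1000L + 600L,
    strand = "+", protein = strrep("A", 60),
    product = "hypothetical protein")
  genome_annotation(genome_id,
                    tibble::tibble(contig_id = paste0(genome_id, "_c1"),
                                   length = (n_genes + 1L) * 1000L),
                    genes)
}

test_that("load_scores validates, deduplicates by max, and accepts empties", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tprofile_name\tbit_score",
               "f1\tAAA_15\t30", "f2\tDUF4435\t28"), path)
  expect_equal(nrow(load_scores(path)), 2)

  writeLines(c("feature_id\tprofile_name\tbit_score",
               "f1\tAAA_15\t30", "f1\tAAA_15\t35"), path)
  expect_warning(sc <- load_scores(path), "duplicate")
  expect_equal(sc$bit_score, 35)

  writeLines("feature_id\tprofile_name\tbit_score", path)
  expect_equal(nrow(load_scores(path)), 0)

  writeLines(c("feature_id\tbit_score", "f1\t3"), path)
  expect_error(load_scores(path), "profile_name")
})

test_that("thresholds are inclusive at equality and reject just below", {
  g <- toy_genome()
  model <- paris_model()
  # two-gene pair at exact thresholds (AAA_15 = 32, DUF4435 = 27)
  sc <- score_tbl(list("tg_f02", "AAA_15", 32), list("tg_f03", "DUF4435", 27))
  hits <- detect_systems(g, sc, model)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$variant, "two_gene")
  expect_equal(hits$spacing, 0L)

  # a hair below threshold: no hit
  sc2 <- score_tbl(list("tg_f02", "AAA_15", 31.9), list("tg_f03", "DUF4435", 27))
  expect_equal(nrow(detect_systems(g, sc2, model)), 0)

  # every threshold of the model, at equality and at -0.1
  cases <- list(
    list(profiles = c("AAA_15", "DUF4435"), thr = c(32, 27), variant = "two_gene"),
    list(profiles = c("AAA_21", "DUF4435"), thr = c(27, 27), variant = "two_gene"),
    list(profiles = "AAA_15+DUF4435", thr = 80, variant = "fused"),
    list(profiles = "AAA_21+DUF4435", thr = 20, variant = "fused"))
  for (cs in cases) {
    at <- purrr::map2(seq_along(cs$profiles), cs$thr, function(i, s)
      list(sprintf("tg_f%02d", i + 1), cs$profiles[i], s))
    hits <- detect_systems(g, do.call(score_tbl, at), paris_model())
    expect_equal(nrow(hits), 1, info = paste(cs$profiles, collapse = "+"))
    expect_equal(hits$variant, cs$variant)
    below <- purrr::map2(seq_along(cs$profiles), cs$thr, function(i, s)
      list(sprintf("tg_f%02d", i + 1), cs$profiles[i], s - 0.1))
    expect_equal(nrow(detect_systems(g, do.call(score_tbl, below),
                                     paris_model())), 0,
                 info = paste(cs$profiles, collapse = "+"))
  }
})

test_that("fused loners need no partner and no co-localization", {
  g <- toy_genome()
  sc <- score_tbl(list("tg_f05", "AAA_15+DUF4435", 80))
  hits <- detect_systems(g, sc, paris_model())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$variant, "fused")
  expect_equal(hits$feature_fused, "tg_f05")
  expect_true(is.na(hits$spacing))
})

test_that("gene spacing is bounded and monotone in the limit", {
  g <- toy_genome(8)
  pair_at <- function(gap) {
    score_tbl(list("tg_f01", "AAA_15", 40),
              list(sprintf("tg_f%02d", 2 + gap), "DUF4435", 40))
  }
  expect_equal(nrow(detect_systems(g, pair_at(2), paris_model())), 1)
  expect_equal(nrow(detect_systems(g, pair_at(3), paris_model())), 0)
  expect_equal(nrow(detect_systems(g, pair_at(3),
                                   paris_model(max_intervening_genes = 3))), 1)
  # raising a threshold never adds hits
  sc <- pair_at(1)
  m_hi <- system_model("m", components = list(atpase = c(AAA_15 = 45),
                                              partner = c(DUF4435 = 27)))
  expect_lte(nrow(detect_systems(g, sc, m_hi)),
             nrow(detect_systems(g, sc, paris_model())))
})

test_that("detection equals brute-force enumeration on random genomes", {
  set.seed(118)
  model <- paris_model()
  profs <- c("AAA_15", "AAA_21", "DUF4435", "AAA_15+DUF4435", "AAA_21+DUF4435")
  for (r in 1:15) {
    g <- toy_genome(n_genes = 20, genome_id = sprintf("rg%02d", r))
    sc <- tidyr::expand_grid(feature_id = g$genes$feature_id,
                             profile_name = profs)
    sc$bit_score <- round(runif(nrow(sc), -20, 90), 1)
    got <- detect_systems(g, sc, model)
    want <- oracle_detect(g, sc, model)
    expect_equal(as.data.frame(got), as.data.frame(want), info = r)
  }
})

test_that("prevalence is the fraction of genomes with a hit", {
  genomes <- lapply(1:20, function(i) toy_genome(4, sprintf("pg%02d", i)))
  sc <- score_tbl(list("pg03_f01", "AAA_15", 50), list("pg03_f02", "DUF4435", 50),
                  list("pg11_f02", "AAA_15+DUF4435", 90))
  prev <- system_prevalence(genomes, sc, paris_model())
  expect_equal(prev$prevalence, 2 / 20)
  g <- glance(prev)
  expect_equal(g$n_two_gene, 1L)
  expect_equal(g$n_fused, 1L)

  # no positives
  prev0 <- system_prevalence(genomes, score_tbl(list("pg01_f01", "AAA_15", 1)),
                             paris_model())
  expect_equal(prev0$prevalence, 0)
})

test_that("noiseless planted corpora are detected at exactly the planted rate", {
  sim <- generate_corpus(corpus_spec(n_genomes = 40, contig_break_prob = 0,
                                     seed = 51))
  sc <- emit_domain_scores(sim$corpus, sim$ledger, noise_sd = 0, seed = 52)
  prev <- system_prevalence(sim$corpus, sc, paris_model())
  planted <- unique(sim$ledger$loci$genome_id[
    sim$ledger$loci$system_id %in% sim$ledger$labeled_systems])
  expect_equal(prev$prevalence, length(planted) / 40)
  rep <- evaluate_against_truth(run_hotspot_mining(sim$corpus), sim$ledger,
                                hits = prev$hits)
  expect_equal(rep$detection_precision, 1)
  expect_equal(rep$detection_recall, 1)
})
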