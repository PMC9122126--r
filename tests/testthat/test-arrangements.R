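# Arrangement tallying, curation arithmetic, system grouping, and summary
# statistics.

fake_loci <- function(tuples, spans = NULL) {
  n <- length(tuples)
  tibble::tibble(
    genome_id = sprintf("g%02d", seq_len(n)),
    contig_id = sprintf("g%02d_c1", seq_len(n)),
    anchor = sprintf("a%02d", seq_len(n)),
    closer = sprintf("z%02d", seq_len(n)),
    cargo = lapply(tuples, function(tt) {
      if (length(tt) == 0) character() else paste0("p", seq_along(tt), "_", seq_len(n)[1])
    }),
    n_cargo = lengths(tuples),
    span_bp = spans %||% rep(1000L, n),
    element_strand = "+")
}


test_that("canonical arrangements preserve anchor-to-closer order", {
  assign <- c(p1 = "c5", p2 = "c2", p3 = "c9")
  expect_equal(canonical_arrangement(c("p1", "p2", "p3"), assign),
               c("c5", "c2", "c9"))
  expect_equal(canonical_arrangement(character(), assign), character())
  expect_equal(canonical_arrangement(c("p3", "p1"), assign, ordered = FALSE),
               c("c5", "c9"))
  expect_error(canonical_arrangement(c("p1", "zz"), assign), "zz")
})

test_that("tallying counts tuples exactly and conserves loci", {
  loci <- tibble::tibble(
    genome_id = sprintf("g%d", 1:4), contig_id = sprintf("g%d_c1", 1:4),
    anchor = sprintf("a%d", 1:4), closer = sprintf("z%d", 1:4),
    cargo = list("p1", "p2", c("p3", "p4"), character()),
    n_cargo = c(1L, 1L, 2L, 0L), span_bp = rep(500L, 4),
    element_strand = "+")
  assign <- c(p1 = "A", p2 = "A", p3 = "A", p4 = "B")
  tab <- tally_arrangements(loci, assign)
  td <- tidy(tab)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$count), 4)            # conservation
  expect_equal(sort(td$count, decreasing = TRUE), c(2, 1, 1))
  expect_equal(tab$total_loci, 4)
  expect_equal(tab$cumulative_fraction, 1)
})

test_that("curation arithmetic matches the worked example", {
  counts <- c(A = 7, B = 5, C = 4, D = 1)
  tab <- single_cluster_table(counts)
  cur <- curate_arrangements(tab, min_count = 5)
  expect_equal(nrow(cur$arrangements), 2)
  expect_equal(cur$cumulative_fraction, 12 / 17)

  # no filter: everything retained
  expect_equal(curate_arrangements(tab, min_count = 1)$cumulative_fraction, 1)

  # monotonicity: cumulative fraction never increases with min_count
  cf <- vapply(1:8, function(mc)
    curate_arrangements(tab, min_count = mc)$cumulative_fraction, 1.0)
  expect_true(all(diff(cf) <= 0))
})

test_that("the short-protein rule drops arrangements below the length floor", {
  set.seed(5)
  loci <- tibble::tibble(
    genome_id = sprintf("g%d", 1:6), contig_id = sprintf("g%d_c1", 1:6),
    anchor = sprintf("a%d", 1:6), closer = sprintf("z%d", 1:6),
    cargo = c(replicate(5, "short_p", simplify = FALSE), list("long_p")),
    n_cargo = 1L, span_bp = 500L, element_strand = "+")
  loci$cargo <- purrr::imap(loci$cargo, function(cc, i) paste0(cc, "_", i))
  proteins <- setNames(
    c(replicate(5, random_protein(119)), random_protein(300)),
    unlist(loci$cargo))
  assign <- setNames(c(rep("S", 5), "L"), unlist(loci$cargo))
  tab <- tally_arrangements(loci, assign, proteins = proteins)
  cur <- curate_arrangements(tab, min_count = 1, min_protein_aa = 120)
  kept <- purrr::map_chr(cur$arrangements$cluster_tuple, paste, collapse = ";")
  expect_equal(kept, "L")   # the 119-aa arrangement is dropped despite count 5
})

test_that("system grouping follows containment / Jaccard components", {
  cargo_ids <- function(tt, id) {
    if (length(tt) == 0) character() else paste0(id, "_", seq_along(tt))
  }
  mk_table <- function(tuples, counts) {
    loci <- purrr::map2_dfr(tuples, counts, function(tt, k) {
      purrr::map_dfr(seq_len(k), function(i) {
        id <- paste0(paste(tt, collapse = ""), i)
        tibble::tibble(genome_id = id, contig_id = id,
                       anchor = paste0("a", id), closer = paste0("z", id),
                       cargo = list(cargo_ids(tt, id)),
                       n_cargo = length(tt), span_bp = 100L,
                       element_strand = "+")
      })
    })
    assign <- unlist(purrr::map2(tuples, counts, function(tt, k) {
      unlist(purrr::map(seq_len(k), function(i) {
        id <- paste0(paste(tt, collapse = ""), i)
        setNames(tt, cargo_ids(tt, id))
      }))
    }))
    tally_arrangements(loci, assign)
  }
  tab <- mk_table(list(c("X", "Y"), c("X", "Y", "Z")), c(30, 10))
  sys <- group_systems(curate_arrangements(tab, min_count = 1))
  expect_equal(nrow(sys), 1)
  expect_setequal(sys$core_clusters[[1]], c("X", "Y"))
  expect_equal(sys$variant_pct[[1]], c(75, 25))
  expect_equal(sum(sys$variant_pct[[1]]), 100)

  # disjoint arrangements stay separate
  tab2 <- mk_table(list(c("A", "B"), c("C", "D")), c(5, 5))
  expect_equal(nrow(group_systems(curate_arrangements(tab2, min_count = 1))), 2)

  # containment chains merge transitively with the shared core
  tab3 <- mk_table(list(c("X", "Y"), c("X", "Y", "Z"), c("X", "Y", "Z", "W")),
                   c(6, 5, 5))
  sys3 <- group_systems(curate_arrangements(tab3, min_count = 1))
  expect_equal(nrow(sys3), 1)
  expect_setequal(sys3$core_clusters[[1]], c("X", "Y"))

  # grouping is idempotent: regrouping the grouped members changes nothing
  sys3b <- group_systems(curate_arrangements(tab3, min_count = 1))
  expect_equal(as.data.frame(tidy(sys3)), as.data.frame(tidy(sys3b)))

  # the empty arrangement is never grouped into a system
  tab4 <- mk_table(list(character(), c("Q", "R")), c(4, 4))
  sys4 <- group_systems(curate_arrangements(tab4, min_count = 1))
  expect_equal(nrow(sys4), 1)
  expect_setequal(sys4$core_clusters[[1]], c("Q", "R"))
})

test_that("hotspot summaries report mean spans and top-N proportions", {
  loci <- fake_loci(list("A", "A", "A"), spans = c(2000L, 3000L, 4000L))
  loci$cargo <- list("p1", "p2", "p3")
  assign <- c(p1 = "A", p2 = "A", p3 = "A")
  tab <- tally_arrangements(loci, assign)
  sys <- group_systems(curate_arrangements(tab, min_count = 1))
  s <- hotspot_summary(loci, tab, sys)
  expect_equal(s$mean_span_kb, 3.0)
  expect_equal(s$top_systems$proportion, 1.0)
  expect_true(all(diff(s$top_systems$proportion) <= 0))
})

test_that("the end-to-end driver is deterministic and truth-exact", {
  sim <- generate_corpus(corpus_spec(n_genomes = 30, seed = 64))
  run1 <- run_hotspot_mining(sim$corpus, min_count = 2)
  run2 <- run_hotspot_mining(sim$corpus, min_count = 2)
  expect_equal(glance(run1), glance(run2))
  expect_equal(as.data.frame(run1$loci[, c("anchor", "closer")]),
               as.data.frame(run2$loci[, c("anchor", "closer")]))
  rep <- evaluate_against_truth(run1, sim$ledger)
  expect_equal(rep$locus_precision, 1)
  expect_equal(rep$locus_recall, 1)
  expect_equal(rep$cluster_family_ari, 1)
  expect_true(rep$arrangement_exact)

  # an empty corpus (no planted loci) flows through without crashing
  sim0 <- generate_corpus(corpus_spec(n_genomes = 8, hotspot_prevalence = 0,
                                      seed = 3))
  expect_equal(nrow(sim0$ledger$loci), 0)
  run0 <- run_hotspot_mining(sim0$corpus)
  expect_equal(nrow(run0$loci), 0)
  expect_null(run0$arrangements)
})
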