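# Synthetic annotated-genome corpus with planted hotspot loci and a ground
# truth ledger. Each carrier genome receives one element
# (anchor -> 0..9 cargo genes -> keyword-annotated closing gene) whose
# cargo is instantiated from a pool of multi-gene system templates drawn
# under a skewed frequency law, with controlled protein divergence,
# orientation flips, decoy genes, and optional contig breaks that split the
# locus (exercising the cross-contig discard rule).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define a system template
#'
#' A template is a cassette of 1-6 gene families with fixed reference
#' protein sequences; planted instances are per-site mutated copies of the
#' references.
#'
#' @param system_id Template name.
#' @param family_seqs Named character vector `family_id -> reference
#'   protein` (1 to 6 families, each >= 30 aa).
#' @param domain_labels Optional tibble (`family_id`, `profile_name`,
#'   `base_score`) marking families that carry detectable domain profiles.
#' @return A list of class `system_template`.
#' @export
system_template <- function(system_id, family_seqs, domain_labels = NULL) {
  stopifnot(length(family_seqs) >= 1, length(family_seqs) <= 6,
            all(nchar(family_seqs) >= 30), !is.null(names(family_seqs)))
  if (!is.null(domain_labels)) {
    domain_labels <- as_tibble(domain_labels)
    stopifnot(all(c("family_id", "profile_name", "base_score") %in%
                    names(domain_labels)),
              all(domain_labels$family_id %in% names(family_seqs)))
  }
  structure(list(system_id = system_id,
                 gene_families = names(family_seqs),
                 family_seqs = family_seqs,
                 family_lengths = nchar(family_seqs),
                 domain_labels = domain_labels),
            class = "system_template")
}

#' Default 12-system template pool
#'
#' Deterministic pool of 12 cassette templates with 1-4 gene families each
#' (reference proteins drawn once from background frequencies under a fixed
#' internal seed). Template 1 is a PARIS-like two-gene cassette labelled
#' AAA_15 (base score 45) + DUF4435 (base score 40); template 2 is a
#' single-gene AAA_15+DUF4435 fusion (base score 95); the rest are
#' unlabelled.
#'
#' @param n_systems Number of templates (default 12).
#' @param seed Internal seed for the reference sequences.
#' @return List of [system_template()] objects.
#' @export
default_system_pool <- function(n_systems = 12, seed = 20125) {
  stopifnot(n_systems >= 1)
  gene_counts <- rep_len(c(2, 1, 3, 2, 1, 4, 2, 3, 1, 2, 4, 3), n_systems)
  with_seed(seed, {
    lapply(seq_len(n_systems), function(k) {
      nf <- gene_counts[k]
      lens <- sample(90:380, nf, replace = TRUE)
      labels <- NULL
      if (k == 1) {
        nf <- 2
        lens <- c(410, 340)
        labels <- tibble(family_id = sprintf("sys%02d_f%d", k, 1:2),
                         profile_name = c("AAA_15", "DUF4435"),
                         base_score = c(45, 40))
      } else if (k == 2) {
        nf <- 1
        lens <- 640
        labels <- tibble(family_id = sprintf("sys%02d_f%d", k, 1),
                         profile_name = "AAA_15+DUF4435",
                         base_score = 95)
      }
      seqs <- vapply(lens, random_protein, "")
      names(seqs) <- sprintf("sys%02d_f%d", k, seq_len(nf))
      system_template(sprintf("sys%02d", k), seqs, domain_labels = labels)
    })
  })
}

#' Corpus generation parameters
#'
#' Defaults describe the standard validation corpus: 200 genomes, 40%
#' hotspot prevalence, a 12-system pool under a Zipf(s = 1.2) frequency
#' law, 10% protein divergence on anchors and cargo, 15 decoy genes per
#' genome, 10% contig-break rate, 50% orientation flips.
#'
#' @param n_genomes Number of genomes.
#' @param hotspot_prevalence Fraction of genomes carrying a planted locus.
#' @param system_pool List of [system_template()] objects.
#' @param zipf_s Zipf exponent of the frequency law over the pool (in pool
#'   order); ignored when `weights` is given.
#' @param weights Optional explicit frequency weights (normalised).
#' @param anchor_divergence Per-site substitution rate on planted anchors.
#' @param cargo_divergence Per-site substitution rate within a family.
#' @param decoy_genes_per_genome Mean decoy gene count (Poisson).
#' @param contig_break_prob Probability a planted locus is split across two
#'   contigs.
#' @param orientation_flip_prob Probability the whole element is placed on
#'   the minus strand (reversed genomic gene order).
#' @param empty_cargo_prob Probability a planted locus carries no cargo.
#' @param min_cargo_aa Minimum family protein length (validated).
#' @param max_locus_kb Maximum planted locus span in kb (validated; the
#'   default 12 mirrors the packaging capacity of a satellite-sized
#'   capsid).
#' @param closer_keyword Keyword placed in the closing gene's product
#'   (`"integrase"` default; `"replication endonuclease"` for the P2-like
#'   scenario).
#' @param anchor_protein,closer_protein Reference proteins for the anchor
#'   and closing gene.
#' @param seed Integer seed; the corpus is a pure function of the spec.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_genomes = 200, hotspot_prevalence = 0.4,
                        system_pool = default_system_pool(),
                        zipf_s = 1.2, weights = NULL,
                        anchor_divergence = 0.1, cargo_divergence = 0.1,
                        decoy_genes_per_genome = 15,
                        contig_break_prob = 0.1,
                        orientation_flip_prob = 0.5,
                        empty_cargo_prob = 0.05,
                        min_cargo_aa = 30, max_locus_kb = 12,
                        closer_keyword = "integrase",
                        anchor_protein = synthetic_anchor_protein(),
                        closer_protein = synthetic_closer_protein(),
                        seed = 1) {
  probs <- c(hotspot_prevalence, contig_break_prob, orientation_flip_prob,
             empty_cargo_prob, anchor_divergence, cargo_divergence)
  stopifnot(all(probs >= 0), all(probs <= 1), n_genomes >= 1,
            decoy_genes_per_genome >= 0)
  if (hotspot_prevalence > 0 && length(system_pool) == 0) {
    abort("system_pool is empty while hotspot_prevalence > 0")
  }
  if (is.null(weights)) {
    weights <- seq_along(system_pool)^(-zipf_s)
  }
  stopifnot(length(weights) == length(system_pool), all(weights >= 0))
  weights <- weights / sum(weights)
  for (tmpl in system_pool) {
    if (any(tmpl$family_lengths < min_cargo_aa)) {
      abort(sprintf("template %s has a family shorter than min_cargo_aa",
                    tmpl$system_id))
    }
    locus_bp <- sum(3 * (tmpl$family_lengths + 1)) +
      200 * (length(tmpl$gene_families) + 1)
    if (locus_bp > max_locus_kb * 1000) {
      abort(sprintf("template %s exceeds max_locus_kb", tmpl$system_id))
    }
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 hotspot_prevalence = hotspot_prevalence,
                 system_pool = system_pool, weights = weights,
                 anchor_divergence = anchor_divergence,
                 cargo_divergence = cargo_divergence,
                 decoy_genes_per_genome = decoy_genes_per_genome,
                 contig_break_prob = contig_break_prob,
                 orientation_flip_prob = orientation_flip_prob,
                 empty_cargo_prob = empty_cargo_prob,
                 min_cargo_aa = min_cargo_aa, max_locus_kb = max_locus_kb,
                 closer_keyword = closer_keyword,
                 anchor_protein = unname(anchor_protein[1]),
                 closer_protein = unname(closer_protein[1]),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

DECOY_PRODUCTS <- c(
  "hypothetical protein", "DNA polymerase III subunit",
  "ABC transporter ATP-binding protein", "elongation factor Tu",
  "MFS transporter", "50S ribosomal protein L3",
  "two-component sensor histidine kinase", "acyl-CoA dehydrogenase",
  "cold-shock protein", "aminoacyl-tRNA ligase")

#' Generate a synthetic corpus with a planted-truth ledger
#'
#' Deterministic given `spec$seed`. Each carrier genome receives one
#' element: a mutated anchor homolog, 0-9 cargo genes instantiated from a
#' system template drawn under the frequency law, and a closing gene whose
#' product contains the configured keyword. Decoy genes carry
#' keyword-free products and background-frequency proteins (so chance
#' anchor hits at E <= 1e-10 are overwhelmingly improbable). With
#' probability `contig_break_prob` the element is split across two contigs
#' (flagged `split` in the ledger); with `orientation_flip_prob` it is
#' placed on the minus strand with reversed genomic gene order.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `corpus` (named list of [genome_annotation()]) and
#'   `ledger` (class `truth_ledger`: `loci`, `membership`, `labels`,
#'   `labeled_systems`, `expected_arrangements`, `spec_seed`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    corpus <- vector("list", spec$n_genomes)
    loci_rows <- list()
    member_rows <- list()
    label_rows <- list()
    for (g in seq_len(spec$n_genomes)) {
      gid <- sprintf("g%04d", g)
      carries <- runif(1) < spec$hotspot_prevalence
      n_dec <- max(3L, rpois(1, spec$decoy_genes_per_genome))
      n_pre <- rbinom(1, n_dec, 0.5)
      n_post <- n_dec - n_pre
      fcount <- 0L
      next_fid <- function() {
        fcount <<- fcount + 1L
        sprintf("%s_f%03d", gid, fcount)
      }
      decoy_gene <- function() {
        list(feature_id = next_fid(),
             protein = random_protein(sample(80:250, 1)),
             product = sample(DECOY_PRODUCTS, 1),
             strand = sample(c("+", "-"), 1), role = "decoy")
      }
      pre <- lapply(seq_len(n_pre), function(i) decoy_gene())
      element <- list()
      planted <- NULL
      if (carries) {
        anchor <- list(feature_id = next_fid(),
                       protein = mutate_protein(spec$anchor_protein,
                                                spec$anchor_divergence),
                       product = "polarity suppression protein",
                       strand = "+", role = "anchor")
        empty <- runif(1) < spec$empty_cargo_prob
        cargo <- list()
        system_id <- NA_character_
        fams <- character()
        if (!empty) {
          k <- sample.int(length(spec$system_pool), 1, prob = spec$weights)
          tmpl <- spec$system_pool[[k]]
          system_id <- tmpl$system_id
          fams <- tmpl$gene_families
          cargo <- lapply(fams, function(fam) {
            list(feature_id = next_fid(),
                 protein = mutate_protein(tmpl$family_seqs[[fam]],
                                          spec$cargo_divergence),
                 product = "hypothetical protein",
                 strand = "+", role = "cargo", family = fam)
          })
          if (!is.null(tmpl$domain_labels)) {
            fid_of <- setNames(purrr::map_chr(cargo, "feature_id"), fams)
            label_rows[[length(label_rows) + 1L]] <-
              tmpl$domain_labels |>
              mutate(feature_id = unname(fid_of[.data$family_id]),
                     genome_id = gid)
          }
        }
        closer <- list(feature_id = next_fid(),
                       protein = mutate_protein(spec$closer_protein,
                                                spec$cargo_divergence),
                       product = paste("putative", spec$closer_keyword),
                       strand = "+", role = "closer")
        element <- c(list(anchor), cargo, list(closer))
        flip <- runif(1) < spec$orientation_flip_prob
        if (flip) {
          element <- rev(element)
          element <- lapply(element, function(e) { e$strand <- "-"; e })
        }
        split <- runif(1) < spec$contig_break_prob
        cut <- if (split) sample.int(length(element) - 1L, 1) else NA_integer_
        planted <- list(anchor_id = anchor$feature_id,
                        closer_id = closer$feature_id,
                        system_id = system_id, fams = fams,
                        cargo_ids = purrr::map_chr(cargo, "feature_id"),
                        split = split, flipped = flip, cut = cut)
        for (cg in cargo) {
          member_rows[[length(member_rows) + 1L]] <-
            tibble(feature_id = cg$feature_id, family_id = cg$family,
                   genome_id = gid)
        }
      }
      post <- lapply(seq_len(n_post), function(i) decoy_gene())
      # assemble contigs
      if (!is.null(planted) && planted$split) {
        contig_gene_sets <- list(c(pre, element[seq_len(planted$cut)]),
                                 c(element[-seq_len(planted$cut)], post))
      } else {
        contig_gene_sets <- list(c(pre, element, post))
      }
      contigs <- list()
      gene_rows <- list()
      for (ci in seq_along(contig_gene_sets)) {
        cid <- sprintf("%s_c%d", gid, ci)
        pos <- 0L
        for (gene in contig_gene_sets[[ci]]) {
          gap <- sample(10:200, 1)
          glen <- 3L * (nchar(gene$protein) + 1L)
          start <- pos + gap + 1L
          end <- start + glen - 1L
          pos <- end
          gene_rows[[length(gene_rows) + 1L]] <- tibble(
            feature_id = gene$feature_id, contig_id = cid,
            start = start, end = end, strand = gene$strand,
            protein = gene$protein, product = gene$product)
        }
        contigs[[ci]] <- tibble(contig_id = cid,
                                length = pos + sample(10:200, 1),
                                sequence = NA_character_)
      }
      gene_tbl <- bind_rows(gene_rows)
      corpus[[g]] <- genome_annotation(gid, bind_rows(contigs),
                                       if (nrow(gene_tbl) > 0) gene_tbl
                                       else empty_gene_table(),
                                       source = "synthetic")
      if (!is.null(planted)) {
        anchor_contig <- gene_tbl$contig_id[gene_tbl$feature_id ==
                                              planted$anchor_id]
        loci_rows[[length(loci_rows) + 1L]] <- tibble(
          genome_id = gid, contig_id = anchor_contig,
          anchor_id = planted$anchor_id, closer_id = planted$closer_id,
          system_id = planted$system_id,
          cargo_families = list(planted$fams),
          cargo_ids = list(planted$cargo_ids),
          split = planted$split, flipped = planted$flipped)
      }
    }
    names(corpus) <- purrr::map_chr(corpus, "genome_id")
    loci <- if (length(loci_rows) > 0) bind_rows(loci_rows) else
      tibble(genome_id = character(), contig_id = character(),
             anchor_id = character(), closer_id = character(),
             system_id = character(), cargo_families = list(),
             cargo_ids = list(), split = logical(), flipped = logical())
    membership <- if (length(member_rows) > 0) bind_rows(member_rows) else
      tibble(feature_id = character(), family_id = character(),
             genome_id = character())
    labels <- if (length(label_rows) > 0) bind_rows(label_rows) else
      tibble(family_id = character(), profile_name = character(),
             base_score = numeric(), feature_id = character(),
             genome_id = character())
    labeled_systems <- purrr::map_chr(
      purrr::keep(spec$system_pool, ~ !is.null(.x$domain_labels)),
      "system_id")
    expected <- expected_arrangement_table(loci)
    ledger <- structure(list(loci = loci, membership = membership,
                             labels = labels,
                             labeled_systems = labeled_systems,
                             expected_arrangements = expected,
                             spec_seed = spec$seed),
                        class = "truth_ledger")
    list(corpus = corpus, ledger = ledger)
  })
}

# Expected arrangement table over non-split planted loci, keyed by
# ";"-joined family tuples in anchor-to-closer order.
expected_arrangement_table <- function(loci) {
  keep <- loci[!loci$split, , drop = FALSE]
  keys <- purrr::map_chr(keep$cargo_families, paste, collapse = TUPLE_SEP)
  tibble(key = keys) |>
    group_by(.data$key) |>
    summarise(count = n(), .groups = "drop") |>
    arrange(desc(.data$count), .data$key)
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat(sprintf("<truth_ledger> %d planted loci (%d split), %d cargo proteins\n",
              nrow(x$loci), sum(x$loci$split), nrow(x$membership)))
  invisible(x)
}

STANDARD_PROFILES <- c("AAA_15", "AAA_21", "DUF4435",
                       "AAA_15+DUF4435", "AAA_21+DUF4435")

#' Emit a domain-profile score table for a corpus
#'
#' Labelled proteins (per the ledger) score `base_score` plus Gaussian
#' noise; every unlabelled protein receives strictly negative scores for
#' all profiles. The table feeds co-localization detection without any
#' profile database.
#'
#' @param corpus Corpus from [generate_corpus()].
#' @param ledger Matching `truth_ledger`.
#' @param noise_sd Gaussian score noise (0 = exact base scores).
#' @param profiles Profile universe (default: the PARIS profiles plus any
#'   ledger label profiles).
#' @param seed Optional seed for the noise/decoy draws.
#' @return Tibble: `feature_id`, `profile_name`, `bit_score`.
#' @export
emit_domain_scores <- function(corpus, ledger, noise_sd = 0,
                               profiles = NULL, seed = NULL) {
  if (is.null(profiles)) {
    profiles <- union(STANDARD_PROFILES, ledger$labels$profile_name)
  }
  with_seed(seed, {
    genes <- corpus_genes(corpus)
    labeled <- ledger$labels
    decoy_ids <- setdiff(genes$feature_id, labeled$feature_id)
    neg <- tidyr::expand_grid(feature_id = decoy_ids,
                              profile_name = profiles) |>
      mutate(bit_score = round(runif(n(), -30, -1), 2))
    pos <- tibble(feature_id = labeled$feature_id,
                  profile_name = labeled$profile_name,
                  bit_score = labeled$base_score +
                    if (noise_sd > 0) rnorm(nrow(labeled), 0, noise_sd) else 0)
    bind_rows(pos, neg) |> arrange(.data$feature_id, .data$profile_name)
  })
}

#' Write / read a truth ledger as JSON
#'
#' @param ledger A `truth_ledger`.
#' @param path JSON file.
#' @return `path` (writer) or the ledger (reader).
#' @export
write_truth_ledger <- function(ledger, path) {
  jsonlite::write_json(
    list(loci = as.data.frame(ledger$loci),
         membership = as.data.frame(ledger$membership),
         labels = as.data.frame(ledger$labels),
         labeled_systems = ledger$labeled_systems,
         expected_arrangements = as.data.frame(ledger$expected_arrangements),
         spec_seed = ledger$spec_seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_ledger
#' @export
read_truth_ledger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixlist <- function(col) lapply(col, function(v) as.character(unlist(v)))
  loci <- as_tibble(x$loci)
  if (nrow(loci) > 0) {
    loci$cargo_families <- fixlist(loci$cargo_families)
    loci$cargo_ids <- fixlist(loci$cargo_ids)
  }
  structure(list(loci = loci,
                 membership = as_tibble(x$membership),
                 labels = as_tibble(x$labels),
                 labeled_systems = as.character(x$labeled_systems),
                 expected_arrangements = as_tibble(x$expected_arrangements),
                 spec_seed = x$spec_seed),
            class = "truth_ledger")
}
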