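# Diversity statistics of hotspot loci: canonical cluster arrangements,
# frequency tables, curation, grouping of similar arrangements into genetic
# systems, and summary statistics, plus the end-to-end mining driver.

TUPLE_SEP <- ";"

#' Canonical arrangement of one locus
#'
#' Maps the cargo features of a locus (already in anchor-to-closer order,
#' regardless of which genomic strand the element occupies) to their
#' cluster ids. An empty cargo yields an empty tuple.
#'
#' @param cargo Character vector of cargo feature ids in anchor-to-closer
#'   order.
#' @param assignment Named character vector `feature_id -> cluster_id`, or
#'   a `protein_clusters` tibble.
#' @param ordered Keep cargo order (default); if `FALSE`, the tuple is
#'   sorted, making arrangement identity order-insensitive.
#' @return Character vector of cluster ids (the tuple).
#' @export
canonical_arrangement <- function(cargo, assignment, ordered = TRUE) {
  if (is.data.frame(assignment)) {
    assignment <- setNames(assignment$cluster_id, assignment$protein_id)
  }
  if (length(cargo) == 0) return(character())
  miss <- setdiff(cargo, names(assignment))
  if (length(miss) > 0) {
    abort(paste0("cargo protein not assigned to a cluster: ", miss[1]))
  }
  tuple <- unname(assignment[cargo])
  if (!ordered) tuple <- sort(tuple)
  tuple
}

#' Tally arrangements across loci
#'
#' Counts each distinct cluster tuple over all loci (exact multiset count).
#' The empty arrangement (a locus with no cargo) is tallied like any other.
#'
#' @param loci Locus tibble from [extract_loci()].
#' @param assignment Cluster assignment (named vector or `protein_clusters`
#'   tibble); must cover every cargo protein.
#' @param proteins Optional named vector of cargo protein sequences, used
#'   to record the longest member protein per arrangement (needed by the
#'   length-based curation rule).
#' @param ordered Passed to [canonical_arrangement()].
#' @return An `arrangement_table`: list with `arrangements` (tibble:
#'   `arrangement_id`, `cluster_tuple` list-column, `count`, `locus_ids`
#'   list-column, `max_member_protein_aa`), `total_loci`, `curation`
#'   (`NULL` before curation) and `cumulative_fraction` (1 before
#'   curation).
#' @export
tally_arrangements <- function(loci, assignment, proteins = NULL,
                               ordered = TRUE) {
  stopifnot(nrow(loci) > 0)
  if (is.data.frame(assignment)) {
    assignment <- setNames(assignment$cluster_id, assignment$protein_id)
  }
  locus_key <- paste(loci$anchor, loci$closer, sep = "|")
  tuples <- purrr::map(loci$cargo, canonical_arrangement,
                       assignment = assignment, ordered = ordered)
  keys <- purrr::map_chr(tuples, paste, collapse = TUPLE_SEP)
  max_aa <- purrr::map_int(loci$cargo, function(cc) {
    if (length(cc) == 0 || is.null(proteins)) return(NA_integer_)
    as.integer(max(nchar(proteins[cc])))
  })
  df <- tibble(key = keys, tuple = tuples, locus_id = locus_key,
               max_aa = max_aa)
  agg <- df |>
    group_by(.data$key) |>
    summarise(count = n(),
              locus_ids = list(.data$locus_id),
              max_member_protein_aa = if (all(is.na(.data$max_aa))) NA_integer_
                                      else max(.data$max_aa, na.rm = TRUE),
              .groups = "drop") |>
    arrange(desc(.data$count), .data$key)
  tuple_of <- setNames(df$tuple, df$key)
  agg$cluster_tuple <- purrr::map(agg$key, ~ tuple_of[[.x]])
  agg$arrangement_id <- sprintf("arr_%04d", seq_len(nrow(agg)))
  arrangements <- agg[, c("arrangement_id", "cluster_tuple", "count",
                          "locus_ids", "max_member_protein_aa")]
  new_arrangement_table(arrangements, total_loci = nrow(loci),
                        curation = NULL, cumulative_fraction = 1)
}

new_arrangement_table <- function(arrangements, total_loci, curation,
                                  cumulative_fraction) {
  structure(list(arrangements = arrangements,
                 total_loci = total_loci,
                 curation = curation,
                 cumulative_fraction = cumulative_fraction),
            class = "arrangement_table")
}

#' @export
print.arrangement_table <- function(x, ...) {
  cat(sprintf("<arrangement_table> %d arrangement(s) over %d loci",
              nrow(x$arrangements), x$total_loci))
  if (!is.null(x$curation)) {
    cat(sprintf(" [curated: min_count=%d%s; %.1f%% of loci retained]",
                x$curation$min_count,
                if (is.null(x$curation$min_protein_aa)) "" else
                  sprintf(", min_protein_aa=%d", x$curation$min_protein_aa),
                100 * x$cumulative_fraction))
  }
  cat("\n")
  invisible(x)
}

#' Curate an arrangement table
#'
#' Keeps arrangements occurring at least `min_count` times and, when
#' `min_protein_aa` is given, whose longest member cargo protein reaches
#' that length (the published run used at least 5 occurrences for the
#' P4-like hotspot, at least 10 plus a 120-aa floor for the P2-like one).
#' `cumulative_fraction` becomes retained loci / total loci.
#'
#' @param table An `arrangement_table`.
#' @param min_count Minimum occurrence count (>= 1).
#' @param min_protein_aa Optional minimum for the longest member protein.
#' @return A curated `arrangement_table` (total_loci unchanged).
#' @export
curate_arrangements <- function(table, min_count = 5, min_protein_aa = NULL) {
  stopifnot(inherits(table, "arrangement_table"), min_count >= 1)
  arr <- table$arrangements
  keep <- arr$count >= min_count
  if (!is.null(min_protein_aa)) {
    keep <- keep & !is.na(arr$max_member_protein_aa) &
      arr$max_member_protein_aa >= min_protein_aa
  }
  kept <- arr[keep, , drop = FALSE]
  new_arrangement_table(kept, total_loci = table$total_loci,
                        curation = list(min_count = as.integer(min_count),
                                        min_protein_aa = min_protein_aa),
                        cumulative_fraction = sum(kept$count) / table$total_loci)
}

#' Group similar arrangements into genetic systems
#'
#' Builds a graph over arrangements with an edge when one cluster set
#' contains the other, or the Jaccard index of the two cluster sets is at
#' least `jaccard_min`; connected components are systems. This
#' operationalises grouping of "highly similar" arrangements sharing a core
#' gene set. The empty arrangement is never grouped (an empty hotspot is a
#' locus state, not a genetic system). The core of a system is the
#' intersection of its members' cluster sets, and variant percentages are
#' member counts as shares of the system total.
#'
#' @param table A curated `arrangement_table`.
#' @param jaccard_min Jaccard threshold for the similarity edge.
#' @return Tibble of class `system_groups`: `system_id`, `core_clusters`
#'   (list), `member_arrangements` (list), `n_arrangements`, `total_count`,
#'   `variant_pct` (list, same order as members), sorted by decreasing
#'   `total_count`.
#' @export
group_systems <- function(table, jaccard_min = 0.5) {
  stopifnot(inherits(table, "arrangement_table"))
  arr <- table$arrangements
  arr <- arr[purrr::map_int(arr$cluster_tuple, length) > 0, , drop = FALSE]
  if (nrow(arr) == 0) {
    out <- tibble(system_id = character(), core_clusters = list(),
                  member_arrangements = list(), n_arrangements = integer(),
                  total_count = integer(), variant_pct = list())
    class(out) <- c("system_groups", class(out))
    return(out)
  }
  sets <- purrr::map(arr$cluster_tuple, unique)
  n <- nrow(arr)
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        a <- sets[[i]]; b <- sets[[j]]
        inter <- length(intersect(a, b))
        contained <- inter == length(a) || inter == length(b)
        jac <- inter / length(union(a, b))
        if (contained || jac >= jaccard_min) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  groups <- purrr::map_dfr(sort(unique(comp)), function(k) {
    ix <- which(comp == k)
    total <- sum(arr$count[ix])
    ord <- ix[order(-arr$count[ix], arr$arrangement_id[ix])]
    tibble(core_clusters = list(Reduce(intersect, sets[ix])),
           member_arrangements = list(arr$arrangement_id[ord]),
           n_arrangements = length(ix),
           total_count = total,
           variant_pct = list(100 * arr$count[ord] / total))
  })
  groups <- groups[order(-groups$total_count,
                         purrr::map_chr(groups$member_arrangements, 1)), ]
  groups$system_id <- sprintf("sys_%03d", seq_len(nrow(groups)))
  out <- groups[, c("system_id", "core_clusters", "member_arrangements",
                    "n_arrangements", "total_count", "variant_pct")]
  class(out) <- c("system_groups", class(out))
  out
}

#' Summary statistics of a mined hotspot family
#'
#' @param loci Locus tibble.
#' @param table The (uncurated) `arrangement_table`.
#' @param systems A `system_groups` tibble.
#' @param top_n Number of most abundant systems to report proportions for
#'   (default 30, mirroring top-30 pie summaries).
#' @return A list of class `hotspot_summary`: `n_loci`, `mean_span_kb`,
#'   `n_arrangements`, `n_systems`, and `top_systems` (tibble `system_id`,
#'   `count`, `proportion` sorted descending).
#' @export
hotspot_summary <- function(loci, table, systems, top_n = 30) {
  stopifnot(nrow(loci) > 0)
  top <- head(systems[order(-systems$total_count), ], top_n)
  top_tbl <- tibble(system_id = top$system_id,
                    count = top$total_count,
                    proportion = top$total_count / nrow(loci))
  structure(list(n_loci = nrow(loci),
                 mean_span_kb = mean(loci$span_bp) / 1000,
                 n_arrangements = nrow(table$arrangements),
                 n_systems = nrow(systems),
                 top_systems = top_tbl),
            class = "hotspot_summary")
}

#' @export
print.hotspot_summary <- function(x, ...) {
  cat(sprintf(paste0("<hotspot_summary> %d loci; mean span %.2f kb; ",
                     "%d arrangements; %d systems\n"),
              x$n_loci, x$mean_span_kb, x$n_arrangements, x$n_systems))
  invisible(x)
}

#' Run the full hotspot-mining pipeline
#'
#' Drives anchor search, locus extraction, cargo clustering, arrangement
#' tallying, curation, system grouping and summary statistics in one call.
#'
#' @param corpus List of [genome_annotation()] objects.
#' @param query Anchor protein string (default: the built-in synthetic
#'   Psu-like anchor).
#' @param config A [mining_config()].
#' @param cluster_config A [clustering_config()].
#' @param min_count,min_protein_aa Curation parameters.
#' @param top_n Top-N size for the summary.
#' @param out_dir Optional directory; when given, every intermediate table
#'   is written there (hits, loci, discards, clusters, arrangements,
#'   curated arrangements, systems, summary JSON).
#' @return A list of class `hotspot_run`: `hits`, `loci`, `discarded`,
#'   `clusters`, `cargo_proteins`, `arrangements`, `curated`, `systems`,
#'   `summary`, `counts` (per-stage log).
#' @export
run_hotspot_mining <- function(corpus, query = synthetic_anchor_protein(),
                               config = mining_config(),
                               cluster_config = clustering_config(),
                               min_count = 5, min_protein_aa = NULL,
                               top_n = 30, out_dir = NULL) {
  query <- unname(query[1])
  hits <- find_anchor_hits(corpus, query, config)
  ext <- extract_loci(corpus, hits, config)
  loci <- ext$loci
  genes <- corpus_genes(corpus)
  protein_of <- setNames(genes$protein, genes$feature_id)
  cargo_ids <- unique(unlist(loci$cargo))
  cargo <- setNames(unname(protein_of[cargo_ids]), cargo_ids)
  clusters <- greedy_cluster(cargo, cluster_config)
  if (nrow(loci) > 0) {
    arr <- tally_arrangements(loci, clusters, proteins = cargo)
    curated <- curate_arrangements(arr, min_count = min_count,
                                   min_protein_aa = min_protein_aa)
    systems <- group_systems(curated)
    summary <- hotspot_summary(loci, arr, systems, top_n = top_n)
  } else {
    arr <- NULL; curated <- NULL; systems <- NULL; summary <- NULL
  }
  counts <- tibble(stage = c("anchor_hits", "loci", "discarded",
                             "cargo_proteins", "clusters", "arrangements",
                             "curated_arrangements", "systems"),
                   n = c(nrow(hits), nrow(loci), nrow(ext$discarded),
                         length(cargo), length(unique(clusters$cluster_id)),
                         if (is.null(arr)) 0L else nrow(arr$arrangements),
                         if (is.null(curated)) 0L else nrow(curated$arrangements),
                         if (is.null(systems)) 0L else nrow(systems)))
  res <- structure(list(hits = hits, loci = loci, discarded = ext$discarded,
                        clusters = clusters, cargo_proteins = cargo,
                        arrangements = arr, curated = curated,
                        systems = systems, summary = summary, counts = counts),
                   class = "hotspot_run")
  if (!is.null(out_dir)) write_hotspot_run(res, out_dir)
  res
}

#' @export
print.hotspot_run <- function(x, ...) {
  cat("<hotspot_run>\n")
  print(x$counts, n = nrow(x$counts))
  invisible(x)
}

#' Write every artifact of a mining run to a directory
#'
#' @param run A `hotspot_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hotspot_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(run$hits, file.path(dir, "anchor_hits.tsv"))
  write_loci(run$loci, file.path(dir, "loci.tsv"))
  write_table(run$discarded, file.path(dir, "discarded.tsv"))
  write_clusters(run$clusters, file.path(dir, "clusters.tsv"))
  if (length(run$cargo_proteins) > 0) {
    write_protein_fasta(run$cargo_proteins, file.path(dir, "cargo.faa"))
  }
  if (!is.null(run$arrangements)) {
    write_arrangements(run$arrangements, file.path(dir, "arrangements.tsv"))
    write_arrangements(run$curated, file.path(dir, "arrangements_curated.tsv"))
    write_table(tidy(run$systems), file.path(dir, "systems.tsv"))
    jsonlite::write_json(summary_to_list(run$summary),
                         file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_table(run$counts, file.path(dir, "stage_counts.tsv"))
  invisible(dir)
}

summary_to_list <- function(s) {
  list(n_loci = s$n_loci, mean_span_kb = s$mean_span_kb,
       n_arrangements = s$n_arrangements, n_systems = s$n_systems,
       top_systems = as.data.frame(s$top_systems))
}
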