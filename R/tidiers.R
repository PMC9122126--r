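# broom-style tidiers for the pipeline's result objects.

#' Tidy an arrangement table
#'
#' @param x An `arrangement_table`.
#' @param ... Unused.
#' @return Tibble with one row per arrangement: `arrangement_id`,
#'   `cluster_tuple` (list), `count`, `frequency` (count / total loci),
#'   `max_member_protein_aa`, `locus_ids` (list).
#' @export
tidy.arrangement_table <- function(x, ...) {
  arr <- x$arrangements
  tibble(arrangement_id = arr$arrangement_id,
         cluster_tuple = arr$cluster_tuple,
         count = arr$count,
         frequency = arr$count / x$total_loci,
         max_member_protein_aa = arr$max_member_protein_aa,
         locus_ids = arr$locus_ids)
}

#' One-row summary of an arrangement table
#'
#' @param x An `arrangement_table`.
#' @param ... Unused.
#' @return One-row tibble: `n_arrangements`, `total_loci`,
#'   `cumulative_fraction`, `min_count`, `min_protein_aa`.
#' @export
glance.arrangement_table <- function(x, ...) {
  tibble(n_arrangements = nrow(x$arrangements),
         total_loci = x$total_loci,
         cumulative_fraction = x$cumulative_fraction,
         min_count = if (is.null(x$curation)) NA_integer_ else x$curation$min_count,
         min_protein_aa = if (is.null(x$curation) ||
                                is.null(x$curation$min_protein_aa))
           NA_integer_ else as.integer(x$curation$min_protein_aa))
}

#' Tidy a system-group table
#'
#' @param x A `system_groups` tibble.
#' @param ... Unused.
#' @return Tibble with list-columns flattened to `";"`-joined strings,
#'   suitable for TSV export.
#' @export
tidy.system_groups <- function(x, ...) {
  tibble(system_id = x$system_id,
         core_clusters = purrr::map_chr(x$core_clusters, paste, collapse = ";"),
         member_arrangements = purrr::map_chr(x$member_arrangements,
                                              paste, collapse = ";"),
         n_arrangements = x$n_arrangements,
         total_count = x$total_count,
         variant_pct = purrr::map_chr(x$variant_pct,
                                      ~ paste(sprintf("%.1f", .x), collapse = ";")))
}

#' One-row summary of a hotspot mining run
#'
#' @param x A `hotspot_run`.
#' @param ... Unused.
#' @return One-row tibble of the per-stage counts plus mean span.
#' @export
glance.hotspot_run <- function(x, ...) {
  n <- setNames(as.list(x$counts$n), x$counts$stage)
  tibble(n_anchor_hits = n$anchor_hits, n_loci = n$loci,
         n_discarded = n$discarded, n_clusters = n$clusters,
         n_arrangements = n$arrangements,
         n_curated = n$curated_arrangements, n_systems = n$systems,
         mean_span_kb = if (is.null(x$summary)) NA_real_ else
           x$summary$mean_span_kb)
}

#' One-row summary of a recovery report
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return One-row tibble of all report fields.
#' @export
glance.recovery_report <- function(x, ...) {
  as_tibble(x[c("n_true_loci", "n_recovered_loci", "locus_precision",
                "locus_recall", "cluster_family_ari", "arrangement_exact",
                "detection_precision", "detection_recall")])
}

#' One-row summary of a prevalence result
#'
#' @param x A `system_prevalence`.
#' @param ... Unused.
#' @return One-row tibble: `prevalence`, `n_genomes`, `n_positive`,
#'   `n_two_gene`, `n_fused` (genomes per variant).
#' @export
glance.system_prevalence <- function(x, ...) {
  bv <- setNames(as.list(x$by_variant$n_genomes), x$by_variant$variant)
  tibble(prevalence = x$prevalence, n_genomes = x$n_genomes,
         n_positive = x$n_positive,
         n_two_gene = bv$two_gene %||% 0L,
         n_fused = bv$fused %||% 0L)
}
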