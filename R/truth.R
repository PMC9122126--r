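# Scoring a pipeline run against the planted truth: locus-level
# precision/recall, cluster-vs-family agreement, exact recovery of the
# arrangement frequency table, and detection performance for planted
# labelled systems.

#' Evaluate a mining run against the planted-truth ledger
#'
#' Loci are matched by their (anchor, closer) feature-id pair; split loci
#' are excluded from the truth set (the pipeline discards them by
#' construction). Cluster-vs-family agreement is the adjusted Rand index
#' over all planted cargo proteins present in both partitions. The
#' arrangement table is compared exactly after mapping each recovered
#' cluster to a planted family by majority membership. When detection
#' `hits` are supplied, genome-level precision/recall is reported for
#' genomes planted with a labelled (detectable) system.
#'
#' @param run A `hotspot_run` from [run_hotspot_mining()].
#' @param ledger The matching `truth_ledger`.
#' @param hits Optional detection hits tibble from [detect_corpus()].
#' @return A list of class `recovery_report`: `n_true_loci` (non-split),
#'   `n_recovered_loci`, `locus_precision`, `locus_recall`,
#'   `cluster_family_ari`, `arrangement_exact`, `detection_precision`,
#'   `detection_recall`.
#' @export
evaluate_against_truth <- function(run, ledger, hits = NULL) {
  stopifnot(inherits(ledger, "truth_ledger"))
  truth <- ledger$loci[!ledger$loci$split, , drop = FALSE]
  truth_keys <- paste(truth$anchor_id, truth$closer_id, sep = "|")
  rec_keys <- paste(run$loci$anchor, run$loci$closer, sep = "|")
  tp <- sum(rec_keys %in% truth_keys)
  locus_precision <- if (length(rec_keys) == 0) NA_real_ else tp / length(rec_keys)
  locus_recall <- if (length(truth_keys) == 0) NA_real_ else tp / length(truth_keys)

  # cluster-vs-family agreement over proteins present in both partitions
  fam_of <- setNames(ledger$membership$family_id, ledger$membership$feature_id)
  clu <- run$clusters
  common <- intersect(clu$protein_id, names(fam_of))
  ari <- if (length(common) == 0) NA_real_ else {
    clu_of <- setNames(clu$cluster_id, clu$protein_id)
    unname(mclust::adjustedRandIndex(clu_of[common], fam_of[common]))
  }

  arrangement_exact <- arrangement_tables_match(run, ledger)

  detection_precision <- NA_real_
  detection_recall <- NA_real_
  if (!is.null(hits)) {
    truth_genomes <- unique(ledger$loci$genome_id[
      ledger$loci$system_id %in% ledger$labeled_systems])
    det_genomes <- unique(hits$genome_id)
    dtp <- sum(det_genomes %in% truth_genomes)
    detection_precision <- if (length(det_genomes) == 0) NA_real_ else
      dtp / length(det_genomes)
    detection_recall <- if (length(truth_genomes) == 0) NA_real_ else
      dtp / length(truth_genomes)
  }
  structure(list(n_true_loci = nrow(truth),
                 n_recovered_loci = nrow(run$loci),
                 locus_precision = locus_precision,
                 locus_recall = locus_recall,
                 cluster_family_ari = ari,
                 arrangement_exact = arrangement_exact,
                 detection_precision = detection_precision,
                 detection_recall = detection_recall),
            class = "recovery_report")
}

# Majority-vote cluster -> family map, then exact multiset comparison of
# the recovered arrangement table with the ledger expectation.
arrangement_tables_match <- function(run, ledger) {
  if (is.null(run$arrangements)) return(nrow(ledger$expected_arrangements) == 0)
  fam_of <- setNames(ledger$membership$family_id, ledger$membership$feature_id)
  clu <- run$clusters
  clu$family <- unname(fam_of[clu$protein_id])
  if (any(is.na(clu$family)) && nrow(clu) > 0) return(FALSE)
  vote <- clu |>
    group_by(.data$cluster_id, .data$family) |>
    summarise(nv = n(), .groups = "drop_last") |>
    arrange(desc(.data$nv), .data$family) |>
    dplyr::slice(1) |>
    ungroup()
  map <- setNames(vote$family, vote$cluster_id)
  arr <- run$arrangements$arrangements
  rec_keys <- purrr::map_chr(arr$cluster_tuple, function(tt) {
    paste(unname(map[tt]), collapse = TUPLE_SEP)
  })
  rec <- tibble(key = rec_keys, count = arr$count) |>
    group_by(.data$key) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$key)
  exp <- ledger$expected_arrangements |> arrange(.data$key)
  isTRUE(all.equal(as.data.frame(rec), as.data.frame(exp),
                   check.attributes = FALSE))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("<recovery_report> loci P=%.3f R=%.3f (n=%d); ",
                     "ARI=%.3f; arrangements exact: %s\n"),
              x$locus_precision, x$locus_recall, x$n_true_loci,
              x$cluster_family_ari, x$arrangement_exact))
  if (!is.na(x$detection_precision)) {
    cat(sprintf("  detection P=%.3f R=%.3f\n",
                x$detection_precision, x$detection_recall))
  }
  invisible(x)
}
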