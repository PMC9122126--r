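# Greedy incremental protein clustering with a bidirectional coverage
# constraint (both sequences must be covered >= min_coverage by the optimal
# local alignment) plus an identity floor. Mirrors the canonical
# longest-first incremental scheme: each sequence joins the FIRST existing
# representative it matches, else founds a new cluster.

#' Clustering configuration
#'
#' @param min_coverage Minimum alignment coverage required of BOTH
#'   sequences (default 0.6, the published coverage threshold).
#' @param min_identity Minimum identity over aligned columns (default 0.3;
#'   an identity floor is needed because coverage alone would merge
#'   unrelated same-length proteins).
#' @param matrix,gap_open,gap_extend Alignment parameters, shared with
#'   [mining_config()].
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(min_coverage = 0.6, min_identity = 0.3,
                              matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1)
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = 0.267, karlin_K = 0.041),
            class = "clustering_config")
}

cluster_pair_ok <- function(aln, config) {
  aln$query_cov >= config$min_coverage &&
    aln$target_cov >= config$min_coverage &&
    aln$identity >= config$min_identity
}

# Processing order: decreasing length, ties by id. Fixed internally so the
# partition is invariant to input order.
cluster_order <- function(proteins) {
  ids <- names(proteins)
  ids[order(-nchar(proteins), ids)]
}

#' Greedy incremental clustering of proteins
#'
#' Sequences are processed longest-first (ties by id). Each sequence joins
#' the first existing cluster (in foundation order) whose representative it
#' matches with coverage of both sequences at least `min_coverage` and
#' identity at least `min_identity` under exact local alignment; otherwise
#' it founds a new cluster. Representatives are therefore the longest
#' member of each cluster. Pairs whose length ratio is below `min_coverage`
#' are skipped without aligning: the local footprint cannot exceed the
#' shorter sequence, so bidirectional coverage is impossible (an exact
#' pruning, not a heuristic).
#'
#' @param proteins Named character vector (id -> amino-acid string).
#' @param config A [clustering_config()].
#' @return Tibble of class `protein_clusters`: `protein_id`, `cluster_id`,
#'   `representative_id`. Cluster ids `cl_0001`, ... are assigned in
#'   foundation order.
#' @export
greedy_cluster <- function(proteins, config = clustering_config()) {
  if (length(proteins) == 0) {
    return(new_protein_clusters(tibble(protein_id = character(),
                                       cluster_id = character(),
                                       representative_id = character())))
  }
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    abort("proteins must be a named vector")
  }
  if (anyDuplicated(names(proteins))) {
    abort(paste0("duplicate protein id: ",
                 names(proteins)[duplicated(names(proteins))][1]))
  }
  stopifnot(all(nchar(proteins) >= 1))
  ord <- cluster_order(proteins)
  reps <- character()     # representative ids in foundation order
  assignment <- character(length(ord))
  names(assignment) <- ord
  mcfg <- list(matrix = config$matrix, gap_open = config$gap_open,
               gap_extend = config$gap_extend,
               karlin_lambda = config$karlin_lambda, karlin_K = config$karlin_K)
  for (id in ord) {
    seq <- proteins[[id]]
    placed <- NA_character_
    for (rep_id in reps) {
      rep_seq <- proteins[[rep_id]]
      lr <- min(nchar(seq), nchar(rep_seq)) / max(nchar(seq), nchar(rep_seq))
      if (lr < config$min_coverage) next
      aln <- local_align(seq, rep_seq, config = mcfg)
      if (cluster_pair_ok(aln, config)) {
        placed <- rep_id
        break
      }
    }
    if (is.na(placed)) {
      reps <- c(reps, id)
      assignment[id] <- id
    } else {
      assignment[id] <- placed
    }
  }
  finish_clusters(assignment, reps)
}

finish_clusters <- function(assignment, reps) {
  cluster_ids <- setNames(sprintf("cl_%04d", seq_along(reps)), reps)
  out <- tibble(protein_id = names(assignment),
                cluster_id = unname(cluster_ids[unname(assignment)]),
                representative_id = unname(assignment))
  new_protein_clusters(out[order(out$cluster_id, out$protein_id), ])
}

new_protein_clusters <- function(df) {
  class(df) <- c("protein_clusters", class(df))
  df
}

#' Reference clustering oracle via exhaustive all-pairs alignment
#'
#' Executes the same greedy policy as [greedy_cluster()], but from a
#' precomputed table of all pairwise alignments (no pruning, no on-demand
#' alignment). Intended as a correctness oracle on small inputs; it must
#' produce exactly the same partition as [greedy_cluster()].
#'
#' @param proteins Named character vector (at most 200 sequences).
#' @param config A [clustering_config()].
#' @return Tibble of class `protein_clusters`.
#' @export
cluster_oracle <- function(proteins, config = clustering_config()) {
  if (length(proteins) > 200) abort("cluster_oracle is capped at 200 proteins")
  if (length(proteins) == 0) return(greedy_cluster(proteins, config))
  if (anyDuplicated(names(proteins))) abort("duplicate protein id")
  ids <- names(proteins)
  mcfg <- list(matrix = config$matrix, gap_open = config$gap_open,
               gap_extend = config$gap_extend,
               karlin_lambda = config$karlin_lambda, karlin_K = config$karlin_K)
  ok <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  # ordered pairs are aligned directly (not mirrored) so the decision seen
  # by the greedy pass is reproduced exactly, byte for byte
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) { ok[i, j] <- TRUE; next }
      aln <- local_align(proteins[[i]], proteins[[j]], config = mcfg)
      ok[i, j] <- cluster_pair_ok(aln, config)
    }
  }
  ord <- cluster_order(proteins)
  reps <- character()
  assignment <- character(length(ord))
  names(assignment) <- ord
  for (id in ord) {
    hit <- reps[ok[id, reps]]
    if (length(hit) == 0) {
      reps <- c(reps, id)
      assignment[id] <- id
    } else {
      assignment[id] <- hit[1]
    }
  }
  finish_clusters(assignment, reps)
}

#' Summarise clusters
#'
#' @param clusters A `protein_clusters` tibble.
#' @return Tibble with one row per cluster: `cluster_id`,
#'   `representative_id`, `n_members`.
#' @export
cluster_summary <- function(clusters) {
  clusters |>
    group_by(.data$cluster_id, .data$representative_id) |>
    summarise(n_members = n(), .groups = "drop") |>
    arrange(.data$cluster_id)
}
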