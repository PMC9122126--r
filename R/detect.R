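# Quorum/loner co-localization detection of multi-gene defense systems from
# per-protein domain-profile bit scores: a hit requires every component of
# the model to be present within a gene-spacing limit (two-gene quorum), or
# a single fused gene carrying a fusion profile above threshold (loner).

#' Declarative system model for co-localization detection
#'
#' @param model_id Model name.
#' @param components Named list, one entry per required component; each is a
#'   named numeric vector of accepted profiles and their score thresholds
#'   (a gene satisfies the component if ANY accepted profile scores at or
#'   above its threshold).
#' @param fusion_profiles Named numeric vector of fusion profiles and
#'   thresholds: a single gene at or above a fusion threshold satisfies the
#'   model alone.
#' @param loner_allowed_for_fusion Whether a fused gene counts anywhere on
#'   the genome, with no co-localization requirement (default `TRUE`).
#' @param max_intervening_genes Maximum number of genes strictly between
#'   two component genes of a quorum hit (default 2).
#' @return A list of class `system_model`.
#' @export
system_model <- function(model_id, components, fusion_profiles = numeric(),
                         loner_allowed_for_fusion = TRUE,
                         max_intervening_genes = 2) {
  stopifnot(length(components) >= 1,
            all(purrr::map_lgl(components, ~ all(.x > 0))),
            all(fusion_profiles > 0), max_intervening_genes >= 0)
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    abort("components must be a named list")
  }
  structure(list(model_id = model_id, components = components,
                 fusion_profiles = fusion_profiles,
                 loner_allowed_for_fusion = isTRUE(loner_allowed_for_fusion),
                 max_intervening_genes = as.integer(max_intervening_genes)),
            class = "system_model")
}

#' The PARIS (ariAB) detection model
#'
#' Two-gene quorum: an ATPase component satisfied by AAA_15 >= 32 or
#' AAA_21 >= 27, and a partner component satisfied by DUF4435 >= 27, at
#' most `max_intervening_genes` genes apart. Single-gene fusions
#' (`AAA_15+DUF4435` >= 80 or `AAA_21+DUF4435` >= 20) satisfy the model
#' alone, anywhere on the genome (loner). Thresholds are compared
#' inclusively.
#'
#' @param max_intervening_genes Spacing limit for the two-gene variant.
#' @return A [system_model()].
#' @export
paris_model <- function(max_intervening_genes = 2) {
  system_model(
    model_id = "PARIS",
    components = list(
      atpase = c(AAA_15 = 32, AAA_21 = 27),
      partner = c(DUF4435 = 27)),
    fusion_profiles = c(`AAA_15+DUF4435` = 80, `AAA_21+DUF4435` = 20),
    loner_allowed_for_fusion = TRUE,
    max_intervening_genes = max_intervening_genes)
}

#' Read a system model from JSON
#'
#' The JSON schema mirrors [system_model()]: fields `model_id`,
#' `components` (object of objects `profile -> threshold`),
#' `fusion_profiles`, `loner_allowed_for_fusion`, `max_intervening_genes`.
#'
#' @param path JSON file.
#' @return A [system_model()].
#' @export
read_system_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  system_model(model_id = x$model_id,
               components = lapply(x$components, unlist),
               fusion_profiles = unlist(x$fusion_profiles) %||% numeric(),
               loner_allowed_for_fusion = x$loner_allowed_for_fusion %||% TRUE,
               max_intervening_genes = x$max_intervening_genes %||% 2)
}

#' Write a system model to JSON
#'
#' @param model A [system_model()].
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_system_model <- function(model, path) {
  jsonlite::write_json(list(model_id = model$model_id,
                            components = lapply(model$components, as.list),
                            fusion_profiles = as.list(model$fusion_profiles),
                            loner_allowed_for_fusion = model$loner_allowed_for_fusion,
                            max_intervening_genes = model$max_intervening_genes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a domain-profile score table
#'
#' @param path TSV with header columns `feature_id`, `profile_name`,
#'   `bit_score`. Duplicate (feature, profile) rows keep the maximum score
#'   with a warning.
#' @return Tibble with one row per (feature, profile).
#' @export
load_scores <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("feature_id", "profile_name", "bit_score")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("score table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(raw) > 0 && !is.numeric(raw$bit_score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$bit_score))))[1]
    abort(sprintf("non-numeric bit_score at line %d", bad + 1L))
  }
  if (nrow(raw) == 0) {
    return(tibble(feature_id = character(), profile_name = character(),
                  bit_score = numeric()))
  }
  dup <- duplicated(raw[, c("feature_id", "profile_name")])
  if (any(dup)) {
    warn(sprintf("%d duplicate (feature, profile) rows: keeping max score",
                 sum(dup)))
    raw <- raw |>
      group_by(.data$feature_id, .data$profile_name) |>
      summarise(bit_score = max(.data$bit_score), .groups = "drop")
  }
  as_tibble(raw[, need])
}

# score lookup: max score of a feature over a set of accepted profiles;
# features with no row score -Inf.
profile_pass <- function(scores, profiles) {
  hits <- scores[scores$profile_name %in% names(profiles), , drop = FALSE]
  if (nrow(hits) == 0) return(character())
  thr <- profiles[hits$profile_name]
  unique(hits$feature_id[hits$bit_score >= thr])
}

#' Detect system occurrences in one genome
#'
#' A gene satisfies a component if any accepted profile scores at or above
#' its threshold (inclusive comparison); a quorum hit is a set of genes on
#' one contig covering all components, assigned to distinct genes, with at
#' most `max_intervening_genes` genes strictly between consecutive
#' component genes. A fused hit is a single gene at or above a fusion
#' threshold, anywhere on the genome when the model allows loners. All
#' maximal non-overlapping hits are reported: candidates are ordered by
#' (contig, leftmost gene index, rightmost gene index, variant with fused
#' first) and accepted greedily, each gene participating in at most one
#' hit.
#'
#' @param genome A [genome_annotation()].
#' @param scores Score tibble from [load_scores()] (features absent from
#'   the table score -Inf everywhere).
#' @param model A [system_model()].
#' @return Tibble: `genome_id`, `contig_id`, `variant` (`"two_gene"` or
#'   `"fused"`), one `feature_<component>` column per component plus
#'   `feature_fused`, and `spacing` (intervening gene count; `NA` for
#'   fused hits).
#' @export
detect_systems <- function(genome, scores, model) {
  genes <- corpus_genes(list(genome))
  out <- empty_hits_table(model)
  if (nrow(genes) == 0) return(out)
  comp_pass <- lapply(model$components, profile_pass, scores = scores)
  fused_pass <- profile_pass(scores, model$fusion_profiles)
  cand <- list()
  for (cid in unique(genes$contig_id)) {
    cg <- genes[genes$contig_id == cid, , drop = FALSE]
    idx_of <- setNames(cg$gene_index, cg$feature_id)
    # fused singletons (emitted standalone only when the model allows loners)
    for (f in if (model$loner_allowed_for_fusion)
                intersect(cg$feature_id, fused_pass) else character()) {
      cand[[length(cand) + 1L]] <- list(contig = cid, left = idx_of[[f]],
                                        right = idx_of[[f]], variant = "fused",
                                        features = c(fused = f),
                                        spacing = NA_integer_)
    }
    # quorum combinations
    comp_idx <- lapply(comp_pass, function(ids) sort(idx_of[intersect(cg$feature_id, ids)]))
    if (all(purrr::map_int(comp_idx, length) > 0)) {
      combos <- expand.grid(lapply(comp_idx, as.integer),
                            KEEP.OUT.ATTRS = FALSE)
      names(combos) <- names(model$components)
      for (r in seq_len(nrow(combos))) {
        ix <- as.integer(combos[r, ])
        if (anyDuplicated(ix)) next
        ord <- sort(ix)
        gaps <- diff(ord) - 1L
        if (any(gaps > model$max_intervening_genes)) next
        feats <- setNames(cg$feature_id[match(ix, cg$gene_index)],
                          names(model$components))
        cand[[length(cand) + 1L]] <- list(contig = cid, left = min(ix),
                                          right = max(ix), variant = "two_gene",
                                          features = feats,
                                          spacing = max(ix) - min(ix) - 1L)
      }
    }
  }
  if (length(cand) == 0) return(out)
  ord <- order(purrr::map_chr(cand, "contig"),
               purrr::map_int(cand, ~ as.integer(.x$left)),
               purrr::map_int(cand, ~ as.integer(.x$right)),
               purrr::map_chr(cand, "variant"))
  used <- character()
  rows <- list()
  for (k in ord) {
    cc <- cand[[k]]
    if (any(cc$features %in% used)) next
    used <- c(used, cc$features)
    row <- tibble(genome_id = genome$genome_id, contig_id = cc$contig,
                  variant = cc$variant, spacing = cc$spacing)
    for (comp in names(model$components)) {
      row[[paste0("feature_", comp)]] <-
        if (cc$variant == "two_gene") unname(cc$features[comp]) else NA_character_
    }
    row$feature_fused <- if (cc$variant == "fused") unname(cc$features[["fused"]])
                         else NA_character_
    rows[[length(rows) + 1L]] <- row
  }
  bind_rows(rows)[, names(out)]
}

empty_hits_table <- function(model) {
  cols <- c("genome_id", "contig_id", "variant", "spacing",
            paste0("feature_", names(model$components)), "feature_fused")
  out <- tibble(genome_id = character(), contig_id = character(),
                variant = character(), spacing = integer())
  for (comp in names(model$components)) out[[paste0("feature_", comp)]] <- character()
  out$feature_fused <- character()
  out[, cols]
}

#' Detect system occurrences across a corpus
#'
#' @param corpus List of [genome_annotation()] objects.
#' @param scores Score tibble from [load_scores()].
#' @param model A [system_model()].
#' @return Tibble of hits over all genomes (see [detect_systems()]).
#' @export
detect_corpus <- function(corpus, scores, model) {
  purrr::map_dfr(corpus, detect_systems, scores = scores, model = model)
}

#' Corpus prevalence of a system
#'
#' Fraction of genomes carrying at least one hit, with a per-variant
#' breakdown (a genome counts once per variant it carries).
#'
#' @param corpus List of [genome_annotation()] objects.
#' @param scores Score tibble.
#' @param model A [system_model()].
#' @return A list of class `system_prevalence`: `prevalence`, `n_genomes`,
#'   `n_positive`, `by_variant` (tibble), `hits`.
#' @export
system_prevalence <- function(corpus, scores, model) {
  stopifnot(length(corpus) > 0)
  hits <- detect_corpus(corpus, scores, model)
  n_pos <- length(unique(hits$genome_id))
  by_var <- hits |>
    distinct(.data$genome_id, .data$variant) |>
    group_by(.data$variant) |>
    summarise(n_genomes = n(), .groups = "drop")
  structure(list(prevalence = n_pos / length(corpus),
                 n_genomes = length(corpus), n_positive = n_pos,
                 by_variant = by_var, hits = hits),
            class = "system_prevalence")
}

#' @export
print.system_prevalence <- function(x, ...) {
  cat(sprintf("<system_prevalence> %.1f%% (%d/%d genomes)\n",
              100 * x$prevalence, x$n_positive, x$n_genomes))
  invisible(x)
}
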