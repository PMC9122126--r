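# Exact affine-gap Smith-Waterman local alignment over BLOSUM matrices,
# with Karlin-Altschul E-values. This is the search primitive behind anchor
# mining and protein clustering; a gap of length k costs
# gap_open + k * gap_extend (BLAST's existence/extension convention).

align_env <- new.env(parent = emptyenv())

#' Fetch a substitution matrix by name
#'
#' Returns the named BLOSUM/PAM matrix shipped with Biostrings, restricted
#' to the 20 standard residues plus `X`, with all scores involving `X`
#' set to 0 (neutral ambiguity).
#'
#' @param name Matrix name, e.g. `"BLOSUM62"`.
#' @return Numeric matrix with dimnames over the 21-letter alphabet.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  key <- paste0("sub_", name)
  if (!is.null(align_env[[key]])) return(align_env[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  full <- e[[name]]
  alpha <- c(aa_alphabet(), "X")
  m <- matrix(0, nrow = length(alpha), ncol = length(alpha),
              dimnames = list(alpha, alpha))
  std <- aa_alphabet()
  m[std, std] <- full[std, std]
  m["X", ] <- 0
  m[, "X"] <- 0
  align_env[[key]] <- m
  m
}

# Encode an amino-acid string as 0-based integer codes into the matrix rows.
encode_protein <- function(seq, what = "sequence") {
  check_protein(seq, what)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  match(chars, c(aa_alphabet(), "X")) - 1L
}

#' Exact local alignment of two proteins
#'
#' Computes the optimal affine-gap Smith-Waterman alignment and summary
#' statistics: the raw score (exact optimum of the recurrence, floored at 0
#' by the empty alignment), the bit score and E-value under Karlin-Altschul
#' statistics, coverages of each sequence by the optimal local footprint,
#' and identity over aligned columns (gap columns included in the
#' denominator).
#'
#' @param query,target Amino-acid strings (standard 20 letters plus `X`,
#'   which scores 0 against everything).
#' @param config A [mining_config()] supplying matrix, gap penalties and
#'   Karlin-Altschul parameters.
#' @param db_residues Effective database size in residues for the E-value;
#'   defaults to the target length.
#' @param query_id,target_id Optional labels.
#' @return One-row tibble: `query_id`, `target_id`, `raw_score`,
#'   `bit_score`, `evalue`, `query_cov`, `target_cov`, `identity`.
#' @export
local_align <- function(query, target, config = mining_config(),
                        db_residues = nchar(target),
                        query_id = "query", target_id = "target") {
  stopifnot(nchar(query) >= 1, nchar(target) >= 1)
  q <- encode_protein(query, "query")
  t <- encode_protein(target, "target")
  m <- substitution_matrix(config$matrix)
  res <- sw_align_cpp(q, t, m, config$gap_open, config$gap_extend)
  qlen <- nchar(query); tlen <- nchar(target)
  qcov <- if (is.na(res$q_start)) 0 else (res$q_end - res$q_start + 1) / qlen
  tcov <- if (is.na(res$t_start)) 0 else (res$t_end - res$t_start + 1) / tlen
  ident <- if (res$columns == 0) 0 else res$matches / res$columns
  tibble(query_id = query_id, target_id = target_id,
         raw_score = res$score,
         bit_score = (config$karlin_lambda * res$score - log(config$karlin_K)) / log(2),
         evalue = estimate_evalue(res$score, qlen, db_residues, config),
         query_cov = qcov, target_cov = tcov, identity = ident)
}

#' Karlin-Altschul E-value for a raw local-alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' database residue count. Monotone decreasing in `S`; at `S = 0` it equals
#' `K * m * n`.
#'
#' @param raw_score Raw Smith-Waterman score (>= 0).
#' @param query_len Query length in residues.
#' @param db_residues Database size in residues.
#' @param config A [mining_config()] supplying `karlin_lambda`, `karlin_K`.
#' @return E-value (numeric).
#' @export
estimate_evalue <- function(raw_score, query_len, db_residues,
                            config = mining_config()) {
  stopifnot(all(raw_score >= 0))
  config$karlin_K * query_len * db_residues *
    exp(-config$karlin_lambda * raw_score)
}

# Minimum raw score whose E-value is <= evalue_max (smallest integer S).
score_cutoff <- function(query_len, db_residues, config) {
  s <- log(config$karlin_K * query_len * db_residues / config$evalue_max) /
    config$karlin_lambda
  max(0, ceiling(s))
}

# Bulk raw scores of one query against many targets (no traceback).
sw_scores <- function(query, targets, config) {
  q <- encode_protein(query, "query")
  enc <- lapply(targets, encode_protein)
  m <- substitution_matrix(config$matrix)
  as.numeric(sw_score_block_cpp(q, enc, m, config$gap_open, config$gap_extend))
}
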