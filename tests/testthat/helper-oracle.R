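# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the alignment oracle is a closed-form quadratic
# DP over full score matrices (scan/cummax formulation), and the detection
# oracle is a plain brute-force enumeration.

# Exact affine-gap Smith-Waterman score; gap of length k costs
# gap_open + k * gap_extend. Row-vectorised: the gap states are computed in
# closed form, ix[i][j] = max_{k<j} (m[i][k] - open - (j-k)*ext) via a
# cumulative max, and symmetrically for iy via a running column max.
oracle_sw_score <- function(query, target, submat = NULL,
                            gap_open = 11, gap_extend = 1) {
  if (is.null(submat)) submat <- substitution_matrix("BLOSUM62")
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  m <- length(qc); n <- length(tc)
  cols <- n + 1L                      # index j+1 holds column j (0..n)
  Mprev <- rep(0, cols)
  IXprev <- rep(-Inf, cols)
  IYprev <- rep(-Inf, cols)
  B <- Mprev                          # max_r (M[r][j] + r*ext), r <= i-1
  best <- 0
  jj <- seq_len(n)
  for (i in seq_len(m)) {
    s <- submat[qc[i], tc]
    diag_best <- pmax(Mprev[jj], IXprev[jj], IYprev[jj])
    Mcur <- c(0, pmax(0, diag_best + s))
    IYcur <- c(-Inf, (B - gap_open - i * gap_extend)[jj + 1L])
    A <- Mcur + (0:n) * gap_extend
    IXcur <- c(-Inf, cummax(A)[jj] - gap_open - jj * gap_extend)
    B <- pmax(B, Mcur + i * gap_extend)
    best <- max(best, Mcur)
    Mprev <- Mcur; IXprev <- IXcur; IYprev <- IYcur
  }
  best
}

# Brute-force co-localization detection: enumerate every fused singleton and
# every assignment of distinct genes to model components, filter by spacing,
# then apply the same deterministic greedy acceptance order the detector
# documents (contig, leftmost index, rightmost index, variant "fused" first).
oracle_detect <- function(genome, scores, model) {
  genes <- corpus_genes(list(genome))
  if (nrow(genes) == 0) return(detect_systems(genome, scores, model)[0, ])
  pass_gene <- function(fid, profiles) {
    rows <- scores[scores$feature_id == fid &
                     scores$profile_name %in% names(profiles), , drop = FALSE]
    if (nrow(rows) == 0) return(FALSE)
    any(rows$bit_score >= profiles[rows$profile_name])
  }
  cand <- list()
  for (cid in unique(genes$contig_id)) {
    cg <- genes[genes$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(cg))) {
      if (model$loner_allowed_for_fusion &&
          pass_gene(cg$feature_id[i], model$fusion_profiles)) {
        cand[[length(cand) + 1L]] <- list(
          contig = cid, left = i, right = i, variant = "fused",
          features = c(fused = cg$feature_id[i]), spacing = NA_integer_)
      }
    }
    comp_names <- names(model$components)
    sat <- lapply(model$components, function(profs) {
      which(vapply(cg$feature_id, pass_gene, TRUE, profiles = profs))
    })
    if (all(lengths(sat) > 0)) {
      grid <- expand.grid(sat, KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid))) {
        ix <- as.integer(grid[r, ])
        if (anyDuplicated(ix)) next
        ord <- sort(ix)
        if (any(diff(ord) - 1L > model$max_intervening_genes)) next
        cand[[length(cand) + 1L]] <- list(
          contig = cid, left = min(ix), right = max(ix), variant = "two_gene",
          features = setNames(cg$feature_id[ix], comp_names),
          spacing = max(ix) - min(ix) - 1L)
      }
    }
  }
  template <- detect_systems(genome, scores, model)[0, ]
  if (length(cand) == 0) return(template)
  ord <- order(vapply(cand, `[[`, "", "contig"),
               vapply(cand, function(x) as.integer(x$left), 1L),
               vapply(cand, function(x) as.integer(x$right), 1L),
               vapply(cand, `[[`, "", "variant"))
  used <- character()
  rows <- list()
  for (k in ord) {
    cc <- cand[[k]]
    if (any(cc$features %in% used)) next
    used <- c(used, cc$features)
    row <- tibble::tibble(genome_id = genome$genome_id, contig_id = cc$contig,
                          variant = cc$variant, spacing = cc$spacing)
    for (comp in names(model$components)) {
      row[[paste0("feature_", comp)]] <-
        if (cc$variant == "two_gene") unname(cc$features[comp]) else NA_character_
    }
    row$feature_fused <- if (cc$variant == "fused")
      unname(cc$features[["fused"]]) else NA_character_
    rows[[length(rows) + 1L]] <- row
  }
  dplyr::bind_rows(rows)[, names(template)]
}

# Random protein pairs for aligner property tests.
random_pairs <- function(n_pairs, max_len = 120, min_len = 10) {
  lapply(seq_len(n_pairs), function(i) {
    list(q = random_protein(sample(min_len:max_len, 1)),
         t = random_protein(sample(min_len:max_len, 1)))
  })
}

# Random protein set mixing planted families and unrelated singletons, for
# clustering equivalence fixtures.
random_cluster_fixture <- function(n_families = 4, members = 3,
                                   n_singletons = 6, divergence = 0.15,
                                   len_range = c(40, 120)) {
  prot <- character()
  for (f in seq_len(n_families)) {
    ref <- random_protein(sample(len_range[1]:len_range[2], 1))
    for (k in seq_len(members)) {
      prot[sprintf("fam%02d_m%02d", f, k)] <- mutate_protein(ref, divergence)
    }
  }
  for (s in seq_len(n_singletons)) {
    prot[sprintf("single%02d", s)] <-
      random_protein(sample(len_range[1]:len_range[2], 1))
  }
  prot
}
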