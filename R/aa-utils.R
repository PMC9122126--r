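# Amino-acid alphabet helpers and the protein mutation/generation primitives
# used throughout the synthetic corpus.

#' The 20 standard amino acids
#'
#' @return Character vector of one-letter codes in alphabetical order.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Robinson & Robinson-style background amino-acid frequencies, renormalised
# over the 20 standard residues. Used for decoy and reference proteins.
aa_background <- function() {
  p <- c(A = 0.082, C = 0.014, D = 0.054, E = 0.067, F = 0.039, G = 0.071,
         H = 0.023, I = 0.059, K = 0.058, L = 0.097, M = 0.024, N = 0.041,
         P = 0.047, Q = 0.039, R = 0.055, S = 0.066, T = 0.053, V = 0.069,
         W = 0.011, Y = 0.029)
  p[aa_alphabet()] / sum(p)
}

#' Draw a random protein sequence from background residue frequencies
#'
#' @param length Number of residues.
#' @return A single amino-acid string.
#' @export
random_protein <- function(length) {
  stopifnot(length >= 1)
  paste(sample(aa_alphabet(), length, replace = TRUE, prob = aa_background()),
        collapse = "")
}

#' Substitute residues of a protein at a fixed per-site rate
#'
#' Each position is substituted independently with probability `divergence`;
#' the replacement is drawn uniformly from the 19 other residues, so a
#' "mutated" site never keeps its original identity. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param seq Amino-acid string.
#' @param divergence Per-site substitution probability in \[0, 1\].
#' @return Mutated amino-acid string of the same length.
#' @export
mutate_protein <- function(seq, divergence) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1,
            divergence >= 0, divergence <= 1)
  if (divergence == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < divergence
  if (any(hit)) {
    aa <- aa_alphabet()
    repl <- vapply(chars[hit], function(x) sample(setdiff(aa, x), 1L), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

# Fixed synthetic stand-in reference proteins for the two anchor roles.
# Generated once from background frequencies; they are NOT the natural Psu
# or integrase sequences (which are irrelevant here: acceptance is against
# planted truth, and any fixed anchor works).
SYNTHETIC_PSU_ANCHOR <- paste0(
  "EGYTHHTVAVGNAAPVVVYIWIDLGIAVRFLGVVAMSETDASPCALSSTKSQPSLTPDMVLHSRLGGGQS",
  "ADGCILQSKATGNVRPAHALQKLELTDEYLVAWTSLGLTSTESYAGAHLRSQIREVNVDQKHDLTDMKSA",
  "SLPGVTDEEHLKHFFQVVPDSALQCFFGPLLLGEYSAALAIVEVIQQETE")

SYNTHETIC_INTEGRASE_CLOSER <- paste0(
  "RRYSSEQDPYAINESKDAKARANTAIYYTKGIYTYETGQLSIKNVEEEGVIASRPFPEGDIPGNLAVVNI",
  "DTNRQMNFHRTMESQLYATTMVIQFPPVRLLSIDQAKQGDNEKELYGDIQLWTTRARLFCLIYYICIDGT",
  "INLTDGLDKRITVELYSTARNGANEVSWVWADATFDIENQKRNGVNTNDRIWQGKDLAASIKDIEGAEHD",
  "LQITPFIILTTSRMKMTLGKIQGTMTSFVIGPGIDMANQPFRALRDACGYTIFIKESVGNGKLEFVLPLP",
  "EVSADMIENLKSNNIRNEEK")

#' Built-in synthetic anchor (Psu-like) reference protein
#'
#' A fixed 190-residue synthetic protein used as the default hotspot anchor
#' in the corpus generator and as the default mining query. It is a
#' synthetic stand-in, not the natural Psu sequence.
#' @return Named character vector of length 1.
#' @export
synthetic_anchor_protein <- function() {
  c(psu_like_anchor = SYNTHETIC_PSU_ANCHOR)
}

#' Built-in synthetic closing-gene (integrase-like) reference protein
#'
#' @return Named character vector of length 1.
#' @export
synthetic_closer_protein <- function() {
  c(integrase_like_closer = SYNTHETIC_INTEGRASE_CLOSER)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of amino-acid strings.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of amino-acid strings.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Validate an amino-acid string: standard 20 letters plus ambiguity X.
check_protein <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(aa_alphabet(), "X"))
  if (length(bad) > 0) {
    abort(sprintf("invalid amino-acid character '%s' at position %d of %s",
                  chars[bad[1]], bad[1], what))
  }
  invisible(TRUE)
}
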