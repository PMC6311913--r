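#' Exponential transform of PSSM scores
#'
#' Each integer log-odds score s is mapped to 2^(0.1 s), which is strictly
#' positive, so row normalisation is always well defined.
#'
#' @param x A `pssm` object (or integer matrix).
#' @return Numeric L x 5 matrix of positive values.
#' @export
pssm_transform <- function(x) {
  2^(0.1 * unclass(as.matrix(x)))
}

#' Row-normalised frequency matrix of a PSSM
#'
#' Applies the exponential score transform and normalises each row to sum to
#' one, giving a per-position distribution over A, C, G, U and the gap symbol.
#'
#' @param x A `pssm` object.
#' @return Numeric L x 5 row-stochastic matrix with columns A,C,G,U,`-`.
#' @export
frequency_matrix <- function(x) {
  tr <- pssm_transform(x)
  rs <- rowSums(tr)
  if (any(!is.finite(rs)) || any(rs <= 0)) {
    stop("degenerate PSSM row: transformed scores do not sum to a positive value")
  }
  tr / rs
}

#' Consensus sequence of a frequency matrix
#'
#' Per position, the nucleotide (gap excluded) with the highest frequency;
#' ties go to the alphabetically first nucleotide (A < C < G < U).
#'
#' @param fm Frequency matrix (L x 5 or L x 4), columns ordered A,C,G,U(,-).
#' @return Consensus string over A/C/G/U of length L.
#' @export
consensus_sequence <- function(fm) {
  nuc <- fm[, 1:4, drop = FALSE]
  idx <- max.col(nuc, ties.method = "first")
  paste(RNA_ALPHABET[idx], collapse = "")
}

#' Nucleotide composition and entropy of a consensus sequence
#'
#' @param cs Consensus string over A/C/G/U.
#' @return Named list: `nccs` (4 relative frequencies) and `ecs`, the Shannon
#'   entropy of that composition in nats (0 log 0 := 0), bounded by log(4).
#' @export
consensus_composition <- function(cs) {
  chars <- strsplit(cs, "", fixed = TRUE)[[1]]
  n <- vapply(RNA_ALPHABET, function(a) sum(chars == a), numeric(1))
  nccs <- n / length(chars)
  ecs <- shannon_entropy(nccs)
  list(nccs = nccs, ecs = ecs)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mean per-position entropy of a frequency matrix
#'
#' @param fm Row-stochastic L x 5 frequency matrix.
#' @return Mean row entropy in nats, in `[0, log(5)]`.
#' @export
profile_entropy <- function(fm) {
  mean(apply(fm, 1, shannon_entropy))
}

#' k-mer composition of a sequence
#'
#' Relative frequencies of all 4^k k-mers over the nchar - k + 1 sliding
#' windows, in lexicographic order (A < C < G < U).
#'
#' @param s Sequence string over A/C/G/U.
#' @param k Word size.
#' @return Named numeric vector of length 4^k summing to 1.
#' @export
kmer_frequencies <- function(s, k) {
  L <- nchar(s)
  if (L < k) stop("sequence of length ", L, " is too short for k = ", k)
  kmers <- apply(
    expand.grid(rep(list(RNA_ALPHABET), k))[, k:1, drop = FALSE],
    1, paste, collapse = ""
  )
  windows <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  counts <- vapply(kmers, function(w) sum(windows == w), numeric(1))
  counts / length(windows)
}

gc_content <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

#' Names of the 87 profile features, in frozen order
#'
#' Composition of the consensus (4), its entropy (1), the frequency-matrix
#' entropy (1), consensus dimer (16) and trimer (64) frequencies, and
#' consensus GC content (1). All names carry the `psi.` prefix.
#'
#' @return Character vector of length 87.
#' @export
profile_feature_names <- function() {
  dimers <- apply(expand.grid(RNA_ALPHABET, RNA_ALPHABET)[, 2:1], 1, paste, collapse = "")
  trimers <- apply(
    expand.grid(RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET)[, 3:1],
    1, paste, collapse = ""
  )
  c(
    paste0("psi.NCCS_", RNA_ALPHABET),
    "psi.Ecs",
    "psi.Efm",
    paste0("psi.di_", dimers),
    paste0("psi.tri_", trimers),
    "psi.GC"
  )
}

#' Extract the 87 profile features from a PSSM
#'
#' The PSSM is exponentiated and row-normalised into a frequency matrix, its
#' consensus sequence is read off, and the feature block is the consensus
#' composition, two entropies, consensus 2-/3-mer frequencies, and consensus
#' GC content. Adding a constant to every score leaves the block unchanged.
#'
#' @param x A `pssm` object.
#' @return Named numeric vector of length 87 (names from
#'   [profile_feature_names()]).
#' @export
profile_features <- function(x) {
  fm <- frequency_matrix(x)
  cs <- consensus_sequence(fm)
  comp <- consensus_composition(cs)
  out <- c(
    comp$nccs,
    comp$ecs,
    profile_entropy(fm),
    kmer_frequencies(cs, 2L),
    kmer_frequencies(cs, 3L),
    gc_content(cs)
  )
  names(out) <- profile_feature_names()
  out
}

#' One-hot pseudo-PSSM for a bare sequence
#'
#' When no PSI-BLAST profile is available the pipeline degrades gracefully by
#' scoring +5 for the sequence's own nucleotide and -5 elsewhere (gap
#' included), whose consensus is the sequence itself.
#'
#' @param sequence RNA string.
#' @return A `pssm` object.
#' @export
pseudo_pssm <- function(sequence) {
  validate_rna(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  mat <- matrix(-5L, nrow = length(chars), ncol = 5L, dimnames = list(NULL, PSSM_COLUMNS))
  mat[cbind(seq_along(chars), match(chars, RNA_ALPHABET))] <- 5L
  new_pssm(mat, sequence)
}
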