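#' Names of the 480 Hilbert-Huang features, in frozen order
#'
#' Property-major, then IMF index 1..8, then statistic
#' (`amp_mean`, `amp_var`, `freq_mean`, `energy_frac`), prefixed `hht.`.
#'
#' @param properties Property matrix (for its column names / order).
#' @return Character vector of length `15 * 32 = 480` for the shipped table.
#' @export
hht_feature_names <- function(properties = dinucleotide_properties()) {
  stats <- c("amp_mean", "amp_var", "freq_mean", "energy_frac")
  unlist(lapply(colnames(properties), function(p) {
    unlist(lapply(1:8, function(k) paste0("hht.", p, ".imf", k, ".", stat = stats)))
  }))
}

#' Extract the 480 Hilbert-Huang features of a sequence
#'
#' The sequence is encoded as one time series per dinucleotide property
#' ([property_series()]); each series is decomposed by [emd()] and summarised
#' by [hilbert_features()] (8 IMF slots x 4 statistics = 32 features per
#' series). A constant series (e.g. for a homopolymer) contributes 32 zeros.
#'
#' @param sequence RNA string (length >= 5).
#' @param properties Property matrix from [dinucleotide_properties()].
#' @param max_imf,sift_tol,max_sift Passed to [emd()].
#' @return Named numeric vector of length 480.
#' @export
hht_features <- function(sequence, properties = dinucleotide_properties(),
                         max_imf = 10L, sift_tol = 0.2, max_sift = 50L) {
  series <- property_series(sequence, properties)
  out <- unlist(lapply(seq_len(ncol(series)), function(j) {
    x <- series[, j]
    if (max(x) - min(x) < 1e-12) {
      return(numeric(32L))
    }
    hilbert_features(emd(x, max_imf = max_imf, sift_tol = sift_tol, max_sift = max_sift))
  }))
  names(out) <- hht_feature_names(properties)
  out
}
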