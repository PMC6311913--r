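#' The 15 RNA dinucleotide physicochemical properties
#'
#' Thermodynamic (duplex enthalpy, entropy and free energy in two published
#' parameterisations, stacking energy), hydrophilicity (two scales) and
#' A-form helical step geometry (rise, roll, shift, slide, tilt, twist) for
#' all 16 dinucleotides. Values are compiled from published nearest-neighbor
#' and helical-parameter sets and ship with the package as a versioned TSV;
#' a user table with the same layout can be supplied instead.
#'
#' @param path Optional path to a replacement TSV (column `dinucleotide`
#'   followed by one column per property, all 16 dinucleotides present).
#' @return A 16 x 15 numeric matrix, rows named by dinucleotide, columns by
#'   property.
#' @export
dinucleotide_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rna_dinucleotide_properties.tsv",
      package = "premirnet", mustWork = TRUE
    )
  }
  tab <- utils::read.delim(path, check.names = FALSE)
  stopifnot("dinucleotide" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "dinucleotide"), drop = FALSE])
  rownames(m) <- tab$dinucleotide
  all_dinucs <- as.vector(outer(RNA_ALPHABET, RNA_ALPHABET, paste0))
  missing <- setdiff(all_dinucs, rownames(m))
  if (length(missing) > 0L) {
    stop("property table lacks dinucleotide(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(m))) stop("non-finite value in property table")
  m
}

#' Encode a sequence as dinucleotide property time series
#'
#' A width-2, step-1 window slides along the sequence; each of the L-1
#' dinucleotides is replaced by its value for each property, giving one
#' length L-1 series per property.
#'
#' @param sequence RNA string (length >= 2).
#' @param properties Property matrix from [dinucleotide_properties()].
#' @return Numeric (L-1) x n_properties matrix, one column per property.
#' @export
property_series <- function(sequence, properties = dinucleotide_properties()) {
  validate_rna(sequence)
  L <- nchar(sequence)
  dinucs <- substring(sequence, seq_len(L - 1L), seq_len(L - 1L) + 1L)
  properties[dinucs, , drop = FALSE]
}
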