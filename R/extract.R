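#' All feature names for a block combination, in frozen order
#'
#' @param blocks Character subset of `c("psi", "net", "hht")`.
#' @param properties Property matrix (names only).
#' @return Character vector (591 names with all three blocks).
#' @export
feature_names <- function(blocks = c("psi", "net", "hht"),
                          properties = dinucleotide_properties()) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  out <- character(0)
  if ("psi" %in% blocks) out <- c(out, profile_feature_names())
  if ("net" %in% blocks) out <- c(out, network_feature_names())
  if ("hht" %in% blocks) out <- c(out, hht_feature_names(properties))
  out
}

#' Extract the feature table of a corpus
#'
#' The central extraction step: for every sequence, the enabled feature
#' blocks are computed and concatenated in the frozen order `psi.*`
#' (87 profile features), `net.*` (24 graph descriptors), `hht.*` (480
#' Hilbert-Huang features) — 591 columns with all blocks on.
#'
#' Structures and PSSMs are taken from the corpus columns when present.
#' A missing structure is folded with [fold_hairpin()] if `fold_fallback`
#' allows; a missing PSSM is replaced by the one-hot [pseudo_pssm()] if
#' `pseudo_pssm_fallback` allows; otherwise extraction aborts. Fallback use
#' is reported via a message.
#'
#' @param corpus A tibble with columns `id`, `sequence`, optional `label`,
#'   optional `structure` (dot-bracket strings) and optional `pssm`
#'   (list-column of `pssm` objects).
#' @param blocks Feature blocks to compute, subset of `c("psi","net","hht")`.
#' @param properties Dinucleotide property matrix for the `hht` block.
#' @param fold_fallback,pseudo_pssm_fallback Allow the built-in fallbacks.
#' @return A tibble: `id`, `label` (if present), then one numeric column per
#'   feature; no missing values.
#' @export
extract_features <- function(corpus, blocks = c("psi", "net", "hht"),
                             properties = dinucleotide_properties(),
                             fold_fallback = TRUE,
                             pseudo_pssm_fallback = TRUE) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  stopifnot(is.data.frame(corpus), all(c("id", "sequence") %in% names(corpus)))
  if (length(blocks) == 0L) stop("at least one feature block must be enabled")
  n <- nrow(corpus)

  structures <- if ("structure" %in% names(corpus)) corpus$structure else rep(NA_character_, n)
  pssms <- if ("pssm" %in% names(corpus)) corpus$pssm else vector("list", n)

  if ("net" %in% blocks && anyNA(structures)) {
    if (!fold_fallback) {
      stop(
        "no structure for record(s) ",
        paste(corpus$id[is.na(structures)], collapse = ", "),
        " and fold_fallback = FALSE"
      )
    }
    message(sum(is.na(structures)), " record(s) folded with the built-in Nussinov fallback")
  }
  if ("psi" %in% blocks) {
    missing_pssm <- vapply(pssms, is.null, logical(1))
    if (any(missing_pssm)) {
      if (!pseudo_pssm_fallback) {
        stop(
          "no PSSM for record(s) ",
          paste(corpus$id[missing_pssm], collapse = ", "),
          " and pseudo_pssm_fallback = FALSE"
        )
      }
      message(sum(missing_pssm), " record(s) given a one-hot pseudo-PSSM")
    }
  }

  rows <- lapply(seq_len(n), function(i) {
    seq_i <- corpus$sequence[i]
    validate_rna(seq_i, corpus$id[i])
    vec <- numeric(0)
    if ("psi" %in% blocks) {
      p <- pssms[[i]]
      if (is.null(p)) p <- pseudo_pssm(seq_i)
      vec <- c(vec, profile_features(p))
    }
    if ("net" %in% blocks) {
      db <- structures[i]
      if (is.na(db)) db <- fold_hairpin(seq_i)
      vec <- c(vec, structure_features(seq_i, db))
    }
    if ("hht" %in% blocks) {
      vec <- c(vec, hht_features(seq_i, properties))
    }
    vec
  })
  feats <- do.call(rbind, rows)
  stopifnot(!anyNA(feats), identical(colnames(feats), feature_names(blocks, properties)))
  out <- tibble::as_tibble(feats)
  if ("label" %in% names(corpus)) {
    out <- dplyr::bind_cols(tibble::tibble(id = corpus$id, label = corpus$label), out)
  } else {
    out <- dplyr::bind_cols(tibble::tibble(id = corpus$id), out)
  }
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("id", "label"))
}

label_factor <- function(table) {
  if (!"label" %in% names(table)) stop("feature table has no 'label' column")
  f <- factor(table$label)
  if (nlevels(f) != 2L) stop("expected exactly 2 label classes, found ", nlevels(f))
  f
}
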