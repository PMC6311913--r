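## Seeded synthetic benchmark: planted-hairpin positives, dinucleotide-
## shuffled negatives (identical length and near-identical composition, so
## any classification signal is order/structure-based), and Dirichlet-
## perturbed one-hot PSSMs standing in for PSI-BLAST output.

revcomp <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_rna <- function(n) {
  paste(sample(RNA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Generate one planted-hairpin sequence and its structure
#'
#' Sequence = 5' flank + 5' arm + loop + reverse-complement 3' arm +
#' 3' flank; the dot-bracket marks the planted stem (all stem positions
#' paired, everything else unpaired). Uses the current RNG state.
#'
#' @param length_total Total sequence length.
#' @param stem_len Number of planted base pairs (>= 3).
#' @param loop_len Loop length (>= 3).
#' @return List with `sequence` and `structure`.
#' @export
make_hairpin <- function(length_total = 90L, stem_len = 20L, loop_len = 6L) {
  stopifnot(stem_len >= 3L, loop_len >= 3L)
  core <- 2L * stem_len + loop_len
  if (core > length_total) stop("stem and loop do not fit in length_total")
  flank_total <- length_total - core
  flank5 <- flank_total %/% 2L
  flank3 <- flank_total - flank5
  arm5 <- random_rna(stem_len)
  sequence <- paste0(
    random_rna(flank5), arm5, random_rna(loop_len), revcomp(arm5), random_rna(flank3)
  )
  structure <- paste0(
    strrep(".", flank5), strrep("(", stem_len), strrep(".", loop_len),
    strrep(")", stem_len), strrep(".", flank3)
  )
  list(sequence = sequence, structure = structure)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: builds the dinucleotide multigraph of the
#' sequence, samples a random last-visit tree to the terminal letter, and
#' emits a random Eulerian walk. The shuffled sequence has exactly the
#' original's dinucleotide (hence mononucleotide) multiset, but any planted
#' stem order is destroyed. Uses the current RNG state.
#'
#' @param sequence RNA string.
#' @return A shuffled string of identical length and dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3L) return(sequence)
  letters_used <- unique(chars)
  last <- chars[n]
  # adjacency lists: edges[[a]] = multiset of successors of letter a
  edges <- lapply(letters_used, function(a) chars[which(chars[-n] == a) + 1L])
  names(edges) <- letters_used
  repeat {
    # pick a random last edge for each letter except the terminal one; the
    # chosen edges must form a tree pointing toward `last` (Altschul-Erickson)
    last_edge <- vapply(letters_used, function(a) {
      if (a == last) NA_character_ else sample(edges[[a]], 1L)
    }, character(1))
    ok <- TRUE
    for (a in setdiff(letters_used, last)) {
      # walk a -> last via chosen edges; must reach `last` without cycling
      seen <- character(0)
      cur <- a
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) {
          ok <- FALSE
          break
        }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle the remaining edges of each letter; append the reserved last edge
  pool <- lapply(letters_used, function(a) {
    e <- edges[[a]]
    if (a != last) {
      drop <- match(last_edge[[a]], e)
      e <- e[-drop]
    }
    e <- if (length(e) > 1L) sample(e) else e
    if (a != last) e <- c(e, last_edge[[a]])
    e
  })
  names(pool) <- letters_used
  ptr <- stats::setNames(rep(1L, length(letters_used)), letters_used)
  out <- character(n)
  out[1] <- chars[1]
  for (i in 2:n) {
    a <- out[i - 1L]
    out[i] <- pool[[a]][ptr[[a]]]
    ptr[[a]] <- ptr[[a]] + 1L
  }
  paste(out, collapse = "")
}

#' Synthesize a perturbed one-hot PSSM for a sequence
#'
#' Stands in for PSI-BLAST output: per position, the one-hot distribution on
#' the sequence's nucleotide is mixed with a Dirichlet(1,...,1) draw over the
#' five symbols with weight `noise`, pseudocounted, and converted to integer
#' log-odds against the uniform background, `floor(10 * log(p / 0.2))`. At
#' `noise = 0` the consensus of the resulting profile is the sequence itself.
#' Uses the current RNG state.
#'
#' @param sequence RNA string.
#' @param noise Mixture weight in `[0, 1)` of the Dirichlet perturbation.
#' @param pseudocount Floor added to every symbol before taking log-odds.
#' @return A `pssm` object.
#' @export
make_pssm <- function(sequence, noise = 0.1, pseudocount = 0.01) {
  validate_rna(sequence)
  stopifnot(noise >= 0, noise < 1)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  onehot <- matrix(0, nrow = L, ncol = 5L)
  onehot[cbind(seq_len(L), match(chars, RNA_ALPHABET))] <- 1
  dirichlet <- matrix(stats::rgamma(L * 5L, shape = 1), nrow = L)
  dirichlet <- dirichlet / rowSums(dirichlet)
  p <- (1 - noise) * onehot + noise * dirichlet
  p <- (p + pseudocount) / (1 + 5 * pseudocount)
  scores <- floor(10 * log(p / 0.2))
  pssm(scores, sequence)
}

#' Generate a seeded synthetic benchmark corpus
#'
#' Positives are planted hairpins with their true structures; each negative
#' is a dinucleotide shuffle of a fresh hairpin of the same length (structure
#' left to the fold fallback), so the two classes match in length and
#' dinucleotide composition and differ in sequence order and foldability —
#' a miniature of the true-vs-pseudo pre-miRNA problem. Every record gets a
#' perturbed one-hot PSSM.
#'
#' @param n_pos,n_neg Class sizes.
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @param length_range Min/max total sequence length (nt).
#' @param stem_len,loop_len Planted stem geometry (see [make_hairpin()]).
#' @param pssm_noise Dirichlet mixture weight for [make_pssm()].
#' @return A corpus tibble: `id`, `sequence`, `label` ("positive"/"negative"),
#'   `structure` (NA for negatives), and list-column `pssm`.
#' @export
synth_corpus <- function(n_pos = 50L, n_neg = 50L, seed = 1L,
                         length_range = c(60L, 130L),
                         stem_len = 20L, loop_len = 6L, pssm_noise = 0.1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lengths_pos <- sample(seq(length_range[1], length_range[2]), n_pos, replace = TRUE)
  lengths_neg <- sample(seq(length_range[1], length_range[2]), n_neg, replace = TRUE)
  pos <- lapply(lengths_pos, function(L) make_hairpin(L, stem_len, loop_len))
  neg_seq <- vapply(lengths_neg, function(L) {
    dinucleotide_shuffle(make_hairpin(L, stem_len, loop_len)$sequence)
  }, character(1))
  sequences <- c(vapply(pos, `[[`, "", "sequence"), neg_seq)
  structures <- c(vapply(pos, `[[`, "", "structure"), rep(NA_character_, n_neg))
  corpus <- tibble::tibble(
    id = c(sprintf("pos%03d", seq_len(n_pos)), sprintf("neg%03d", seq_len(n_neg))),
    sequence = sequences,
    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
    structure = structures,
    pssm = lapply(sequences, make_pssm, noise = pssm_noise)
  )
  corpus
}

#' Write a corpus to disk as plain-text files
#'
#' FASTA sequences, Vienna dot-bracket structures (records with one), one
#' PSSM TSV per record under `pssm/`, and a `labels.tsv`.
#'
#' @param corpus Corpus tibble from [synth_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(corpus, file.path(dir, "sequences.fasta"))
  with_struct <- corpus[!is.na(corpus$structure), ]
  if (nrow(with_struct) > 0L) {
    write_dotbracket(with_struct, file.path(dir, "structures.db"))
  }
  for (i in seq_len(nrow(corpus))) {
    if (!is.null(corpus$pssm[[i]])) {
      write_pssm(corpus$pssm[[i]], file.path(dir, "pssm", paste0(corpus$id[i], ".pssm")))
    }
  }
  readr::write_tsv(corpus[, c("id", "label")], file.path(dir, "labels.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Corpus directory.
#' @return A corpus tibble (`structure` NA where no structure was stored).
#' @export
read_corpus <- function(dir) {
  corpus <- read_fasta(file.path(dir, "sequences.fasta"))
  labels_path <- file.path(dir, "labels.tsv")
  if (file.exists(labels_path)) {
    labels <- readr::read_tsv(labels_path, show_col_types = FALSE, progress = FALSE)
    corpus <- dplyr::left_join(corpus, labels, by = "id")
  }
  db_path <- file.path(dir, "structures.db")
  corpus$structure <- NA_character_
  if (file.exists(db_path)) {
    db <- read_dotbracket(db_path)
    corpus$structure[match(db$id, corpus$id)] <- db$structure
  }
  corpus$pssm <- lapply(seq_len(nrow(corpus)), function(i) {
    p <- file.path(dir, "pssm", paste0(corpus$id[i], ".pssm"))
    if (file.exists(p)) read_pssm(p, corpus$sequence[i]) else NULL
  })
  corpus
}
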