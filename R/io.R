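#' Read RNA sequences from a FASTA file
#'
#' Sequences are upper-cased and DNA thymine is transliterated to uracil, so
#' downstream code always sees the RNA alphabet A/C/G/U. Record ids must be
#' unique; any character outside A/C/G/U/T (either case) aborts with the
#' offending record named.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty id in '", path, "'")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGUT]", seqs)
  if (any(bad)) {
    stop(
      "invalid characters (outside A/C/G/U/T) in record(s): ",
      paste(ids[bad], collapse = ", ")
    )
  }
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write RNA sequences to a FASTA file
#'
#' @param x A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

validate_rna <- function(sequence, id = "<sequence>", min_len = 4L) {
  if (nchar(sequence) < min_len) {
    stop("sequence '", id, "' is shorter than ", min_len, " nt")
  }
  if (grepl(paste0("[^", paste(RNA_ALPHABET, collapse = ""), "]"), sequence)) {
    stop("sequence '", id, "' contains characters outside A/C/G/U")
  }
  invisible(sequence)
}

#' Validate a dot-bracket secondary structure
#'
#' Checks that the structure uses only `(`, `)` and `.`, that parentheses are
#' balanced, and (when a sequence is given) that lengths match. Extra bracket
#' levels (pseudoknot notation) are rejected.
#'
#' @param structure Dot-bracket string.
#' @param sequence Optional sequence the structure annotates.
#' @return `structure`, invisibly.
#' @export
validate_dotbracket <- function(structure, sequence = NULL) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    stop("invalid structure character '", chars[bad[1]], "' at position ", bad[1])
  }
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unmatched at end of structure")
  if (!is.null(sequence) && nchar(structure) != nchar(sequence)) {
    stop(
      "structure length (", nchar(structure), ") does not match sequence length (",
      nchar(sequence), ")"
    )
  }
  invisible(structure)
}

#' Extract base pairs from a dot-bracket string
#'
#' @param structure Dot-bracket string.
#' @return Integer matrix with columns `i`, `j` (1-based, i < j), one row per pair.
#' @export
dotbracket_pairs <- function(structure) {
  validate_dotbracket(structure)
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs <- rbind(pairs, c(i, k))
    }
  }
  pairs
}

#' Read sequences and dot-bracket structures
#'
#' Accepts Vienna-style files: either repeated id/sequence/structure triplets
#' (`>id` header) or alternating sequence/structure line pairs, in which case
#' ids `seq1`, `seq2`, ... are assigned. Every structure is validated for
#' balance and length against its sequence.
#'
#' @param path Path to the structure file.
#' @return A tibble with columns `id`, `sequence`, `structure`.
#' @export
read_dotbracket <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty structure file '", path, "'")
  # Vienna often appends the MFE to the structure line: "(((...))) (-1.20)"
  strip_energy <- function(x) sub("\\s+\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", x)
  if (startsWith(lines[1], ">")) {
    if (length(lines) %% 3L != 0L) {
      stop("expected id/sequence/structure triplets in '", path, "'")
    }
    ids <- sub("^>", "", sub("\\s.*$", "", lines[seq(1, length(lines), by = 3)]))
    seqs <- lines[seq(2, length(lines), by = 3)]
    structs <- strip_energy(lines[seq(3, length(lines), by = 3)])
  } else {
    if (length(lines) %% 2L != 0L) {
      stop("expected alternating sequence/structure lines in '", path, "'")
    }
    seqs <- lines[seq(1, length(lines), by = 2)]
    structs <- strip_energy(lines[seq(2, length(lines), by = 2)])
    ids <- paste0("seq", seq_along(seqs))
  }
  seqs <- gsub("T", "U", toupper(seqs), fixed = TRUE)
  for (k in seq_along(ids)) {
    validate_rna(seqs[k], ids[k])
    validate_dotbracket(structs[k], seqs[k])
  }
  tibble::tibble(id = ids, sequence = seqs, structure = structs)
}

#' Write sequences and structures in Vienna triplet layout
#'
#' @param x Data frame with columns `id`, `sequence`, `structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(x, path) {
  stopifnot(all(c("id", "sequence", "structure") %in% names(x)))
  out <- as.vector(rbind(paste0(">", x$id), x$sequence, x$structure))
  writeLines(out, path)
  invisible(path)
}

#' Read a position-specific scoring matrix
#'
#' Understands two dialects, sniffed from the first non-blank line:
#' the PSI-BLAST `-out_ascii_pssm` layout (banner line, a header row of
#' residue letters, then one row per position: index, residue, scores) and a
#' simple headered TSV (`pos`, `residue`, then score columns). Score columns
#' are taken in the order A, C, G, U, `-`; when the gap column is absent each
#' row's gap score is filled with that row's minimum score so the matrix is
#' always L x 5.
#'
#' @param path Path to the PSSM file.
#' @param sequence Optional expected sequence; mismatch in length or letters aborts.
#' @return A `pssm` object: integer score matrix with columns A,C,G,U,`-` and
#'   the residue sequence as attribute `sequence`.
#' @export
read_pssm <- function(path, sequence = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("empty PSSM file '", path, "'")
  first <- trimws(nonblank[1])
  if (grepl("^pos\\b", first, ignore.case = TRUE)) {
    tab <- utils::read.delim(path, check.names = FALSE)
    residues <- toupper(as.character(tab$residue))
    score_cols <- setdiff(names(tab), c("pos", "residue"))
    scores <- as.matrix(tab[, score_cols, drop = FALSE])
  } else {
    # PSI-BLAST ASCII: locate the header row of residue letters, read rows
    # of the form "<pos> <residue> <scores...>" until a blank line.
    hdr <- grep("^\\s*A\\s+C\\s+G\\s+[UT](\\s|$)", lines)
    if (length(hdr) == 0L) {
      stop("cannot locate residue header row in PSSM file '", path, "'")
    }
    letters_row <- strsplit(trimws(lines[hdr[1]]), "\\s+")[[1]]
    body <- lines[seq(hdr[1] + 1L, length(lines))]
    body <- body[grepl("^\\s*[0-9]+\\s+[A-Za-z]\\s", body)]
    if (length(body) == 0L) stop("no score rows in PSSM file '", path, "'")
    fields <- strsplit(trimws(body), "\\s+")
    residues <- toupper(vapply(fields, `[[`, "", 2L))
    scores <- t(vapply(
      fields,
      function(f) {
        vals <- suppressWarnings(as.numeric(f[seq(3L, 2L + length(letters_row))]))
        if (anyNA(vals)) stop("non-numeric score in PSSM row: ", paste(f, collapse = " "))
        vals
      },
      numeric(length(letters_row))
    ))
    colnames(scores) <- letters_row
  }
  colnames(scores) <- sub("^T$", "U", toupper(colnames(scores)))
  if (any(scores != round(scores))) stop("non-integer score in PSSM file '", path, "'")
  missing_cols <- setdiff(c("A", "C", "G", "U"), colnames(scores))
  if (length(missing_cols) > 0L) {
    stop("PSSM file '", path, "' lacks score column(s): ", paste(missing_cols, collapse = ", "))
  }
  mat <- matrix(0L, nrow = nrow(scores), ncol = 5L, dimnames = list(NULL, PSSM_COLUMNS))
  mat[, c("A", "C", "G", "U")] <- as.integer(scores[, c("A", "C", "G", "U")])
  if ("-" %in% colnames(scores)) {
    mat[, "-"] <- as.integer(scores[, "-"])
  } else {
    # sentinel: the row minimum, so the gap column never dominates
    mat[, "-"] <- as.integer(apply(mat[, 1:4, drop = FALSE], 1, min))
  }
  residues <- gsub("T", "U", residues, fixed = TRUE)
  seq_string <- paste(residues, collapse = "")
  if (!is.null(sequence)) {
    if (nchar(sequence) != nrow(mat)) {
      stop(
        "PSSM has ", nrow(mat), " rows but sequence has ", nchar(sequence),
        " positions"
      )
    }
    if (seq_string != sequence) {
      stop("PSSM residue column disagrees with the supplied sequence")
    }
  }
  new_pssm(mat, seq_string)
}

new_pssm <- function(scores, sequence) {
  stopifnot(nrow(scores) == nchar(sequence))
  structure(scores, sequence = sequence, class = c("pssm", "matrix", "array"))
}

#' Construct a PSSM object from a score matrix
#'
#' @param scores Integer matrix, one row per position, columns A,C,G,U,`-`
#'   (a 4-column matrix gets its gap column filled with the row minimum).
#' @param sequence The query sequence the rows annotate.
#' @return A `pssm` object.
#' @export
pssm <- function(scores, sequence) {
  scores <- as.matrix(scores)
  if (any(scores != round(scores))) stop("PSSM scores must be integers")
  if (ncol(scores) == 4L) {
    scores <- cbind(scores, apply(scores, 1, min))
  }
  stopifnot(ncol(scores) == 5L)
  mode(scores) <- "integer"
  dimnames(scores) <- list(NULL, PSSM_COLUMNS)
  validate_rna(sequence, min_len = 1L) # a PSSM may annotate a short fragment
  new_pssm(scores, sequence)
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM for sequence of length", nrow(x), "\n")
  print(utils::head(unclass(x), 5))
  if (nrow(x) > 5) cat("... (", nrow(x) - 5, " more rows)\n", sep = "")
  invisible(x)
}

#' Write a PSSM in the package's TSV dialect
#'
#' Header `pos  residue  A  C  G  U  -`, one row per position. `read_pssm()`
#' reads this dialect back losslessly.
#'
#' @param x A `pssm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  tab <- data.frame(
    pos = seq_len(nrow(x)),
    residue = strsplit(attr(x, "sequence"), "")[[1]],
    unclass(x)[, , drop = FALSE],
    check.names = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write labelled feature tables
#'
#' TSV with a header row; first column `id`, optional `label` column, the
#' rest numeric features. Full double precision is preserved on write.
#'
#' @param path File path.
#' @return `read_feature_table()`: a tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @param x Feature tibble (columns `id`, optional `label`, features).
#' @rdname read_feature_table
#' @export
write_feature_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
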