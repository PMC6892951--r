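# Validation of raw peptides and conversion between native-length
# sequences (8-15 residues) and the canonical padded 15mer.
#
# The padding rule keeps the anchor segments of the 9-residue binding core
# intact: original residues 1-4 and (when present) 6-9 each stay contiguous,
# with no padding residue inserted inside either segment. Positions are
# 1-based throughout.

#' Validate a raw peptide sequence
#'
#' Trims whitespace, uppercases, and checks that the sequence is 8--15
#' residues over the 20 standard amino-acid letters. The padding residue
#' `"X"` and ambiguity codes (B, Z, U, J, O) are rejected: `"X"` is reserved
#' for length normalization and silent remapping would corrupt its meaning.
#'
#' @param raw A single character string.
#' @return An object of class `"peptide"`: a list with `sequence` and
#'   `length`.
#' @examples
#' validate_peptide("SIINFEKL")
#' @export
validate_peptide <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("peptide must be a single character string", call. = FALSE)
  seq <- toupper(trimws(raw))
  n <- nchar(seq)
  if (n < 8L || n > 15L)
    stop("peptide length ", n, " outside the supported range 8-15",
         call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% standard_residues())
  if (length(bad)) {
    stop("invalid residue '", chars[bad[1]], "' at position ", bad[1],
         ": only the 20 standard amino-acid letters are allowed",
         call. = FALSE)
  }
  structure(list(sequence = seq, length = n), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("peptide ", x$sequence, " (", x$length, "mer)\n", sep = "")
  invisible(x)
}

#' Normalize a peptide to the canonical 15mer
#'
#' Pads an 8--15mer to exactly 15 symbols with the artificial residue
#' `"X"` while preserving the anchor segments of the binding core. The
#' deterministic placement rule is: peptides of length 9 or more keep
#' their residues at positions 1..L and are right-padded; an 8mer keeps
#' residues 1--4 at positions 1--4, takes a single X at position 5 so that
#' residues 5--8 shift onto core positions 6--9, and is then right-padded.
#' Both anchor segments (original residues 1--4, and 6--9 when the peptide
#' has at least 9 residues) therefore remain contiguous with no internal X.
#'
#' @param p A `"peptide"` object from [validate_peptide()], or a raw
#'   string which is validated first.
#' @return An object of class `"padded_peptide"`: a list with `sequence15`
#'   (15 symbols), `original_length`, and the sorted 1-based `x_positions`.
#' @examples
#' normalize_to_15mer("ACDEFGHIK")   # right-padded with six X
#' normalize_to_15mer("ACDEFGHI")    # 8mer: single X at position 5
#' @export
normalize_to_15mer <- function(p) {
  if (is.character(p)) p <- validate_peptide(p)
  stopifnot(inherits(p, "peptide"))
  L <- p$length
  if (L == 8L) {
    seq15 <- paste0(substr(p$sequence, 1, 4), "X", substr(p$sequence, 5, 8),
                    strrep("X", 6))
    xpos <- c(5L, 10:15)
  } else {
    seq15 <- paste0(p$sequence, strrep("X", 15L - L))
    xpos <- if (L < 15L) seq.int(L + 1L, 15L) else integer(0)
  }
  structure(list(sequence15 = seq15, original_length = L,
                 x_positions = as.integer(xpos)),
            class = "padded_peptide")
}

#' @export
print.padded_peptide <- function(x, ...) {
  cat("padded 15mer ", x$sequence15, " (original ", x$original_length,
      "mer)\n", sep = "")
  invisible(x)
}

#' Recover the original peptide from a padded 15mer
#'
#' Strips every `"X"` and returns the original peptide;
#' `denormalize(normalize_to_15mer(p))` is the identity.
#'
#' @param np A `"padded_peptide"` object, or a bare 15-symbol string over
#'   the 21-letter alphabet.
#' @return A `"peptide"` object.
#' @export
denormalize <- function(np) {
  if (is.character(np)) {
    if (length(np) != 1L || nchar(np) != 15L)
      stop("a padded peptide must be exactly 15 symbols", call. = FALSE)
    chars <- strsplit(np, "", fixed = TRUE)[[1]]
    if (!all(chars %in% aa_alphabet()))
      stop("padded peptide contains symbols outside the 21-letter alphabet",
           call. = FALSE)
    np <- structure(list(sequence15 = np,
                         original_length = sum(chars != "X"),
                         x_positions = which(chars == "X")),
                    class = "padded_peptide")
  }
  stopifnot(inherits(np, "padded_peptide"))
  if (nchar(np$sequence15) != 15L)
    stop("malformed padded peptide: length ", nchar(np$sequence15),
         " != 15", call. = FALSE)
  validate_peptide(gsub("X", "", np$sequence15, fixed = TRUE))
}

#' Read a peptide list from plain text or FASTA
#'
#' One sequence per line; lines starting with `>` begin FASTA records whose
#' sequence lines are concatenated. Blank lines are skipped. Sequences are
#' returned raw (unvalidated) so callers can route failures explicitly.
#'
#' @param path Path to a text or FASTA file.
#' @return Character vector of sequences (named by FASTA header if present).
#' @export
read_peptides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character(0))
  if (any(startsWith(lines, ">"))) {
    hdr <- startsWith(lines, ">")
    id <- cumsum(hdr)
    if (id[1] == 0L) stop("FASTA file must start with a '>' header",
                          call. = FALSE)
    seqs <- vapply(split(lines[!hdr], id[!hdr]), paste0, "", collapse = "")
    names(seqs) <- sub("^>\\s*", "", lines[hdr])[as.integer(names(seqs))]
    seqs
  } else {
    lines
  }
}

#' Normalize a batch of peptides to a table
#'
#' Validates and pads each sequence; failures are collected, not fatal.
#'
#' @param peptides Character vector of raw sequences.
#' @return A data frame with columns `peptide`, `sequence15`,
#'   `original_length`, `x_positions` (comma-joined) and `error`
#'   (`NA` for clean rows).
#' @export
normalize_peptides <- function(peptides) {
  rows <- lapply(peptides, function(s) {
    np <- tryCatch(normalize_to_15mer(s), error = identity)
    if (inherits(np, "error")) {
      data.frame(peptide = s, sequence15 = NA_character_,
                 original_length = NA_integer_, x_positions = NA_character_,
                 error = conditionMessage(np), stringsAsFactors = FALSE)
    } else {
      data.frame(peptide = s, sequence15 = np$sequence15,
                 original_length = np$original_length,
                 x_positions = paste(np$x_positions, collapse = ","),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
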