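# Residue alphabet, property tables and the extended substitution matrix.
#
# The 21-symbol alphabet (20 standard amino acids + the artificial padding
# residue "X") is ordered once here; every encoding in the package indexes
# into this order, so it must never be permuted.

#' The 21-symbol peptide alphabet
#'
#' The 20 standard amino acids in BLOSUM62 row order, followed by the
#' artificial padding residue `"X"`. The position of a symbol in this vector
#' is its sequence-index feature value (1--21), so the ordering is fixed.
#'
#' @return Character vector of 21 one-letter codes; `"X"` is last.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
    "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
}

# standard residues only (no X); used by input validation
standard_residues <- function() aa_alphabet()[1:20]

#' Sequence index of an alphabet symbol
#'
#' Maps each symbol of [aa_alphabet()] to its 1-based position, 1 for `"A"`
#' through 20 for `"V"`, with the padding residue `"X"` mapped to 21.
#'
#' @param symbol Character vector of single-letter codes.
#' @return Integer vector of indices in `1:21`.
#' @examples
#' sequence_index(c("A", "V", "X"))
#' @export
sequence_index <- function(symbol) {
  idx <- match(symbol, aa_alphabet())
  if (anyNA(idx)) {
    bad <- symbol[is.na(idx)][1]
    stop("invalid residue '", bad, "': not in the 21-symbol alphabet",
         call. = FALSE)
  }
  idx
}

# Eisenberg consensus hydropathy values; the padding residue scores 0.
.hydropathy_table <- c(
  A =  0.62, R = -2.5,  N = -0.78, D = -0.9,  C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H =  0.40, I =  1.4,
  L =  1.1,  K = -1.5,  M =  0.64, F =  1.2,  P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.1,
  X =  0
)

# Polarity classes: 0 padding, 1 non-polar aliphatic/aromatic,
# 2 polar uncharged, 3 acidic, 4 basic.
.polarity_table <- c(
  A = 1, G = 1, I = 1, L = 1, F = 1, P = 1, V = 1,
  N = 2, C = 2, Q = 2, S = 2, T = 2, W = 2, Y = 2, M = 2,
  D = 3, E = 3,
  R = 4, H = 4, K = 4,
  X = 0
)

#' Eisenberg consensus hydropathy of a symbol
#'
#' Dimensionless hydropathy on the Eisenberg consensus scale, ranging from
#' -2.5 (Arg) to 1.4 (Ile). The padding residue `"X"` scores exactly 0.
#'
#' @param symbol Character vector of single-letter codes.
#' @return Numeric vector of hydropathy values.
#' @examples
#' hydropathy(c("R", "I", "X"))
#' @export
hydropathy <- function(symbol) {
  unname(.hydropathy_table[aa_alphabet()[sequence_index(symbol)]])
}

#' Polarity class of a symbol
#'
#' Five-class grouping by side-chain polarity at physiological pH:
#' 1 = non-polar (A, G, I, L, F, P, V), 2 = polar uncharged
#' (N, C, Q, S, T, W, Y, M), 3 = negatively charged (D, E),
#' 4 = positively charged (R, H, K), and 0 for the padding residue `"X"`.
#'
#' @param symbol Character vector of single-letter codes.
#' @return Integer vector of class labels in `0:4`.
#' @examples
#' polarity_class(c("D", "K", "X"))
#' @export
polarity_class <- function(symbol) {
  unname(as.integer(.polarity_table[aa_alphabet()[sequence_index(symbol)]]))
}

#' Per-symbol property tables
#'
#' Bundles the three per-symbol lookups used by the chemical-property
#' encoding: sequence index (1--21), Eisenberg hydropathy and polarity
#' class, each as a named vector over the full 21-symbol alphabet.
#'
#' @return A list with components `sequence_index`, `hydropathy` and
#'   `polarity_class`.
#' @export
property_tables <- function() {
  ab <- aa_alphabet()
  list(
    sequence_index = stats::setNames(seq_along(ab), ab),
    hydropathy     = stats::setNames(hydropathy(ab), ab),
    polarity_class = stats::setNames(polarity_class(ab), ab)
  )
}

.pkg_cache <- new.env(parent = emptyenv())

#' Extended 21x21 BLOSUM62 substitution table
#'
#' The canonical NCBI BLOSUM62 integer matrix over the 20 standard amino
#' acids, extended by one row and column for the padding residue `"X"`:
#' X scores 0 against every amino acid and 1 against itself, so a padded
#' position carries no substitution signal of its own. The 20x20 block is
#' read from a versioned plain-text copy shipped with the package.
#'
#' @return Integer matrix, 21 rows and columns, dimnames [aa_alphabet()].
#' @examples
#' substitution_table()["A", "A"]  # 4
#' substitution_table()["X", "X"]  # 1
#' @export
substitution_table <- function() {
  if (!is.null(.pkg_cache$subst)) return(.pkg_cache$subst)
  path <- system.file("extdata", "blosum62.tsv", package = "pepcnn")
  if (path == "") stop("embedded BLOSUM62 fixture not found", call. = FALSE)
  core <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  storage.mode(core) <- "integer"
  ab <- aa_alphabet()
  stopifnot(identical(rownames(core), ab[1:20]),
            identical(colnames(core), ab[1:20]),
            isSymmetric(unname(core)))
  m <- matrix(0L, 21, 21, dimnames = list(ab, ab))
  m[1:20, 1:20] <- core
  m["X", "X"] <- 1L
  .pkg_cache$subst <- m
  m
}
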