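# Per-peptide feature matrices: the 15x21 extended-BLOSUM62 substitution
# encoding and the 4x15 chemical-property encoding.

seq15_chars <- function(np) strsplit(np$sequence15, "", fixed = TRUE)[[1]]

#' Substitution encoding of a padded peptide
#'
#' Encodes a padded 15mer as a 15x21 integer matrix: row i is the extended
#' BLOSUM62 row of the symbol at position i (see [substitution_table()]).
#' A padded position therefore becomes a row of zeros with a single 1 in
#' the X column.
#'
#' @param np A `"padded_peptide"` (or raw sequence, normalized first).
#' @return Integer matrix, 15 rows (positions) x 21 columns (alphabet).
#' @examples
#' m <- encode_substitution("ACDEFGHIK")
#' dim(m)  # 15 21
#' @export
encode_substitution <- function(np) {
  if (is.character(np)) np <- normalize_to_15mer(np)
  stopifnot(inherits(np, "padded_peptide"))
  st <- substitution_table()
  m <- st[seq15_chars(np), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Chemical-property encoding of a padded peptide
#'
#' Encodes a padded 15mer as a 4x15 matrix, one column per position:
#' row 1 the sequence index (1--21, 21 marking padded positions), row 2
#' the Eisenberg hydropathy (0 at padded positions), row 3 the polarity
#' class (0--4, 0 at padded positions), and row 4 the original peptide
#' length repeated across all 15 columns.
#'
#' @param np A `"padded_peptide"` (or raw sequence, normalized first).
#' @return Numeric matrix, 4 rows x 15 columns, rownames
#'   `c("sequence", "hydropathy", "polarity", "length")`.
#' @examples
#' encode_chemical("ACDEFGHIK")[, 1:3]
#' @export
encode_chemical <- function(np) {
  if (is.character(np)) np <- normalize_to_15mer(np)
  stopifnot(inherits(np, "padded_peptide"))
  chars <- seq15_chars(np)
  rbind(
    sequence   = sequence_index(chars),
    hydropathy = hydropathy(chars),
    polarity   = polarity_class(chars),
    length     = rep(np$original_length, 15L)
  )
}

#' Encode a batch of peptides as a feature tensor
#'
#' Normalizes and encodes each peptide, stacking the per-peptide matrices
#' into one array. All modes emit channels-by-position matrices so that
#' encodings are concatenable along the channel axis: `"chemical"` gives
#' 4x15, `"substitution"` the transposed substitution encoding (21x15),
#' and `"stacked"` their concatenation (25x15, substitution rows first).
#'
#' Invalid peptides abort the whole batch with a report naming each
#' offending item; nothing is dropped silently.
#'
#' @param peptides Character vector of raw sequences, or a list of
#'   `"padded_peptide"` objects.
#' @param mode One of `"chemical"`, `"substitution"`, `"stacked"`.
#' @return A list with `tensor` (array `n x channels x 15`), `index`
#'   (data frame of peptide, original length) and `mode`.
#' @examples
#' b <- encode_batch(c("SIINFEKL", "ACDEFGHIK"), mode = "chemical")
#' dim(b$tensor)  # 2 4 15
#' @export
encode_batch <- function(peptides,
                         mode = c("chemical", "substitution", "stacked")) {
  mode <- match.arg(mode)
  if (is.character(peptides)) {
    parsed <- lapply(peptides, function(s)
      tryCatch(normalize_to_15mer(s), error = identity))
    errs <- vapply(parsed, inherits, TRUE, what = "error")
    if (any(errs)) {
      msgs <- vapply(which(errs), function(i)
        paste0("item ", i, " ('", peptides[i], "'): ",
               conditionMessage(parsed[[i]])), "")
      stop("batch encoding failed for ", sum(errs), " peptide(s):\n",
           paste(msgs, collapse = "\n"), call. = FALSE)
    }
  } else {
    parsed <- peptides
    stopifnot(all(vapply(parsed, inherits, TRUE, what = "padded_peptide")))
  }
  n <- length(parsed)
  channels <- switch(mode, chemical = 4L, substitution = 21L, stacked = 25L)
  tensor <- array(0, dim = c(n, channels, 15L))
  for (i in seq_len(n)) {
    np <- parsed[[i]]
    tensor[i, , ] <- switch(mode,
      chemical     = encode_chemical(np),
      substitution = t(encode_substitution(np)),
      stacked      = rbind(t(encode_substitution(np)), encode_chemical(np)))
  }
  index <- data.frame(
    peptide = vapply(parsed, function(np) denormalize(np)$sequence, ""),
    sequence15 = vapply(parsed, `[[`, "", "sequence15"),
    original_length = vapply(parsed, `[[`, 0L, "original_length"),
    stringsAsFactors = FALSE)
  list(tensor = tensor, index = index, mode = mode)
}

#' Write feature matrices as delimited text
#'
#' One tab-delimited block per peptide, preceded by a `# <peptide>` comment
#' line; blocks are separated by blank lines.
#'
#' @param batch Result of [encode_batch()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_blocks <- function(batch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(batch$tensor)[1])) {
    cat("# ", batch$index$peptide[i], "\n", sep = "", file = con)
    utils::write.table(batch$tensor[i, , ], con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    cat("\n", file = con)
  }
  invisible(path)
}
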