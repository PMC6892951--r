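# Reading IEDB-style measurement tables, binary labeling, allele support
# filtering, and shuffled cross-validation splits.
#
# A "measurement table" is delimited text with at least `allele` and
# `peptide` columns; the full IEDB MHC-I export dialect additionally has
# measurement_value, measurement_inequality, measurement_type,
# measurement_source and original_allele. Column names are matched after
# lower-casing and squashing spaces/dots to underscores.

.canon_cols <- function(nms) {
  x <- tolower(trimws(nms))
  gsub("[ .]+", "_", x)
}

#' Read an IEDB-style measurement table
#'
#' Reads a comma- or tab-delimited binding table and validates every
#' peptide. Rows whose peptide fails validation (wrong length, non-standard
#' residue) are quarantined with the reason, never dropped silently.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; `"auto"` (default) picks tab if the header
#'   contains one, else comma.
#' @return A list with `records` (data frame of clean rows, canonical
#'   column names) and `quarantined` (data frame with `row`, `peptide`,
#'   `reason`).
#' @export
read_measurement_table <- function(path, sep = "auto") {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (identical(sep, "auto")) {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  names(df) <- .canon_cols(names(df))
  missing <- setdiff(c("allele", "peptide"), names(df))
  if (length(missing))
    stop("measurement table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (opt in c("measurement_value", "measurement_inequality",
                "measurement_type", "measurement_source", "original_allele"))
    if (!opt %in% names(df)) df[[opt]] <- rep(NA, nrow(df))
  df$allele <- trimws(as.character(df$allele))
  df$peptide <- trimws(as.character(df$peptide))
  df$measurement_value <- suppressWarnings(as.numeric(df$measurement_value))

  reason <- vapply(df$peptide, function(p) {
    e <- tryCatch({ validate_peptide(p); NA_character_ },
                  error = conditionMessage)
    e
  }, "", USE.NAMES = FALSE)
  bad <- !is.na(reason)
  list(
    records = df[!bad, , drop = FALSE],
    quarantined = data.frame(row = which(bad), peptide = df$peptide[bad],
                             reason = reason[bad], stringsAsFactors = FALSE)
  )
}

.is_quant <- function(type) grepl("quant|ic50|ba", type, ignore.case = TRUE)
.is_el <- function(type) grepl("elut|ligand|mass|\\bel\\b|spectro",
                               type, ignore.case = TRUE)

# provenance rank used for duplicate resolution: BA quant > qualitative > EL
.prov_rank <- function(type) {
  ifelse(.is_quant(type), 1L, ifelse(.is_el(type), 3L, 2L))
}

#' Label binding records as binders / non-binders
#'
#' Quantitative binding-affinity rows are thresholded at `threshold_nM`
#' (default 500 nM, the usual IEDB convention): label 1 iff the affinity is
#' at or below the threshold. Inequalities are honored: `< v` resolves only
#' when `v <= threshold` (label 1) and `> v` only when `v >= threshold`
#' (label 0); unresolvable bounds are quarantined as indeterminate.
#' Qualitative rows map Positive-like terms to 1 and Negative to 0;
#' eluted-ligand detections are positives. Duplicate (allele, peptide)
#' pairs keep one record, preferring quantitative over qualitative over
#' eluted-ligand provenance.
#'
#' @param records Data frame from [read_measurement_table()].
#' @param threshold_nM Positive affinity cut in nM; default 500.
#' @param dedupe Drop duplicate (allele, peptide) pairs? Default `TRUE`.
#' @return A list with `examples` (data frame: allele, peptide, label,
#'   provenance) and `quarantined` (data frame: allele, peptide, reason).
#' @export
label_records <- function(records, threshold_nM = 500, dedupe = TRUE) {
  stopifnot(is.numeric(threshold_nM), threshold_nM > 0)
  r <- records
  if (dedupe && nrow(r)) {
    ord <- order(.prov_rank(as.character(r$measurement_type)))
    r <- r[ord, , drop = FALSE]
    r <- r[!duplicated(paste(r$allele, r$peptide, sep = "\r")), ,
           drop = FALSE]
  }
  n <- nrow(r)
  label <- rep(NA_integer_, n)
  prov <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    type <- as.character(r$measurement_type[i])
    if (is.na(type)) type <- ""
    if (.is_quant(type) || (!.is_el(type) && !is.na(r$measurement_value[i]) &&
                            !nzchar(type))) {
      v <- r$measurement_value[i]
      ineq <- as.character(r$measurement_inequality[i])
      if (is.na(ineq) || !nzchar(ineq)) ineq <- "="
      prov[i] <- "BA"
      if (is.na(v)) {
        reason[i] <- "quantitative record without a measurement value"
      } else if (ineq == "=") {
        label[i] <- as.integer(v <= threshold_nM)
      } else if (ineq == "<") {
        if (v <= threshold_nM) label[i] <- 1L
        else reason[i] <- paste0("indeterminate bound <", v,
                                 " against threshold ", threshold_nM)
      } else if (ineq == ">") {
        if (v >= threshold_nM) label[i] <- 0L
        else reason[i] <- paste0("indeterminate bound >", v,
                                 " against threshold ", threshold_nM)
      } else {
        reason[i] <- paste0("unknown inequality '", ineq, "'")
      }
    } else if (.is_el(type)) {
      prov[i] <- "EL"
      label[i] <- 1L
    } else {
      # qualitative
      prov[i] <- "BA"
      v <- as.character(r$measurement_value[i])
      term <- if (!is.na(v) && !nzchar(gsub("[0-9. ]", "", v))) "" else v
      qual <- tolower(paste(type, term))
      if (grepl("positive", qual)) label[i] <- 1L
      else if (grepl("negative", qual)) label[i] <- 0L
      else reason[i] <- paste0("unmappable qualitative term '", type, "'")
    }
  }
  keep <- is.na(reason)
  list(
    examples = data.frame(allele = r$allele[keep], peptide = r$peptide[keep],
                          label = label[keep], provenance = prov[keep],
                          stringsAsFactors = FALSE),
    quarantined = data.frame(allele = r$allele[!keep],
                             peptide = r$peptide[!keep],
                             reason = reason[!keep], stringsAsFactors = FALSE)
  )
}

#' Filter alleles by peptide support
#'
#' Retains only alleles with strictly more than `min_count` labeled
#' examples, and summarizes the dataset.
#'
#' @param examples Data frame with columns allele, peptide, label.
#' @param min_count Support cut; an allele survives iff its count is
#'   `> min_count`. Default 20.
#' @return A list with `examples` (retained rows) and `summary` (list:
#'   total, retained, positives, allele_counts, length_freq per allele).
#' @export
filter_alleles <- function(examples, min_count = 20) {
  counts <- table(examples$allele)
  keep_alleles <- names(counts)[counts > min_count]
  kept <- examples[examples$allele %in% keep_alleles, , drop = FALSE]
  length_freq <- lapply(split(nchar(kept$peptide), kept$allele), table)
  summary <- list(
    total = nrow(examples),
    retained = nrow(kept),
    positives = sum(kept$label == 1L),
    n_alleles = length(keep_alleles),
    allele_counts = as.list(counts[keep_alleles]),
    length_freq = lapply(length_freq, as.list)
  )
  list(examples = kept, summary = summary)
}

#' Shuffled k-fold split
#'
#' Globally shuffles the example indices under a fixed seed, then cuts
#' them into `k` near-equal folds; when `n` is not a multiple of `k` the
#' leftover examples go to the lowest-index folds. The same seed always
#' reproduces the same folds.
#'
#' @param n Number of examples (or a data frame, whose row count is used).
#' @param k Number of folds, at least 2. Default 5.
#' @param seed Integer RNG seed for the shuffle.
#' @param stratify Optional label vector; when given, the shuffle-and-cut
#'   is applied within each class so folds keep the class ratio.
#' @return A list of `k` integer vectors partitioning `1:n`.
#' @export
shuffle_and_split <- function(n, k = 5, seed = 42, stratify = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(k >= 2)
  if (n < k) stop("cannot split ", n, " example(s) into ", k, " folds",
                  call. = FALSE)
  cut_folds <- function(idx, k) {
    m <- length(idx)
    sizes <- rep(m %/% k, k)
    extra <- m %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    split(idx, rep(seq_len(k), times = sizes))
  }
  with_seed(seed, {
    if (is.null(stratify)) {
      folds <- cut_folds(sample.int(n), k)
    } else {
      stopifnot(length(stratify) == n)
      folds <- vector("list", k)
      for (cls in unique(stratify)) {
        idx <- which(stratify == cls)
        sub <- cut_folds(idx[sample.int(length(idx))], k)
        for (nm in names(sub)) {
          j <- as.integer(nm)
          folds[[j]] <- c(folds[[j]], sub[[nm]])
        }
      }
      folds <- lapply(folds, sort)
    }
    unname(folds)
  })
}
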