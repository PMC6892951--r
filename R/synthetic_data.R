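# Seeded synthetic allele datasets with planted, recoverable structure:
# an anchor-position binding motif, a hydropathy bias and a length
# preference. These emulate the statistical shape of per-allele binding
# data well enough to exercise training, evaluation and the length probe
# end to end; they make no attempt at the motif of any real HLA allele.

#' Specify a planted binding motif
#'
#' Describes how synthetic positive peptides differ from the uniform
#' random background: at each anchor position of the 9-residue binding
#' core the residue is drawn from a small preferred set with probability
#' `motif_strength`; the remaining core positions are biased toward
#' hydrophobic residues with weight `exp(hydropathy_bias * hydropathy)`;
#' and positive lengths follow `length_dist`. `motif_strength = 0`
#' together with `hydropathy_bias = 0` and a uniform `length_dist` makes
#' positives statistically identical to negatives (the null generator).
#'
#' @param anchor_positions Anchor positions of the binding core, a subset
#'   of `c(1, 4, 6, 7, 9)` (the default).
#' @param preferred Named list mapping each anchor position (as character)
#'   to its preferred residue set; the default plants hydrophobic anchors
#'   (L/I/V at 1 and 9, F/Y/W at 4, L/M/I at 6 and 7).
#' @param motif_strength Probability an anchor uses its preferred set,
#'   in \[0, 1\]. Default 0.9.
#' @param hydropathy_bias Exponential tilt toward hydrophobic residues at
#'   non-anchor core positions; 0 disables. Default 1.
#' @param length_dist Probability vector over lengths 8--15 for positive
#'   peptides; the default concentrates on 9mers the way class I binding
#'   data do. Negatives are always uniform over 8--15.
#' @param positive_fraction Fraction of positive examples, in (0, 1).
#' @param noise_rate Label-flip probability, in \[0, 0.5).
#' @return A list of class `"motif_spec"`.
#' @export
motif_spec <- function(anchor_positions = c(1, 4, 6, 7, 9),
                       preferred = NULL,
                       motif_strength = 0.9,
                       hydropathy_bias = 1,
                       length_dist = c(0.05, 0.55, 0.15, 0.10,
                                       0.05, 0.04, 0.03, 0.03),
                       positive_fraction = 0.5,
                       noise_rate = 0) {
  stopifnot(all(anchor_positions %in% c(1, 4, 6, 7, 9)),
            motif_strength >= 0, motif_strength <= 1,
            hydropathy_bias >= 0,
            length(length_dist) == 8, all(length_dist >= 0),
            abs(sum(length_dist) - 1) < 1e-8,
            positive_fraction > 0, positive_fraction < 1,
            noise_rate >= 0, noise_rate < 0.5)
  if (is.null(preferred)) {
    defaults <- list(`1` = c("L", "I", "V"), `4` = c("F", "Y", "W"),
                     `6` = c("L", "M", "I"), `7` = c("L", "M", "I"),
                     `9` = c("L", "I", "V"))
    preferred <- defaults[as.character(anchor_positions)]
  }
  preferred <- preferred[as.character(anchor_positions)]
  if (any(vapply(preferred, function(s) is.null(s) || !length(s), TRUE)))
    stop("every anchor position needs a non-empty preferred residue set",
         call. = FALSE)
  bad <- setdiff(unlist(preferred), standard_residues())
  if (length(bad)) stop("preferred sets contain invalid residues: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(anchor_positions = as.integer(anchor_positions),
                 preferred = preferred,
                 motif_strength = motif_strength,
                 hydropathy_bias = hydropathy_bias,
                 length_dist = length_dist,
                 positive_fraction = positive_fraction,
                 noise_rate = noise_rate),
            class = "motif_spec")
}

# map binding-core positions (1..9) to original-sequence positions for a
# peptide of length L under the padding rule: identity for L >= 9; for an
# 8mer core positions 1-4 are residues 1-4 and core 6-9 are residues 5-8
# (core position 5 is padding and has no original residue)
core_to_original <- function(core_pos, L) {
  if (L >= 9L) return(core_pos)
  ifelse(core_pos <= 4L, core_pos, ifelse(core_pos >= 6L, core_pos - 1L, NA))
}

#' Generate a synthetic allele dataset
#'
#' Draws `n` labeled peptides for one synthetic allele: positives carry
#' the planted motif of `spec` (anchor residues from the preferred sets,
#' hydrophobic bias elsewhere in the core, lengths from the preferred
#' distribution), negatives are uniform random 8--15mers, and labels are
#' then flipped with the spec's noise rate. Identical spec + seed
#' reproduce the dataset exactly.
#'
#' @param spec A [motif_spec()].
#' @param n Number of examples, at least 20.
#' @param seed Integer RNG seed.
#' @param allele Allele name recorded on every row.
#' @return An object of class `"synthetic_dataset"`: list with `examples`
#'   (data frame: allele, peptide, label), `spec`, `seed`, `allele`.
#' @examples
#' ds <- generate_allele_dataset(motif_spec(), n = 50, seed = 7)
#' table(ds$examples$label)
#' @export
generate_allele_dataset <- function(spec, n, seed = 42L,
                                    allele = "SYN-A*01:01") {
  stopifnot(inherits(spec, "motif_spec"))
  if (n < 20) stop("n must be at least 20", call. = FALSE)
  res <- standard_residues()
  hyd_w <- exp(spec$hydropathy_bias * hydropathy(res))
  with_seed(seed, {
    n_pos <- max(1L, min(n - 1L, round(n * spec$positive_fraction)))
    labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    peptides <- character(n)
    for (i in seq_len(n)) {
      if (labels[i] == 1L) {
        L <- sample(8:15, 1L, prob = spec$length_dist)
        pep <- sample(res, L, replace = TRUE)
        core <- seq_len(min(L, 9L))
        biased <- setdiff(core, spec$anchor_positions)
        orig_b <- core_to_original(biased, L)
        orig_b <- orig_b[!is.na(orig_b)]
        if (spec$hydropathy_bias > 0 && length(orig_b))
          pep[orig_b] <- sample(res, length(orig_b), replace = TRUE,
                                prob = hyd_w)
        for (a in spec$anchor_positions) {
          o <- core_to_original(a, L)
          if (!is.na(o) && o <= L && stats::runif(1) < spec$motif_strength)
            pep[o] <- sample(spec$preferred[[as.character(a)]], 1L)
        }
      } else {
        L <- sample(8:15, 1L)
        pep <- sample(res, L, replace = TRUE)
      }
      peptides[i] <- paste(pep, collapse = "")
    }
    if (spec$noise_rate > 0) {
      flip <- stats::runif(n) < spec$noise_rate
      labels[flip] <- 1L - labels[flip]
    }
    ord <- sample.int(n)  # shuffle so positives are not block-ordered
    structure(list(examples = data.frame(allele = allele,
                                         peptide = peptides[ord],
                                         label = labels[ord],
                                         stringsAsFactors = FALSE),
                   spec = spec, seed = as.integer(seed), allele = allele),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic dataset [", x$allele, "]: ", nrow(x$examples),
      " peptides (", sum(x$examples$label), " positive), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset as an IEDB-style measurement table
#'
#' Emits a comma-delimited table in the dialect [read_measurement_table()]
#' reads, with quantitative affinities synthesized on the matching side of
#' the 500 nM labeling threshold (log-uniform in 1--500 nM for positives,
#' 501--50,000 nM for negatives), so the full real-data path — read,
#' label, filter, split — can be exercised on synthetic data. At noise 0
#' the round trip recovers the planted labels exactly.
#'
#' @param ds A `"synthetic_dataset"`.
#' @param path Output file path.
#' @param seed Seed for the synthesized affinity values.
#' @return `path`, invisibly. A JSON sidecar `<path>.json` records the
#'   spec and seed.
#' @export
write_iedb_like_table <- function(ds, path, seed = ds$seed + 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  ex <- ds$examples
  values <- with_seed(seed, ifelse(
    ex$label == 1L,
    10^stats::runif(nrow(ex), 0, log10(500)),
    10^stats::runif(nrow(ex), log10(501), log10(50000))))
  df <- data.frame(
    allele = ex$allele,
    peptide = ex$peptide,
    measurement_value = round(values, 2),
    measurement_inequality = "=",
    measurement_type = "quantitative affinity",
    measurement_source = "synthetic generator",
    original_allele = ex$allele,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(allele = ds$allele, n = nrow(ex), seed = ds$seed,
         value_seed = seed,
         spec = lapply(unclass(ds$spec), function(x)
           if (is.list(x)) lapply(x, identity) else x)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
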