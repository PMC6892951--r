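# The peptide-length-preference probe: score a uniform-length random
# peptide set with a trained allele model and report the length
# distribution of the top-scoring fraction.

#' Generate a random peptide probe set
#'
#' Draws `per_length_count` peptides of every length 8--15 (default 1,250
#' per length, 10,000 in total), residues uniform over the 20 standard
#' amino acids unless a background frequency table is given. Fully
#' deterministic under `seed`.
#'
#' @param per_length_count Peptides per length. Default 1250.
#' @param seed Integer RNG seed.
#' @param background Optional named numeric vector of residue weights over
#'   the 20 standard amino acids; default uniform.
#' @return An object of class `"probe_set"`: list with `peptides`
#'   (character vector), `lengths`, `per_length_count`, `seed`.
#' @examples
#' pr <- generate_probe(per_length_count = 2, seed = 1)
#' table(nchar(pr$peptides))
#' @export
generate_probe <- function(per_length_count = 1250L, seed = 42L,
                           background = NULL) {
  stopifnot(per_length_count >= 1)
  res <- standard_residues()
  w <- if (is.null(background)) rep(1, 20) else {
    stopifnot(all(res %in% names(background)))
    as.numeric(background[res])
  }
  lens <- rep(8:15, each = per_length_count)
  peptides <- with_seed(seed, vapply(lens, function(L)
    paste(sample(res, L, replace = TRUE, prob = w), collapse = ""), ""))
  structure(list(peptides = peptides, lengths = lens,
                 per_length_count = as.integer(per_length_count),
                 seed = as.integer(seed)),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("probe set: ", length(x$peptides), " random peptides, ",
      x$per_length_count, " per length 8-15 (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Select the top-scoring fraction of a probe
#'
#' Returns the indices of the `ceiling(fraction * N)` highest-scoring
#' peptides; score ties at the boundary are broken by stable input order.
#'
#' @param scores Numeric scores, one per probe peptide.
#' @param fraction Fraction to keep, in (0, 1]. Default 0.02 (top 2%).
#' @return Integer vector of selected indices.
#' @export
top_fraction <- function(scores, fraction = 0.02) {
  if (!length(scores)) stop("empty probe: nothing to select", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  n_sel <- ceiling(fraction * length(scores))
  order(scores, decreasing = TRUE)[seq_len(n_sel)]  # radix order is stable
}

#' Length distribution of a selected peptide set
#'
#' @param lengths Integer lengths of the selected peptides.
#' @param allele Optional allele name carried into the report.
#' @param fraction The selection fraction used (for the record).
#' @return An object of class `"length_pref"`: per-length counts and
#'   proportions over 8--15 and the modal length.
#' @export
length_distribution <- function(lengths, allele = NULL, fraction = NA_real_) {
  if (!length(lengths)) stop("empty selection: no length distribution",
                             call. = FALSE)
  counts <- table(factor(lengths, levels = 8:15))
  props <- counts / sum(counts)
  structure(list(allele = allele, fraction = fraction,
                 n_selected = length(lengths),
                 counts = c(counts), proportions = c(props),
                 modal_length = as.integer(names(counts)[which.max(counts)])),
            class = "length_pref")
}

#' Probe a trained model for its peptide-length preference
#'
#' Generates the random probe, scores it with the model, keeps the
#' top-scoring fraction and reports the length distribution of the
#' selection — the end-to-end probe for which length(s) an allele model
#' prefers to call binders.
#'
#' @param model A fitted `"pepcnn"` (or `"pepcnn_group"`) model.
#' @param per_length_count Peptides per length. Default 1250.
#' @param fraction Selected fraction. Default 0.02.
#' @param seed Probe RNG seed.
#' @param background Optional residue background (see [generate_probe()]).
#' @return A `"length_pref"` report.
#' @export
length_preference <- function(model, per_length_count = 1250L,
                              fraction = 0.02, seed = 42L,
                              background = NULL) {
  probe <- generate_probe(per_length_count, seed, background)
  scores <- predict(model, probe$peptides)
  sel <- top_fraction(scores, fraction)
  length_distribution(probe$lengths[sel],
                      allele = if (inherits(model, "pepcnn")) model$allele,
                      fraction = fraction)
}

#' @export
print.length_pref <- function(x, ...) {
  cat("Length preference",
      if (!is.null(x$allele)) paste0(" [", x$allele, "]"),
      ": top ", x$n_selected, " peptides\n", sep = "")
  df <- data.frame(length = 8:15, count = as.integer(x$counts),
                   proportion = round(unname(x$proportions), 3))
  print(df, row.names = FALSE)
  cat("  modal length: ", x$modal_length, "\n", sep = "")
  invisible(x)
}

#' @export
plot.length_pref <- function(x, ...) {
  graphics::barplot(x$proportions, names.arg = 8:15,
                    xlab = "peptide length", ylab = "proportion of selected",
                    main = if (!is.null(x$allele))
                      paste("Length preference:", x$allele)
                    else "Length preference", ...)
  invisible(x)
}

#' Write a length-preference report
#'
#' @param report A `"length_pref"` object.
#' @param path Output path; `.json` writes JSON, anything else a
#'   tab-delimited table.
#' @return `path`, invisibly.
#' @export
write_length_pref <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      allele = report$allele, fraction = report$fraction,
      n_selected = report$n_selected,
      counts = as.list(report$counts),
      proportions = as.list(report$proportions),
      modal_length = report$modal_length
    ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    utils::write.table(
      data.frame(length = 8:15, count = as.integer(report$counts),
                 proportion = unname(report$proportions)),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
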