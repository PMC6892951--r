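# Model evaluation: F1 at a probability cut, rank-based ROC-AUC, shuffled
# k-fold cross-validation per allele, and cohort summaries across alleles.

#' Confusion counts from binary labels and calls
#'
#' @param labels True 0/1 labels.
#' @param calls Predicted 0/1 calls.
#' @return A list of class `"confusion_counts"` with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_counts <- function(labels, calls) {
  stopifnot(length(labels) == length(calls))
  labels <- as.integer(labels); calls <- as.integer(calls)
  structure(list(tp = sum(labels == 1L & calls == 1L),
                 fp = sum(labels == 0L & calls == 1L),
                 fn = sum(labels == 1L & calls == 0L),
                 tn = sum(labels == 0L & calls == 0L)),
            class = "confusion_counts")
}

#' F1 score from confusion counts
#'
#' Computed as `2*TP / (2*TP + FN + FP)`, the harmonic mean of precision
#' and recall. When the denominator is zero (no true positives, no false
#' calls in either direction, i.e. no positives anywhere) the score is
#' defined as 0 and flagged via the `"degenerate"` attribute rather than
#' returned as `NaN`, so cohort averages stay defined but the case is
#' never hidden.
#'
#' @param counts A `"confusion_counts"` object, or the TP count when the
#'   individual counts are given.
#' @param fp,fn False positive / false negative counts (scalar form).
#' @return F1 in \[0, 1\]; attribute `degenerate` is `TRUE` when the
#'   denominator was zero.
#' @examples
#' f1_score(confusion_counts(c(1, 1, 0), c(1, 0, 1)))
#' f1_score(3, fp = 1, fn = 2)  # 6/9
#' @export
f1_score <- function(counts, fp = NULL, fn = NULL) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  } else {
    tp <- counts
    if (is.null(fp) || is.null(fn))
      stop("scalar form needs tp, fp and fn", call. = FALSE)
  }
  if (any(c(tp, fp, fn) < 0)) stop("negative counts", call. = FALSE)
  den <- 2 * tp + fn + fp
  if (den == 0) return(structure(0, degenerate = TRUE))
  structure(2 * tp / den, degenerate = FALSE)
}

#' ROC-AUC by rank statistic
#'
#' The area under the ROC curve computed as the Mann-Whitney probability
#' that a random positive outscores a random negative, with ties counted
#' one half.
#'
#' @param labels True 0/1 labels; both classes must be present.
#' @param scores Numeric scores (higher = more positive).
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cross-validate the binding classifier for one allele
#'
#' Shuffles the examples under `seed`, cuts them into `k` folds, and for
#' each fold trains on the remaining folds and scores the held-out fold:
#' F1 at the probability cut `threshold` and ROC-AUC. Folds whose training
#' data contain a single class are skipped and reported, never silently
#' averaged.
#'
#' @param peptides Character vector of peptide sequences.
#' @param labels Binary 0/1 labels.
#' @param k Number of folds. Default 5.
#' @param seed Seed for the shuffle (fold assignment); fold models train
#'   under per-fold seeds derived from it.
#' @param allele Optional allele name carried into the result.
#' @param threshold Probability cut for the F1 calls. Default 0.5.
#' @param fit_fun Model factory `function(x, y, seed)` returning an object
#'   with a `predict` method giving probabilities. Defaults to the
#'   convolutional classifier with configuration from `...`.
#' @param ... Configuration overrides passed to [pepcnn()].
#' @return An object of class `"pepcnn_cv"`: per-fold F1/AUC, their means,
#'   and any skipped folds.
#' @export
cross_validate <- function(peptides, labels, k = 5, seed = 42, allele = NULL,
                           threshold = 0.5, fit_fun = NULL, ...) {
  labels <- as.integer(labels)
  folds <- shuffle_and_split(length(labels), k = k, seed = seed)
  if (is.null(fit_fun))
    fit_fun <- function(x, y, seed) pepcnn(x, y, seed = seed, ...)
  f1 <- auc <- rep(NA_real_, k)
  skipped <- integer(0)
  for (j in seq_len(k)) {
    te <- folds[[j]]
    tr <- setdiff(seq_along(labels), te)
    if (length(unique(labels[tr])) < 2L || length(unique(labels[te])) < 2L) {
      skipped <- c(skipped, j)
      next
    }
    fit <- fit_fun(peptides[tr], labels[tr], seed = seed + j)
    p <- predict(fit, peptides[te])
    f1[j] <- as.numeric(f1_score(confusion_counts(labels[te],
                                                  as.integer(p >= threshold))))
    auc[j] <- auc_score(labels[te], p)
  }
  structure(list(allele = allele, k = k, seed = seed,
                 fold_f1 = f1, fold_auc = auc,
                 mean_f1 = mean(f1, na.rm = TRUE),
                 mean_auc = mean(auc, na.rm = TRUE),
                 skipped_folds = skipped, n = length(labels)),
            class = "pepcnn_cv")
}

#' @export
print.pepcnn_cv <- function(x, ...) {
  cat("Cross-validation", if (!is.null(x$allele)) paste0(" [", x$allele, "]"),
      ": ", x$k, " folds, n = ", x$n, "\n", sep = "")
  cat("  F1  per fold: ", paste(round(x$fold_f1, 3), collapse = " "),
      "  (mean ", round(x$mean_f1, 4), ")\n", sep = "")
  cat("  AUC per fold: ", paste(round(x$fold_auc, 3), collapse = " "),
      "  (mean ", round(x$mean_auc, 4), ")\n", sep = "")
  if (length(x$skipped_folds))
    cat("  skipped single-class folds: ",
        paste(x$skipped_folds, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Cross-validate every allele in a labeled dataset
#'
#' Applies [cross_validate()] per allele (after the support filter) and
#' collects the per-allele metrics.
#'
#' @param examples Data frame with columns allele, peptide, label.
#' @param min_count Allele support cut (strictly greater-than), default 20.
#' @param ... Passed to [cross_validate()].
#' @return A list of `"pepcnn_cv"` objects, one per retained allele.
#' @export
evaluate_alleles <- function(examples, min_count = 20, ...) {
  flt <- filter_alleles(examples, min_count)
  per <- split(flt$examples, flt$examples$allele)
  lapply(per, function(d)
    cross_validate(d$peptide, d$label, allele = d$allele[1], ...))
}

#' Summarize per-allele metrics across a cohort
#'
#' Mean, median and sample standard deviation (0 for a single allele) of
#' the per-allele mean F1 and mean AUC, plus binned distributions: F1 in
#' three bands (below 0.5, 0.5--0.9, above 0.9) and AUC in deciles.
#'
#' @param metrics List of `"pepcnn_cv"` objects (or a single one).
#' @return A list of class `"pepcnn_cohort"`.
#' @export
summarize_cohort <- function(metrics) {
  if (inherits(metrics, "pepcnn_cv")) metrics <- list(metrics)
  if (!length(metrics)) stop("empty metrics list", call. = FALSE)
  f1 <- vapply(metrics, `[[`, 0, "mean_f1")
  auc <- vapply(metrics, `[[`, 0, "mean_auc")
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  f1_bins <- c(`<0.5` = mean(f1 < 0.5),
               `0.5-0.9` = mean(f1 >= 0.5 & f1 <= 0.9),
               `>0.9` = mean(f1 > 0.9))
  auc_bins <- table(cut(auc, breaks = seq(0, 1, by = 0.1),
                        include.lowest = TRUE)) / length(auc)
  structure(list(
    n_alleles = length(metrics),
    f1 = list(mean = mean(f1), median = stats::median(f1), sd = sd0(f1),
              values = f1, bins = f1_bins),
    auc = list(mean = mean(auc), median = stats::median(auc), sd = sd0(auc),
               values = auc, bins = c(auc_bins))
  ), class = "pepcnn_cohort")
}

#' @export
print.pepcnn_cohort <- function(x, ...) {
  cat("Cohort summary over ", x$n_alleles, " allele(s)\n", sep = "")
  cat(sprintf("  F1 : mean %.3f  median %.3f  sd %.3f\n",
              x$f1$mean, x$f1$median, x$f1$sd))
  cat(sprintf("  AUC: mean %.3f  median %.3f  sd %.3f\n",
              x$auc$mean, x$auc$median, x$auc$sd))
  cat("  F1 bands: ",
      paste(names(x$f1$bins), sprintf("%.0f%%", 100 * x$f1$bins),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
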