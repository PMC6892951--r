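# shared test fixtures, all generated in code

random_peptide <- function(L) {
  paste(sample(aa_alphabet()[1:20], L, replace = TRUE), collapse = "")
}

# a small trained model on the strong-motif synthetic allele, cached so
# several test files can probe the same fit
fixture_env <- new.env()

fixture_model <- function() {
  if (is.null(fixture_env$model)) {
    ds <- generate_allele_dataset(motif_spec(), n = 800, seed = 101,
                                  allele = "SYN-A*02:01")
    fixture_env$data <- ds
    fixture_env$model <- pepcnn(ds$examples$peptide, ds$examples$label,
                                allele = ds$allele, seed = 7, epochs = 40)
  }
  fixture_env$model
}

# brute-force AUC: probability a random positive outranks a random
# negative, ties counted one half
auc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# F1 recomputed from raw (label, call) vectors built to match the counts
f1_from_vectors_oracle <- function(tp, fp, fn) {
  labels <- c(rep(1, tp), rep(0, fp), rep(1, fn))
  calls <- c(rep(1, tp), rep(1, fp), rep(0, fn))
  prec_den <- sum(calls == 1)
  rec_den <- sum(labels == 1)
  if (prec_den == 0 && rec_den == 0) return(0)
  prec <- if (prec_den == 0) 0 else sum(labels == 1 & calls == 1) / prec_den
  rec <- if (rec_den == 0) 0 else sum(labels == 1 & calls == 1) / rec_den
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
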