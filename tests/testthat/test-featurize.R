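# Frozen, independently transcribed property tables: the consensus
# hydropathy scale and the five polarity classes over the 21 symbols.
ref_hydropathy <- c(
  R = -2.5, K = -1.5, D = -0.9, Q = -0.85, N = -0.78, E = -0.74,
  H = 0.40, S = -0.18, T = -0.05, P = 0.12, Y = 0.26, C = 0.29,
  G = 0.48, A = 0.62, M = 0.64, W = 0.81, L = 1.1, V = 1.1,
  F = 1.2, I = 1.4, X = 0)
ref_polarity <- c(X = 0,
  A = 1, G = 1, I = 1, L = 1, F = 1, P = 1, V = 1,
  N = 2, C = 2, Q = 2, S = 2, T = 2, W = 2, Y = 2, M = 2,
  D = 3, E = 3, R = 4, H = 4, K = 4)

test_that("the 21-symbol alphabet and sequence index are fixed", {
  ab <- aa_alphabet()
  expect_length(ab, 21L)
  expect_identical(ab, c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                         "X"))
  expect_false(anyDuplicated(ab) > 0)
  expect_equal(sequence_index("A"), 1L)
  expect_equal(sequence_index("V"), 20L)
  expect_equal(sequence_index("X"), 21L)
  expect_equal(sequence_index(ab), 1:21)
  expect_error(sequence_index("B"), "invalid residue")
})

test_that("hydropathy and polarity lookups reproduce the tables exactly", {
  for (s in aa_alphabet()) {
    expect_identical(hydropathy(s), unname(ref_hydropathy[s]))
    expect_identical(polarity_class(s), unname(as.integer(ref_polarity[s])))
  }
  pt <- property_tables()
  expect_identical(unname(pt$hydropathy[names(ref_hydropathy)]),
                   unname(ref_hydropathy))
  expect_identical(pt$sequence_index[["X"]], 21L)
})

test_that("the extended substitution table matches canonical BLOSUM62", {
  st <- substitution_table()
  expect_equal(dim(st), c(21L, 21L))
  expect_true(isSymmetric(unname(st)))
  # X row: zeros against everything, 1 against itself
  expect_equal(unname(st["X", ]), c(rep(0L, 20), 1L))
  expect_equal(unname(st[, "X"]), c(rep(0L, 20), 1L))
  # independent reference copy of BLOSUM62
  ref <- local({ data("BLOSUM62", package = "Biostrings",
                      envir = environment()); BLOSUM62 })
  expect_identical(unname(st[1:20, 1:20]),
                   unname(ref[rownames(st)[1:20], colnames(st)[1:20]]))
})

test_that("substitution encoding picks the right rows", {
  m <- encode_substitution("ACDEFGHIK")
  expect_equal(dim(m), c(15L, 21L))
  # padded positions: one-hot on the X column
  for (i in 10:15) expect_equal(unname(m[i, ]), c(rep(0L, 20), 1L))
  expect_equal(unname(m[1, 1]), 4L)  # A against itself
  m2 <- encode_substitution("AADEFGHIK")
  expect_equal(m2[1, ], m2[2, ])  # same residue, same row
})

test_that("substitution encoding is injective on padded peptides", {
  set.seed(30)
  seqs <- unique(replicate(60, random_peptide(sample(8:15, 1))))
  encs <- vapply(seqs, function(s)
    paste(encode_substitution(s), collapse = ","), "")
  expect_equal(anyDuplicated(encs), 0L)
})

test_that("chemical encoding agrees with a per-symbol oracle loop", {
  set.seed(31)
  for (rep in 1:20) {
    raw <- random_peptide(sample(8:15, 1))
    np <- normalize_to_15mer(raw)
    cm <- encode_chemical(np)
    expect_equal(dim(cm), c(4L, 15L))
    chars <- strsplit(np$sequence15, "")[[1]]
    expect_equal(unname(cm[1, ]), sequence_index(chars))
    expect_equal(unname(cm[2, ]), hydropathy(chars))
    expect_equal(unname(cm[3, ]), polarity_class(chars))
    expect_equal(unname(cm[4, ]), rep(np$original_length, 15))
  }
})

test_that("chemical encoding marks padded positions as the null column", {
  cm <- encode_chemical("ACDEFGHIK")
  expect_equal(unname(cm[, 10]), c(21, 0, 0, 9))
  # R column: index 2, hydropathy -2.5, class 4
  cmr <- encode_chemical("RCDEFGHIK")
  expect_equal(unname(cmr[, 1]), c(2, -2.5, 4, 9))
})

test_that("batch encoding stacks matrices with the documented shapes", {
  peps <- c("ACDEFGHIK", "SIINFEKL", "KLMNPQRST")
  expect_equal(dim(encode_batch(peps, "chemical")$tensor), c(3L, 4L, 15L))
  expect_equal(dim(encode_batch(peps, "substitution")$tensor),
               c(3L, 21L, 15L))
  st <- encode_batch(peps, "stacked")
  expect_equal(dim(st$tensor), c(3L, 25L, 15L))
  # stacked = transposed substitution on top of the chemical rows
  expect_equal(st$tensor[2, 1:21, ],
               unname(t(encode_substitution("SIINFEKL"))))
  expect_equal(st$tensor[2, 22:25, ], unname(encode_chemical("SIINFEKL")))
})

test_that("batch encoding handles empty input and reports bad items", {
  empty <- encode_batch(character(0), "chemical")
  expect_equal(dim(empty$tensor), c(0L, 4L, 15L))
  err <- expect_error(encode_batch(c("ACDEFGHIK", "NOPE", "SIINFEKL")),
                      "item 2")
  expect_match(conditionMessage(err), "NOPE")
})
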