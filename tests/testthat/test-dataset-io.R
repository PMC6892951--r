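write_toy_table <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste("allele", "peptide", "measurement_value",
                  "measurement_inequality", "measurement_type",
                  "measurement_source", "original_allele", sep = ",")
  writeLines(c(header, rows), path)
  path
}

test_that("clean tables parse with nothing quarantined", {
  path <- write_toy_table(c(
    "HLA-A*02:01,SIINFEKL,50,=,quantitative affinity,src,HLA-A*02:01",
    "HLA-A*02:01,ACDEFGHIK,900,=,quantitative affinity,src,HLA-A*02:01",
    "HLA-B*27:05,KLMNPQRST,20,=,quantitative affinity,src,HLA-B*27:05"))
  got <- read_measurement_table(path)
  expect_equal(nrow(got$records), 3L)
  expect_equal(nrow(got$quarantined), 0L)
  expect_equal(got$records$allele[3], "HLA-B*27:05")
})

test_that("rows with invalid peptides are quarantined with reasons", {
  path <- write_toy_table(c(
    "HLA-A*02:01,SIINFEKL,50,=,quantitative affinity,src,x",
    "HLA-A*02:01,ACDEFB,60,=,quantitative affinity,src,x"))
  got <- read_measurement_table(path)
  expect_equal(nrow(got$records), 1L)
  expect_equal(got$quarantined$peptide, "ACDEFB")
  expect_match(got$quarantined$reason, "length 6")
})

test_that("schema problems and degenerate files are explicit", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("allele,value", "HLA-A*02:01,5"), bad)
  expect_error(read_measurement_table(bad), "missing mandatory.*peptide")
  hdr <- tempfile(fileext = ".csv")
  writeLines("allele,peptide", hdr)
  expect_equal(nrow(read_measurement_table(hdr)$records), 0L)
  expect_error(read_measurement_table(tempfile()), "cannot read")
})

test_that("tab-delimited dialect is auto-detected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("allele\tpeptide\tmeasurement_value",
               "HLA-A*02:01\tSIINFEKL\t50"), path)
  got <- read_measurement_table(path)
  expect_equal(got$records$peptide, "SIINFEKL")
})

test_that("quantitative labeling is threshold- and inequality-aware", {
  path <- write_toy_table(c(
    "A,SIINFEKL,50,=,quantitative affinity,s,A",       # 1
    "A,ACDEFGHIK,20000,>,quantitative affinity,s,A",   # 0 (bound above)
    "A,KLMNPQRST,1000,<,quantitative affinity,s,A",    # indeterminate
    "A,ACDEFGHIV,400,<,quantitative affinity,s,A",     # 1 (bound below)
    "A,ACDEFGHIW,500,=,quantitative affinity,s,A",     # 1 (at threshold)
    "A,ACDEFGHIY,501,=,quantitative affinity,s,A"))    # 0
  lab <- label_records(read_measurement_table(path)$records)
  expect_equal(nrow(lab$quarantined), 1L)
  expect_match(lab$quarantined$reason, "indeterminate")
  got <- lab$examples
  expect_equal(got$label[match(c("SIINFEKL", "ACDEFGHIK", "ACDEFGHIV",
                                 "ACDEFGHIW", "ACDEFGHIY"), got$peptide)],
               c(1L, 0L, 1L, 1L, 0L))
  expect_true(all(got$provenance == "BA"))
})

test_that("qualitative and eluted-ligand records map to labels", {
  path <- write_toy_table(c(
    "A,SIINFEKL,,,qualitative binding Positive-High,s,A",
    "A,ACDEFGHIK,,,qualitative binding Negative,s,A",
    "A,KLMNPQRST,,,eluted ligand,s,A",
    "A,ACDEFGHIV,,,qualitative binding mystery,s,A"))
  lab <- label_records(read_measurement_table(path)$records)
  got <- lab$examples
  expect_equal(got$label[match(c("SIINFEKL", "ACDEFGHIK", "KLMNPQRST"),
                               got$peptide)], c(1L, 0L, 1L))
  expect_equal(got$provenance[got$peptide == "KLMNPQRST"], "EL")
  expect_match(lab$quarantined$reason, "unmappable qualitative")
})

test_that("duplicate allele-peptide pairs keep the preferred provenance", {
  path <- write_toy_table(c(
    "A,SIINFEKL,,,eluted ligand,s,A",
    "A,SIINFEKL,900,=,quantitative affinity,s,A"))
  lab <- label_records(read_measurement_table(path)$records)
  expect_equal(nrow(lab$examples), 1L)
  # quantitative wins over EL, so the 900 nM record labels it negative
  expect_equal(lab$examples$label, 0L)
})

test_that("every input row lands in exactly one of retained or quarantined", {
  set.seed(40)
  rows <- vapply(1:30, function(i) {
    pep <- if (i %% 7 == 0) "BADPEP" else random_peptide(sample(8:15, 1))
    v <- sample(c(10, 5000), 1)
    paste("A", pep, v, "=", "quantitative affinity", "s", "A", sep = ",")
  }, "")
  path <- write_toy_table(rows)
  tab <- read_measurement_table(path)
  lab <- label_records(tab$records, dedupe = FALSE)
  expect_equal(nrow(tab$records) + nrow(tab$quarantined), 30L)
  expect_equal(nrow(lab$examples) + nrow(lab$quarantined), nrow(tab$records))
  expect_true(all(nzchar(tab$quarantined$reason)))
})

test_that("allele support filter uses a strict greater-than cut", {
  ex <- data.frame(
    allele = c(rep("A21", 21), rep("A20", 20)),
    peptide = replicate(41, random_peptide(9)),
    label = rep(c(0L, 1L), length.out = 41))
  flt <- filter_alleles(ex, min_count = 20)
  expect_setequal(unique(flt$examples$allele), "A21")
  expect_equal(flt$summary$retained, 21L)
  expect_equal(flt$summary$total, 41L)
  expect_equal(flt$summary$positives, sum(flt$examples$label))
  # everything below the cut: empty result is legal
  all_small <- filter_alleles(ex[ex$allele == "A20", ], min_count = 20)
  expect_equal(nrow(all_small$examples), 0L)
  expect_equal(all_small$summary$retained, 0L)
})

test_that("shuffled splits partition the data deterministically", {
  folds <- shuffle_and_split(10, k = 5, seed = 1)
  expect_equal(lengths(folds), rep(2L, 5))
  folds11 <- shuffle_and_split(11, k = 5, seed = 1)
  expect_equal(lengths(folds11), c(3L, 2L, 2L, 2L, 2L))
  expect_setequal(unlist(folds11), 1:11)
  expect_identical(folds11, shuffle_and_split(11, k = 5, seed = 1))
  expect_false(identical(folds11, shuffle_and_split(11, k = 5, seed = 2)))
  expect_error(shuffle_and_split(3, k = 5), "cannot split")
})

test_that("stratified splits keep the class ratio per fold", {
  y <- rep(c(0L, 1L), c(40, 10))
  folds <- shuffle_and_split(50, k = 5, seed = 3, stratify = y)
  expect_setequal(unlist(folds), 1:50)
  for (f in folds) expect_equal(sum(y[f]), 2L)
})
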