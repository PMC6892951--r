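test_that("configuration is validated before any training", {
  expect_error(pepcnn_config(dropout = 1), "dropout")
  expect_error(pepcnn_config(pool_size = 0))
  # geometry guards: kernel/pool incompatible with the 15-position axis
  expect_error(pepcnn:::cnn_geometry(pepcnn_config(kernel_size = 16), 4L),
               "kernel size")
  expect_error(pepcnn:::cnn_geometry(pepcnn_config(pool_size = 14), 4L),
               "pool size")
  # the faithful preset fits: 15 -> 13 -> 6 -> 4 -> 2, flatten 40
  g <- pepcnn:::cnn_geometry(pepcnn_config(), 4L)
  expect_equal(c(g$L1, g$P1, g$L2, g$P2, g$flat), c(13, 6, 4, 2, 40))
})

test_that("degenerate training data is refused", {
  expect_error(pepcnn("SIINFEKL", 1L), "at least 2")
  expect_error(pepcnn(c("SIINFEKL", "ACDEFGHIK"), c(1L, 1L)),
               "both classes")
  expect_error(pepcnn(c("SIINFEKL", "ACDEFGHIK"), c(1L, 2L)), "binary")
  expect_error(pepcnn(c("SIINFEKL", "ACDEFGHIK"), c(1L, 0L), nonsense = 1),
               "unknown configuration")
})

test_that("identical seed and config reproduce the fit exactly", {
  ds <- generate_allele_dataset(motif_spec(), n = 60, seed = 50)
  ex <- ds$examples
  f1 <- pepcnn(ex$peptide, ex$label, seed = 9, epochs = 3,
               validation_fraction = 0)
  f2 <- pepcnn(ex$peptide, ex$label, seed = 9, epochs = 3,
               validation_fraction = 0)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, ex$peptide), predict(f2, ex$peptide))
  f3 <- pepcnn(ex$peptide, ex$label, seed = 10, epochs = 3,
               validation_fraction = 0)
  expect_false(identical(f1$params, f3$params))
})

test_that("training loss decreases on a planted-motif dataset", {
  ds <- generate_allele_dataset(motif_spec(), n = 200, seed = 51)
  fit <- pepcnn(ds$examples$peptide, ds$examples$label, seed = 1,
                epochs = 10, validation_fraction = 0)
  h <- fit$history
  expect_equal(nrow(h), 10L)
  expect_lt(h$train_loss[10], h$train_loss[1])
})

test_that("constant inputs converge to the base-rate probability", {
  # analytic optimum of cross-entropy under a constant input is the
  # positive fraction; 10 of 30 labels are positive
  peps <- rep("SIINFEKLM", 30)
  y <- rep(c(1L, 0L, 0L), 10)
  fit <- pepcnn(peps, y, seed = 2, epochs = 150, validation_fraction = 0,
                dropout = 0, learning_rate = 1e-2)
  expect_equal(unique(round(predict(fit, peps[1:5]), 6)),
               round(predict(fit, peps[1]), 6))
  expect_lt(abs(predict(fit, peps[1]) - 1 / 3), 0.05)
})

test_that("predictions are probabilities, order-preserving and batch-stable", {
  fit <- fixture_model()
  set.seed(52)
  peps <- vapply(sample(8:15, 40, replace = TRUE), random_peptide, "")
  p <- predict(fit, peps)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict(fit, rev(peps)), rev(p), tolerance = 1e-12)
  one_at_a_time <- vapply(peps, function(s) predict(fit, s), 0,
                          USE.NAMES = FALSE)
  expect_equal(one_at_a_time, p, tolerance = 1e-6)
  expect_equal(p[1], predict(fit, c(peps[1], peps[1]))[2])
  expect_error(predict(fit, "AAAA"), "length 4")
  cls <- predict(fit, peps, type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
})

test_that("model methods behave like a classed fit", {
  fit <- fixture_model()
  expect_output(print(fit), "two|conv\\(20\\)")
  s <- summary(fit)
  expect_gt(s$train_auc, 0.8)
  expect_equal(s$n_parameters,
               sum(vapply(coef(fit), length, 0L)))
  expect_equal(residuals(fit), fit$labels - fitted(fit))
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_equal(dim(sims), c(length(fit$labels), 2L))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 5))
  expect_true(all(unlist(sims) %in% 0:1))
})

test_that("length-group scope trains submodels and dispatches by length", {
  ds <- generate_allele_dataset(motif_spec(), n = 300, seed = 53)
  ex <- ds$examples
  fit <- pepcnn_lengthgroups(ex$peptide, ex$label, seed = 3, epochs = 5,
                             min_group = 30)
  expect_s3_class(fit, "pepcnn_group")
  expect_named(fit$models, c("L<=8", "L=9", "L=10", "L>=11"))
  p <- predict(fit, c("SIINFEKL", "ACDEFGHIK", "ACDEFGHIKLMNPQ"))
  expect_length(p, 3L)
  expect_true(all(p >= 0 & p <= 1))
  # sparse groups fall back to the base rate
  tiny <- pepcnn_lengthgroups(ex$peptide, ex$label, min_group = 10000)
  expect_true(all(vapply(tiny$models, inherits, TRUE, "pepcnn_baserate")))
})

test_that("model bundles round-trip through disk", {
  fit <- fixture_model()
  dir <- tempfile()
  write_model_bundle(fit, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  back <- read_model_bundle(dir)
  peps <- c("SIINFEKL", "ACDEFGHIK")
  expect_identical(predict(back, peps), predict(fit, peps))
  expect_error(read_model_bundle(tempfile()), "no model bundle")
})
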