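# The per-allele binding classifier: a classic fit-function + S3-methods
# interface over the internal convolutional engine.

#' Configuration for the binding-prediction network
#'
#' The faithful preset follows the published architecture: two convolution
#' layers of 20 filters each, ReLU activations and max pooling, applied as
#' 1-D convolutions along the 15 peptide positions with the feature rows as
#' input channels. Details the architecture leaves open are pinned here and
#' are all overridable: kernel size 3, pool size 2, one 64-unit dense
#' layer, dropout 0.25, a sigmoid probability output, Adam-style
#' optimization at learning rate 1e-3, batch size 32, up to 100 epochs
#' with early stopping (patience 10) on a held-out validation split.
#'
#' @param mode Peptide encoding fed to the network: `"chemical"` (4x15,
#'   the default), `"substitution"` (21x15) or `"stacked"` (25x15).
#' @param filters Filters per convolution layer (both layers). Default 20.
#' @param kernel_size 1-D kernel width along the position axis. Default 3.
#' @param pool_size Max-pooling width. Default 2.
#' @param dense_units Units in the dense head. Default 64.
#' @param dropout Dropout rate on the dense head during training.
#' @param learning_rate,batch_size,epochs Optimizer settings.
#' @param patience Early-stopping patience in epochs; validation loss is
#'   monitored on an internal split of `validation_fraction` of the data.
#' @param validation_fraction Fraction held out for early stopping;
#'   set to 0 to train on everything for exactly `epochs` epochs.
#' @param standardize Standardize each feature channel to zero mean and
#'   unit variance on the training set? Default `FALSE` (raw features).
#' @param seed Integer seed governing initialization, batching and dropout.
#' @return A list of class `"pepcnn_config"`.
#' @export
pepcnn_config <- function(mode = c("chemical", "substitution", "stacked"),
                          filters = 20L, kernel_size = 3L, pool_size = 2L,
                          dense_units = 64L, dropout = 0.25,
                          learning_rate = 1e-3, batch_size = 32L,
                          epochs = 100L, patience = 10L,
                          validation_fraction = 0.1,
                          standardize = FALSE, seed = 42L) {
  mode <- match.arg(mode)
  stopifnot(filters >= 1, kernel_size >= 1, pool_size >= 1,
            dense_units >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1,
            patience >= 1, validation_fraction >= 0,
            validation_fraction < 1)
  structure(list(mode = mode, filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "pepcnn_config")
}

# per-channel standardization statistics from a training tensor
channel_stats <- function(X) {
  C <- dim(X)[2]
  center <- numeric(C); scale <- numeric(C)
  for (c in seq_len(C)) {
    v <- X[, c, ]
    center[c] <- mean(v)
    s <- stats::sd(as.numeric(v))
    scale[c] <- if (is.finite(s) && s > 0) s else 1
  }
  list(center = center, scale = scale)
}

apply_channel_stats <- function(X, st) {
  for (c in seq_len(dim(X)[2]))
    X[, c, ] <- (X[, c, ] - st$center[c]) / st$scale[c]
  X
}

#' Fit a peptide-MHC binding classifier
#'
#' Trains the convolutional binding classifier for one allele on labeled
#' peptides: each 8--15mer is padded to the canonical 15mer, encoded per
#' `config$mode`, and the network is trained with binary cross-entropy.
#' Training is fully reproducible under `config$seed`.
#'
#' @param x Character vector of peptide sequences (8--15 residues each),
#'   or a formula like `label ~ peptide` together with `data`.
#' @param y Binary labels (0/1, or logical), one per peptide.
#' @param config A [pepcnn_config()]; individual settings can also be
#'   overridden through `...` (e.g. `pepcnn(x, y, epochs = 30)`).
#' @param allele Optional allele name stored with the model.
#' @param data,... For the formula method, the data frame holding the
#'   variables; otherwise configuration overrides.
#' @return An object of class `"pepcnn"` with `print`, `summary`,
#'   `predict`, `fitted`, `residuals`, `coef`, `simulate` and `plot`
#'   methods.
#' @examples
#' \donttest{
#' ds <- generate_allele_dataset(motif_spec(), n = 200, seed = 1)
#' fit <- pepcnn(ds$examples$peptide, ds$examples$label, epochs = 5)
#' head(predict(fit, c("SIINFEKL", "ILKEPVHGV")))
#' }
#' @export
pepcnn <- function(x, ...) UseMethod("pepcnn")

#' @rdname pepcnn
#' @export
pepcnn.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  pepcnn.default(as.character(mf[[2L]]), mf[[1L]], ...)
}

#' @rdname pepcnn
#' @export
pepcnn.default <- function(x, y, config = pepcnn_config(), allele = NULL,
                           ...) {
  dots <- list(...)
  if (length(dots)) {
    known <- names(formals(pepcnn_config))
    bad <- setdiff(names(dots), known)
    if (length(bad)) stop("unknown configuration option(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg <- unclass(config)
    cfg[names(dots)] <- dots
    config <- do.call(pepcnn_config, cfg)
  }
  y <- as.integer(y)
  if (length(x) != length(y))
    stop("x and y lengths differ", call. = FALSE)
  if (length(y) < 2L)
    stop("degenerate data: need at least 2 examples", call. = FALSE)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate data: both classes must be present", call. = FALSE)
  batch <- encode_batch(x, mode = config$mode)
  X <- batch$tensor
  stats <- NULL
  if (config$standardize) {
    stats <- channel_stats(X)
    X <- apply_channel_stats(X, stats)
  }
  fitres <- cnn_train(X, y, config)
  obj <- structure(list(
    call = match.call(),
    allele = allele,
    config = config,
    params = fitres$params,
    geometry = fitres$geometry,
    channel_stats = stats,
    history = fitres$history,
    training = list(n = length(y), positives = sum(y),
                    epochs_run = fitres$epochs_run,
                    best_epoch = fitres$best_epoch,
                    final_loss = utils::tail(fitres$history$train_loss, 1)),
    peptides = x, labels = y
  ), class = "pepcnn")
  obj$fitted_values <- predict(obj, x)
  obj
}

#' Predict binding probabilities
#'
#' @param object A fitted `"pepcnn"` model.
#' @param newdata Character vector of peptides (8--15 residues). Defaults
#'   to the training peptides.
#' @param type `"response"` for probabilities (default) or `"class"` for
#'   0/1 calls at `threshold`.
#' @param threshold Probability cut for `type = "class"`. Default 0.5.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\] (or integer labels),
#'   one per peptide, in input order.
#' @export
predict.pepcnn <- function(object, newdata = NULL,
                           type = c("response", "class"), threshold = 0.5,
                           ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$peptides
  X <- encode_batch(newdata, mode = object$config$mode)$tensor
  if (!is.null(object$channel_stats))
    X <- apply_channel_stats(X, object$channel_stats)
  p <- cnn_forward(object$params, X, object$geometry, object$config)$p
  if (type == "class") as.integer(p >= threshold) else p
}

#' @export
print.pepcnn <- function(x, ...) {
  cat("Peptide-MHC binding CNN",
      if (!is.null(x$allele)) paste0(" [", x$allele, "]"), "\n", sep = "")
  cat("  encoding: ", x$config$mode, " (", x$geometry$C, " x 15)\n", sep = "")
  cat("  architecture: conv(", x$config$filters, ") -> relu -> maxpool -> ",
      "conv(", x$config$filters, ") -> relu -> maxpool -> dense(",
      x$config$dense_units, ") -> sigmoid\n", sep = "")
  cat("  trained on ", x$training$n, " peptides (", x$training$positives,
      " positive), ", x$training$epochs_run, " epochs, final loss ",
      signif(x$training$final_loss, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pepcnn <- function(object, ...) {
  p <- object$fitted_values
  y <- object$labels
  cc <- confusion_counts(y, as.integer(p >= 0.5))
  out <- list(model = object,
              train_f1 = f1_score(cc),
              train_auc = auc_score(y, p),
              confusion = cc,
              n_parameters = sum(vapply(object$params, length, 0L)))
  class(out) <- "summary.pepcnn"
  out
}

#' @export
print.summary.pepcnn <- function(x, ...) {
  print(x$model)
  cat("  parameters: ", x$n_parameters, "\n", sep = "")
  cat("  training F1 (cut 0.5): ", round(x$train_f1, 4),
      ", training AUC: ", round(x$train_auc, 4), "\n", sep = "")
  invisible(x)
}

#' @export
fitted.pepcnn <- function(object, ...) object$fitted_values

#' @export
residuals.pepcnn <- function(object, ...) {
  object$labels - object$fitted_values
}

#' @export
coef.pepcnn <- function(object, ...) object$params

#' Simulate labels from a fitted binding model
#'
#' Draws Bernoulli labels from the model's predicted binding
#' probabilities, the model-based parametric simulation for a binary
#' classifier.
#'
#' @param object A fitted `"pepcnn"` model.
#' @param nsim Number of simulated label vectors.
#' @param seed Integer seed.
#' @param newdata Peptides to simulate for; defaults to training peptides.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of 0/1 labels.
#' @export
simulate.pepcnn <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            ...) {
  p <- predict(object, newdata)
  draw <- function() as.integer(stats::runif(length(p)) < p)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' @export
plot.pepcnn <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "binary cross-entropy", ylim = range(
                   c(h$train_loss, h$val_loss), na.rm = TRUE, finite = TRUE),
                 main = "training history", ...)
  if (any(is.finite(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' Fit one classifier per peptide-length group
#'
#' The alternative model scope: instead of one model per allele across all
#' lengths, fit four submodels on the length groups L<=8, L=9, L=10 and
#' L>=11 and dispatch predictions by peptide length. Groups with fewer
#' than `min_group` examples or a single class fall back to the base-rate
#' predictor for that group (reported in the object).
#'
#' @param x Peptides; @param y binary labels; passed to [pepcnn()].
#' @param y Binary labels.
#' @param min_group Minimum examples to train a group model. Default 30.
#' @param ... Passed on to [pepcnn()].
#' @return An object of class `"pepcnn_group"` with a `predict` method.
#' @export
pepcnn_lengthgroups <- function(x, y, min_group = 30L, ...) {
  grp <- length_group(nchar(x))
  models <- list()
  for (gname in c("L<=8", "L=9", "L=10", "L>=11")) {
    sel <- grp == gname
    ys <- as.integer(y[sel])
    if (sum(sel) >= min_group && length(unique(ys)) == 2L) {
      models[[gname]] <- pepcnn(x[sel], ys, ...)
    } else {
      models[[gname]] <- list(base_rate = if (sum(sel)) mean(ys) else 0.5)
      class(models[[gname]]) <- "pepcnn_baserate"
    }
  }
  structure(list(models = models, n = length(y)), class = "pepcnn_group")
}

length_group <- function(L) {
  cut(L, breaks = c(-Inf, 8, 9, 10, Inf),
      labels = c("L<=8", "L=9", "L=10", "L>=11"))
}

#' @export
predict.pepcnn_group <- function(object, newdata, ...) {
  grp <- length_group(nchar(newdata))
  p <- numeric(length(newdata))
  for (gname in names(object$models)) {
    sel <- grp == gname
    if (!any(sel)) next
    m <- object$models[[gname]]
    p[sel] <- if (inherits(m, "pepcnn_baserate")) m$base_rate
              else predict(m, newdata[sel])
  }
  p
}

#' @export
print.pepcnn_group <- function(x, ...) {
  cat("Length-grouped binding CNN (", x$n, " training peptides)\n", sep = "")
  for (gname in names(x$models)) {
    m <- x$models[[gname]]
    cat("  ", format(gname, width = 6), ": ",
        if (inherits(m, "pepcnn_baserate"))
          paste0("base rate ", round(m$base_rate, 3))
        else paste0("CNN, n = ", m$training$n), "\n", sep = "")
  }
  invisible(x)
}

#' Save / load a trained model bundle
#'
#' A bundle is a directory holding the serialized model and a plain-JSON
#' sidecar with the configuration and training summary.
#'
#' @param object A fitted `"pepcnn"` or `"pepcnn_group"` model.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (write) or the model (read), invisibly for write.
#' @export
write_model_bundle <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(object, file.path(dir, "model.rds"))
  if (inherits(object, "pepcnn")) {
    meta <- list(allele = object$allele, config = unclass(object$config),
                 training = object$training)
    jsonlite::write_json(meta, file.path(dir, "model.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path))
    stop("no model bundle at '", dir, "' (expected ", path, ")",
         call. = FALSE)
  readRDS(path)
}
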