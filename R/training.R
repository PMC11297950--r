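#' Training configuration
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 2e-4, beta1 0.9, beta2 0.999, epsilon 1e-6, decoupled L2 weight decay
#' 2e-5 (weights only, not biases), batch size 64, at most 500 epochs with
#' early stopping on the validation cross-entropy loss.
#'
#' @param learning_rate,beta1,beta2,epsilon,weight_decay Adam settings.
#' @param batch_size Proteins per gradient step (default 64).
#' @param max_epochs Maximum epochs (default 500).
#' @param patience Early-stop patience: number of consecutive validation
#'   epochs without improvement tolerated before stopping (default 20).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return A list of class `coev_train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-6, weight_decay = 2e-5,
                         batch_size = 64, max_epochs = 500, patience = 20,
                         seed = 1) {
  stopifnot(learning_rate > 0, beta1 > 0, beta2 > 0, epsilon > 0,
            weight_decay >= 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "coev_train_config")
}

#' Multi-label binary cross-entropy loss
#'
#' `-(1/N) * sum_i sum_j [y_ij log(p_ij) + (1 - y_ij) log(1 - p_ij)]`:
#' mean over samples, sum over function classes. Predictions are clipped
#' to `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param predictions `N x F` matrix of probabilities.
#' @param truths `N x F` binary matrix.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(predictions, truths) {
  predictions <- as.matrix(predictions)
  truths <- as.matrix(truths)
  if (!all(dim(predictions) == dim(truths))) {
    stop(sprintf("shape mismatch: predictions %dx%d vs truths %dx%d",
                 nrow(predictions), ncol(predictions),
                 nrow(truths), ncol(truths)))
  }
  eps <- 1e-7
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -sum(truths * log(p) + (1 - truths) * log(1 - p)) / nrow(p)
}

#' Labelled protein dataset
#'
#' @param proteins List of [protein_graph()] objects, each carrying a
#'   binary label vector of length `F`.
#' @param vocabulary Character vector of the `F` function-label
#'   identifiers.
#' @param split Character vector (`"train"`, `"validation"`, `"test"`) of
#'   the same length as `proteins`.
#' @return An object of class `coev_dataset`.
#' @export
coev_dataset <- function(proteins, vocabulary, split) {
  stopifnot(length(split) == length(proteins),
            all(split %in% c("train", "validation", "test")))
  nf <- length(vocabulary)
  ok <- vapply(proteins, function(g) length(g$labels) == nf, logical(1))
  if (!all(ok)) stop("all label vectors must have length ", nf)
  structure(list(proteins = proteins, vocabulary = vocabulary,
                 split = split), class = "coev_dataset")
}

#' @export
print.coev_dataset <- function(x, ...) {
  cat(sprintf("coev_dataset: %d proteins, %d labels (%s)\n",
              length(x$proteins), length(x$vocabulary),
              paste(sprintf("%s: %d", names(table(x$split)), table(x$split)),
                    collapse = ", ")))
  invisible(x)
}

#' @keywords internal
dataset_labels <- function(dataset, idx = seq_along(dataset$proteins)) {
  do.call(rbind, lapply(dataset$proteins[idx], function(g) g$labels))
}

#' Train the dual-channel GCN
#'
#' Minimizes the multi-label cross-entropy with Adam over mini-batches of
#' proteins (stacked into block-diagonal graphs), evaluating the
#' validation loss after every epoch. Training stops after `patience`
#' epochs without strict improvement, or at `max_epochs`; the returned
#' parameters are those of the best validation epoch. Fully reproducible
#' given `config$seed`.
#'
#' @param dataset A [coev_dataset()] with nonempty train and validation
#'   splits.
#' @param hidden GCN hidden width (default 512).
#' @param fc_hidden First FC layer width (default `hidden`).
#' @param dropout Dropout rate for the second FC layer (default 0.3).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `coev_fit`: list with `model` (best-epoch
#'   [dual_gcn()] parameters), `log` (tibble: epoch, train_loss,
#'   val_loss), `best_epoch`, `config`.
#' @export
train_dual_gcn <- function(dataset, hidden = 512, fc_hidden = hidden,
                           dropout = 0.3, config = train_config(),
                           verbose = FALSE) {
  stopifnot(inherits(dataset, "coev_dataset"),
            inherits(config, "coev_train_config"))
  tr_idx <- which(dataset$split == "train")
  va_idx <- which(dataset$split == "validation")
  if (length(tr_idx) == 0 || length(va_idx) == 0) {
    stop("dataset needs nonempty train and validation splits")
  }
  D <- ncol(dataset$proteins[[1]]$features)
  nf <- length(dataset$vocabulary)
  va_batch <- build_batch(dataset$proteins[va_idx])
  va_y <- dataset_labels(dataset, va_idx)
  withr::with_seed(config$seed, {
    model <- dual_gcn(D, nf, hidden = hidden, fc_hidden = fc_hidden,
                      dropout = dropout, vocabulary = dataset$vocabulary,
                      seed = sample.int(2^30, 1))
    opt <- list(m = lapply(model$par, function(x) x * 0),
                v = lapply(model$par, function(x) x * 0), step = 0L)
    best_val <- Inf
    best_par <- model$par
    best_epoch <- 0L
    wait <- 0L
    log <- vector("list", config$max_epochs)
    # batch composition is drawn once (seeded) and the stacked structures
    # cached; epochs reshuffle only the batch order
    ord <- sample(tr_idx)
    parts <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    batches <- lapply(parts, function(bi)
      list(batch = build_batch(dataset$proteins[bi]),
           y = dataset_labels(dataset, bi), n = length(bi)))
    for (epoch in seq_len(config$max_epochs)) {
      epoch_loss <- 0
      for (b in batches[sample(length(batches))]) {
        fw <- forward_batch(b$batch, model, training = TRUE, keep_cache = TRUE)
        epoch_loss <- epoch_loss + bce_loss(fw$probs, b$y) * b$n
        grads <- backward_batch(fw$cache, b$y, model)
        upd <- adam_step(model$par, grads, opt, config)
        model$par <- upd$par
        opt <- upd$opt
      }
      train_loss <- epoch_loss / length(tr_idx)
      va_fw <- forward_batch(va_batch, model, training = FALSE)
      val_loss <- bce_loss(va_fw$probs, va_y)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stop(sprintf("training diverged at epoch %d (loss is not finite)", epoch))
      }
      log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        train_loss, val_loss))
      }
      if (val_loss < best_val) {
        best_val <- val_loss
        best_par <- model$par
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    model$par <- best_par
    structure(list(model = model,
                   log = dplyr::bind_rows(log[!vapply(log, is.null, logical(1))]),
                   best_epoch = best_epoch, best_val_loss = best_val,
                   config = config),
              class = "coev_fit")
  })
}

# One Adam step with decoupled L2 weight decay on weight matrices (biases
# exempt). Returns the updated parameters and optimizer state.
#' @keywords internal
adam_step <- function(par, grads, opt, config) {
  t <- opt$step + 1L
  bc1 <- 1 - config$beta1^t
  bc2 <- 1 - config$beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- config$beta1 * opt$m[[nm]] + (1 - config$beta1) * g
    opt$v[[nm]] <- config$beta2 * opt$v[[nm]] + (1 - config$beta2) * g^2
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + config$epsilon)
    if (startsWith(nm, "W") && config$weight_decay > 0) {
      upd <- upd + config$weight_decay * par[[nm]]
    }
    par[[nm]] <- par[[nm]] - config$learning_rate * upd
  }
  opt$step <- t
  list(par = par, opt = opt)
}

#' Predict function-annotation probabilities
#'
#' Runs the trained model over proteins with dropout disabled; the result
#' is deterministic.
#'
#' @param object A `coev_fit` from [train_dual_gcn()] (or a `coev_model`).
#' @param proteins List of [protein_graph()] objects, or a
#'   [coev_dataset()] (optionally restricted via `split`).
#' @param split When `proteins` is a dataset: which split to score
#'   (`NULL` = all proteins).
#' @param ... Unused.
#' @return `N x F` matrix of probabilities with vocabulary column names
#'   (when known) and protein ids as row names (when known).
#' @export
predict.coev_fit <- function(object, proteins, split = NULL, ...) {
  predict_graphs(object$model, proteins, split = split)
}

#' @rdname predict.coev_fit
#' @export
predict.coev_model <- function(object, proteins, split = NULL, ...) {
  predict_graphs(object, proteins, split = split)
}

#' @keywords internal
predict_graphs <- function(model, proteins, split = NULL) {
  if (inherits(proteins, "coev_dataset")) {
    if (!is.null(model$config$vocabulary) &&
        !identical(model$config$vocabulary, proteins$vocabulary)) {
      stop("label vocabulary of the dataset does not match the model's")
    }
    idx <- if (is.null(split)) seq_along(proteins$proteins) else
      which(proteins$split == split)
    proteins <- proteins$proteins[idx]
  }
  batch <- build_batch(proteins)
  probs <- forward_batch(batch, model, training = FALSE)$probs
  ids <- vapply(proteins, function(g) g$id %||% NA_character_, character(1))
  if (!anyNA(ids)) rownames(probs) <- ids
  probs
}

#' @export
print.coev_fit <- function(x, ...) {
  cat(sprintf("coev_fit: best epoch %d (val loss %.5f) of %d run\n",
              x$best_epoch, x$best_val_loss, nrow(x$log)))
  invisible(x)
}

#' Tidy the per-epoch training log
#'
#' @param x A `coev_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.coev_fit <- function(x, ...) x$log

#' One-row summary of a fit
#'
#' @param x A `coev_fit`.
#' @param ... Unused.
#' @return One-row tibble: epochs run, best epoch, best validation loss,
#'   final training loss.
#' @export
glance.coev_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_train_loss = x$log$train_loss[nrow(x$log)])
}

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics (broom-style) for package objects.
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot the training log
#'
#' @param object A `coev_fit`.
#' @param ... Unused.
#' @return A ggplot object showing train and validation loss per epoch.
#' @method autoplot coev_fit
#' @export
autoplot.coev_fit <- function(object, ...) {
  df <- tidyr_longer_losses(object$log)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @keywords internal
tidyr_longer_losses <- function(log) {
  rbind(tibble::tibble(epoch = log$epoch, loss = log$train_loss, set = "train"),
        tibble::tibble(epoch = log$epoch, loss = log$val_loss, set = "validation"))
}

#' Serialize a model to a JSON archive
#'
#' Writes weights plus a manifest (shapes, config, seed, package version)
#' into a single JSON file.
#'
#' @param model A `coev_model` (or `coev_fit`, whose model is taken).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "coev_fit")) model <- model$model
  stopifnot(inherits(model, "coev_model"))
  payload <- list(
    manifest = list(format = "coevnet-model", version = "1",
                    package_version = as.character(utils::packageVersion("coevnet")),
                    config = model$config,
                    shapes = lapply(model$par, function(x)
                      if (is.matrix(x)) dim(x) else length(x))),
    par = lapply(model$par, as.numeric))  # column-major flattening
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model from a JSON archive
#'
#' @param path Path written by [write_model()].
#' @return A `coev_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$manifest$format, "coevnet-model")) {
    stop("not a coevnet model archive: ", path)
  }
  cfg <- payload$manifest$config
  par <- payload$par
  shapes <- payload$manifest$shapes
  for (nm in names(par)) {
    if (length(shapes[[nm]]) == 2) {
      par[[nm]] <- matrix(as.numeric(par[[nm]]), shapes[[nm]][1], shapes[[nm]][2])
    } else {
      par[[nm]] <- as.numeric(par[[nm]])
    }
  }
  structure(list(par = par,
                 config = list(D = cfg$D, hidden = cfg$hidden,
                               fc_hidden = cfg$fc_hidden,
                               n_classes = cfg$n_classes, dropout = cfg$dropout,
                               output = cfg$output,
                               vocabulary = cfg$vocabulary,
                               seed = cfg$seed)),
            class = "coev_model")
}
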