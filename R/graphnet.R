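#' Protein graph
#'
#' Bundles the per-residue node feature matrix with the two binary channel
#' adjacencies (evolutionary couplings, residue communities) and an optional
#' multi-label target vector.
#'
#' @param features `L x D` numeric feature matrix.
#' @param adj_evc,adj_rc Binary symmetric `L x L` adjacencies with zero
#'   diagonal (channels 1 and 2).
#' @param labels Optional binary vector of length `F` (one per function
#'   class).
#' @param id Optional protein identifier.
#' @param sequence Optional amino-acid string of length `L`.
#' @return An object of class `coev_graph`.
#' @export
protein_graph <- function(features, adj_evc, adj_rc, labels = NULL,
                          id = NULL, sequence = NULL) {
  features <- unclass(as.matrix(features))
  attr(features, "featurizer") <- NULL
  L <- nrow(features)
  check_adj <- function(A, name) {
    if (!is.matrix(A) || nrow(A) != L || ncol(A) != L) {
      stop(name, " must be an L x L matrix matching the features (L = ", L, ")")
    }
    if (max(abs(A - t(A))) > 0) stop(name, " must be symmetric")
    if (!all(A %in% c(0, 1))) stop(name, " must be binary")
    if (any(diag(A) != 0)) stop(name, " must have a zero diagonal")
    unname(A)
  }
  adj_evc <- check_adj(adj_evc, "adj_evc")
  adj_rc <- check_adj(adj_rc, "adj_rc")
  if (!all(is.finite(features))) stop("features must be finite")
  if (!is.null(labels)) stopifnot(all(labels %in% c(0, 1)))
  # normalized sparse adjacencies cached once; training reuses them every epoch
  structure(list(features = features, adj_evc = adj_evc, adj_rc = adj_rc,
                 labels = labels, id = id, sequence = sequence,
                 norm_evc = Matrix::Matrix(normalize_adjacency(adj_evc),
                                           sparse = TRUE),
                 norm_rc = Matrix::Matrix(normalize_adjacency(adj_rc),
                                          sparse = TRUE)),
            class = "coev_graph")
}

#' @export
print.coev_graph <- function(x, ...) {
  cat(sprintf("coev_graph: L = %d, D = %d, |E_evc| = %d, |E_rc| = %d%s\n",
              nrow(x$features), ncol(x$features),
              sum(x$adj_evc) / 2, sum(x$adj_rc) / 2,
              if (is.null(x$labels)) "" else
                sprintf(", %d/%d positive labels", sum(x$labels), length(x$labels))))
  invisible(x)
}

#' Symmetric normalized adjacency with self-loops
#'
#' Returns `D^{-1/2} (A + I) D^{-1/2}` where `D(i,i) = sum_j (A + I)(i,j)`.
#' Self-loops guarantee every degree is at least 1, so the normalization is
#' always defined; the result is symmetric with spectral radius at most 1.
#'
#' @param A Binary symmetric adjacency matrix.
#' @return Normalized adjacency matrix (dense).
#' @export
normalize_adjacency <- function(A) {
  A_hat <- A + diag(nrow(A))
  d <- rowSums(A_hat)
  inv_sqrt <- 1 / sqrt(d)
  A_hat * outer(inv_sqrt, inv_sqrt)
}

#' Single graph-convolution layer
#'
#' The normalized propagation rule: `activation(A_norm %*% H %*% W + b)`.
#'
#' @param H `L x d` input representation.
#' @param A_norm Normalized adjacency from [normalize_adjacency()].
#' @param W `d x d'` weight matrix.
#' @param b Optional bias vector of length `d'`.
#' @param activation `"relu"` or `"identity"`.
#' @return `L x d'` output representation.
#' @export
gcn_layer <- function(H, A_norm, W, b = NULL, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(H) != nrow(W)) {
    stop(sprintf("shape mismatch in gcn_layer: H is %dx%d but W is %dx%d",
                 nrow(H), ncol(H), nrow(W), ncol(W)))
  }
  S <- as.matrix(A_norm %*% H %*% W)
  if (!is.null(b)) S <- sweep(S, 2, b, "+")
  if (activation == "relu") relu(S) else S
}

#' Initialize a dual-channel stacked GCN model
#'
#' The architecture: two independent channels of three GCN layers each
#' (channel 1 propagates over the evolutionary-coupling adjacency, channel
#' 2 over the residue-community adjacency), channel outputs concatenated
#' along the feature axis into the residue-resolved feature map, sum-pooled
#' over residues, then two fully connected layers (ReLU after the first,
#' dropout before the second) ending in per-class sigmoid probabilities.
#' Weights are Glorot-uniform, seeded; biases start at zero.
#'
#' @param D Input feature dimension.
#' @param n_classes Number of function classes `F`.
#' @param hidden GCN hidden width per channel (default 512).
#' @param fc_hidden Width of the first fully connected layer (default
#'   `hidden`).
#' @param dropout Dropout rate applied to the second fully connected
#'   layer's input during training (default 0.3).
#' @param output `"sigmoid"` (multi-label, default) or `"softmax"`.
#' @param vocabulary Optional character vector of `n_classes` label names.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `coev_model`: list with `par` (named weight
#'   list) and `config`.
#' @export
dual_gcn <- function(D, n_classes, hidden = 512, fc_hidden = hidden,
                     dropout = 0.3, output = c("sigmoid", "softmax"),
                     vocabulary = NULL, seed = 1) {
  output <- match.arg(output)
  if (!is.null(vocabulary)) stopifnot(length(vocabulary) == n_classes)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  par <- withr::with_seed(as.integer(seed), {
    p <- list()
    for (ch in c("evc", "rc")) {
      p[[paste0("W1_", ch)]] <- glorot(D, hidden)
      p[[paste0("b1_", ch)]] <- rep(0, hidden)
      p[[paste0("W2_", ch)]] <- glorot(hidden, hidden)
      p[[paste0("b2_", ch)]] <- rep(0, hidden)
      p[[paste0("W3_", ch)]] <- glorot(hidden, hidden)
      p[[paste0("b3_", ch)]] <- rep(0, hidden)
    }
    p$W_fc1 <- glorot(2 * hidden, fc_hidden)
    p$b_fc1 <- rep(0, fc_hidden)
    p$W_fc2 <- glorot(fc_hidden, n_classes)
    p$b_fc2 <- rep(0, n_classes)
    p
  })
  structure(list(par = par,
                 config = list(D = D, hidden = hidden, fc_hidden = fc_hidden,
                               n_classes = n_classes, dropout = dropout,
                               output = output, vocabulary = vocabulary,
                               seed = as.integer(seed))),
            class = "coev_model")
}

#' @export
print.coev_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "coev_model: dual-channel GCN (3+3 layers, hidden %d) -> FC %d -> %d classes (%s)\n",
    cfg$hidden, cfg$fc_hidden, cfg$n_classes, cfg$output))
  invisible(x)
}

# ---- batched internals ------------------------------------------------------
# Proteins in a batch are stacked into one block-diagonal graph: sparse
# adjacencies via Matrix::bdiag, node features row-bound, and a sparse
# pooling indicator (one row per protein) implementing SumPooling.

#' @keywords internal
build_batch <- function(graphs) {
  sizes <- vapply(graphs, function(g) nrow(g$features), integer(1))
  X <- do.call(rbind, lapply(graphs, function(g) g$features))
  Ae <- Matrix::bdiag(lapply(graphs, function(g) g$norm_evc))
  Ar <- Matrix::bdiag(lapply(graphs, function(g) g$norm_rc))
  pool <- Matrix::sparseMatrix(i = rep(seq_along(graphs), sizes),
                               j = seq_len(sum(sizes)), x = 1,
                               dims = c(length(graphs), sum(sizes)))
  list(X = X, Ae = Ae, Ar = Ar, pool = pool, sizes = sizes)
}

#' @keywords internal
check_finite <- function(x, layer) {
  if (!all(is.finite(x))) stop("non-finite values in layer: ", layer)
  x
}

#' @keywords internal
forward_batch <- function(batch, model, training = FALSE, keep_cache = FALSE) {
  p <- model$par
  cfg <- model$config
  cache <- list(batch = batch)
  run_channel <- function(A, ch) {
    H <- batch$X
    out <- list()
    for (k in 1:3) {
      P <- as.matrix(A %*% H)
      S <- sweep(P %*% p[[paste0("W", k, "_", ch)]], 2,
                 p[[paste0("b", k, "_", ch)]], "+")
      check_finite(S, paste0("gcn", k, "_", ch))
      H <- relu(S)
      out[[paste0("P", k)]] <- P
      out[[paste0("mask", k)]] <- S > 0
      out[[paste0("H", k)]] <- H
    }
    out
  }
  ce <- run_channel(batch$Ae, "evc")
  cr <- run_channel(batch$Ar, "rc")
  fmap <- cbind(ce$H3, cr$H3)
  pooled <- as.matrix(batch$pool %*% fmap)
  S1 <- sweep(pooled %*% p$W_fc1, 2, p$b_fc1, "+")
  check_finite(S1, "fc1")
  Z1 <- relu(S1)
  if (training && cfg$dropout > 0) {
    keep <- matrix(stats::runif(length(Z1)) >= cfg$dropout, nrow(Z1), ncol(Z1))
    Z1d <- Z1 * keep / (1 - cfg$dropout)
  } else {
    keep <- NULL
    Z1d <- Z1
  }
  S2 <- sweep(Z1d %*% p$W_fc2, 2, p$b_fc2, "+")
  check_finite(S2, "fc2")
  probs <- if (cfg$output == "softmax") {
    e <- exp(S2 - apply(S2, 1, max))
    e / rowSums(e)
  } else {
    sigmoid(S2)
  }
  if (!is.null(cfg$vocabulary)) colnames(probs) <- cfg$vocabulary
  out <- list(probs = probs, fmap = fmap, pooled = pooled)
  if (keep_cache) {
    out$cache <- c(cache, list(evc = ce, rc = cr, fmap = fmap, pooled = pooled,
                               fc1_mask = S1 > 0, Z1 = Z1, keep = keep,
                               Z1d = Z1d, probs = probs))
  }
  out
}

# Gradients of the multi-label BCE loss (mean over proteins, sum over
# classes) with respect to every parameter; sigmoid output assumed, for
# which dL/dlogit = probs - Y.
#' @keywords internal
backward_batch <- function(cache, Y, model) {
  p <- model$par
  cfg <- model$config
  batch <- cache$batch
  B <- nrow(Y)
  g <- list()
  dZ2 <- (cache$probs - Y) / B
  g$W_fc2 <- crossprod(cache$Z1d, dZ2)
  g$b_fc2 <- colSums(dZ2)
  dZ1d <- dZ2 %*% t(p$W_fc2)
  dZ1 <- if (!is.null(cache$keep)) dZ1d * cache$keep / (1 - cfg$dropout) else dZ1d
  dS1 <- dZ1 * cache$fc1_mask
  g$W_fc1 <- crossprod(cache$pooled, dS1)
  g$b_fc1 <- colSums(dS1)
  dpooled <- dS1 %*% t(p$W_fc1)
  dfmap <- as.matrix(Matrix::crossprod(batch$pool, dpooled))
  h <- cfg$hidden
  for (ch in c("evc", "rc")) {
    cc <- if (ch == "evc") cache$evc else cache$rc
    A <- if (ch == "evc") batch$Ae else batch$Ar
    dH <- if (ch == "evc") dfmap[, seq_len(h), drop = FALSE] else
      dfmap[, h + seq_len(h), drop = FALSE]
    for (k in 3:1) {
      dS <- dH * cc[[paste0("mask", k)]]
      g[[paste0("W", k, "_", ch)]] <- crossprod(cc[[paste0("P", k)]], dS)
      g[[paste0("b", k, "_", ch)]] <- colSums(dS)
      if (k > 1) {
        dH <- as.matrix(A %*% (dS %*% t(p[[paste0("W", k, "_", ch)]])))
      }
    }
  }
  g
}

#' Forward pass of the dual-channel GCN
#'
#' Runs one protein graph through both channels and the classification
#' head. Dropout is active only in training mode.
#'
#' @param graph A [protein_graph()].
#' @param model A [dual_gcn()] model.
#' @param training Logical; enables dropout.
#' @return List with `probabilities` (length-`F` vector in `[0, 1]`) and
#'   `feature_map` (`L x 2*hidden` matrix, the residue-resolved
#'   concatenated channel output retained for Grad-CAM).
#' @export
forward_dual_gcn <- function(graph, model, training = FALSE) {
  stopifnot(inherits(graph, "coev_graph"), inherits(model, "coev_model"))
  if (ncol(graph$features) != model$config$D) {
    stop(sprintf("feature dimension %d does not match model input dimension %d",
                 ncol(graph$features), model$config$D))
  }
  out <- forward_batch(build_batch(list(graph)), model, training = training)
  list(probabilities = drop(out$probs), feature_map = out$fmap)
}
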