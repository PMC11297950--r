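#' Residue-level activation scores (Grad-CAM)
#'
#' Scores every residue's importance for one predicted function class by
#' gradient-weighted class activation mapping over the residue-resolved
#' feature map `F^k` (the `L x 2*hidden` concatenation of the two channel
#' outputs, taken before sum pooling — the only residue-resolved layer of
#' the head). Neuron weights are
#' `alpha_k = (1/L) * sum_i dY_c / dF_ik`, the gradient of the class-`c`
#' probability with respect to the feature map averaged over residues
#' (because pooling is a sum, this equals the gradient with respect to the
#' pooled feature). Raw scores are `ReLU(sum_k alpha_k F_ik)`; normalized
#' scores divide by the maximum raw score (an all-zero raw profile stays
#' all-zero).
#'
#' @param model A `coev_model` or `coev_fit`.
#' @param graph A [protein_graph()].
#' @param class Class index (1-based) or vocabulary label name.
#' @param target `"probability"` (default: gradient of the post-sigmoid
#'   score) or `"logit"`.
#' @return An object of class `coev_profile`: tibble with columns
#'   `residue` (1-based), `score` (normalized, in `[0, 1]`) and `raw`;
#'   attributes `alpha` (neuron weights), `class_label`, `probability`.
#' @export
activation_scores <- function(model, graph, class,
                              target = c("probability", "logit")) {
  target <- match.arg(target)
  if (inherits(model, "coev_fit")) model <- model$model
  stopifnot(inherits(model, "coev_model"), inherits(graph, "coev_graph"))
  cfg <- model$config
  if (is.character(class)) {
    if (is.null(cfg$vocabulary) || !(class %in% cfg$vocabulary)) {
      stop("class label not in the model vocabulary: ", class)
    }
    class_label <- class
    class <- match(class, cfg$vocabulary)
  } else {
    class <- as.integer(class)
    if (class < 1 || class > cfg$n_classes) {
      stop(sprintf("class index %d out of range (model has %d classes)",
                   class, cfg$n_classes))
    }
    class_label <- cfg$vocabulary[class] %||% as.character(class)
  }
  out <- forward_batch(build_batch(list(graph)), model, training = FALSE,
                       keep_cache = TRUE)
  cache <- out$cache
  p <- model$par
  # head gradient dY_c/dpooled, dropout off
  prob <- out$probs[1, class]
  dZ2 <- if (target == "probability") prob * (1 - prob) else 1
  dZ1 <- dZ2 * p$W_fc2[, class]
  dS1 <- dZ1 * cache$fc1_mask[1, ]
  alpha <- as.numeric(p$W_fc1 %*% dS1)  # = dY_c/dpooled = mean_i dY_c/dF_ik
  raw <- relu(as.numeric(out$fmap %*% alpha))
  score <- if (max(raw) > 0) raw / max(raw) else raw
  structure(tibble::tibble(residue = seq_along(raw), score = score, raw = raw),
            alpha = alpha, class_label = class_label, probability = unname(prob),
            class = c("coev_profile", class(tibble::tibble())))
}

#' Call functional-site residues from an activation profile
#'
#' Residues whose normalized score is at or above the cutoff (the `>=`
#' convention).
#'
#' @param profile A `coev_profile` from [activation_scores()].
#' @param cutoff Score cutoff (default 0.5).
#' @return Sorted integer vector of 1-based residue indices.
#' @export
call_functional_sites <- function(profile, cutoff = 0.5) {
  stopifnot(inherits(profile, "coev_profile"))
  sort(profile$residue[profile$score >= cutoff])
}

#' Agreement between an activation profile and reference sites
#'
#' Compares the continuous scores against binary reference membership
#' (AUROC), and the thresholded site calls against the reference
#' (precision and recall at `cutoff`).
#'
#' @param profile A `coev_profile`.
#' @param reference_sites Integer vector of 1-based reference residue
#'   indices (e.g. curated binding sites).
#' @param cutoff Site-calling cutoff (default 0.5).
#' @return One-row tibble: `auroc`, `precision`, `recall`, `n_called`,
#'   `n_reference`.
#' @export
site_agreement <- function(profile, reference_sites, cutoff = 0.5) {
  stopifnot(inherits(profile, "coev_profile"))
  L <- nrow(profile)
  reference_sites <- unique(as.integer(reference_sites))
  if (length(reference_sites) == 0) stop("reference site set is empty")
  if (any(reference_sites < 1 | reference_sites > L)) {
    stop("reference site indices out of range 1..", L)
  }
  truth <- as.integer(profile$residue %in% reference_sites)
  auroc <- if (length(unique(truth)) < 2) {
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(truth, profile$score, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }
  called <- call_functional_sites(profile, cutoff)
  tp <- length(intersect(called, reference_sites))
  tibble::tibble(
    auroc = auroc,
    precision = if (length(called) > 0) tp / length(called) else NA_real_,
    recall = tp / length(reference_sites),
    n_called = length(called),
    n_reference = length(reference_sites))
}

#' Write an activation profile as TSV
#'
#' Columns: residue (1-based), amino acid (when the graph carried a
#' sequence), score, called (0/1 at the cutoff).
#'
#' @param profile A `coev_profile`.
#' @param path Output path.
#' @param sequence Optional amino-acid string for the `aa` column.
#' @param cutoff Site-calling cutoff (default 0.5).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, sequence = NULL, cutoff = 0.5) {
  out <- tibble::tibble(residue = profile$residue,
                        aa = if (!is.null(sequence))
                          strsplit(sequence, "")[[1]] else NA_character_,
                        score = profile$score,
                        called = as.integer(profile$score >= cutoff))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Plot an activation profile
#'
#' @param object A `coev_profile`.
#' @param cutoff Cutoff line to draw (default 0.5).
#' @param reference_sites Optional reference residues highlighted as rug
#'   marks.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coev_profile
#' @export
autoplot.coev_profile <- function(object, cutoff = 0.5,
                                  reference_sites = NULL, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$score)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "activation score",
                  title = attr(object, "class_label")) +
    ggplot2::theme_minimal()
  if (!is.null(reference_sites)) {
    gg <- gg + ggplot2::geom_rug(
      data = tibble::tibble(residue = reference_sites),
      ggplot2::aes(x = .data$residue), inherit.aes = FALSE, sides = "b")
  }
  gg
}
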