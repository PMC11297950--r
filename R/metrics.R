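#' Evaluation set
#'
#' Pairs an `N x F` matrix of prediction scores with the binary truth
#' matrix, the label vocabulary, and (optionally) each protein's maximum
#' sequence identity to the training set for stratified evaluation.
#'
#' @param predictions `N x F` numeric matrix of scores in `[0, 1]`.
#' @param truths `N x F` binary matrix.
#' @param vocabulary Optional character vector of `F` label names.
#' @param identity Optional numeric vector of per-protein identities in
#'   `[0, 1]`.
#' @return An object of class `coev_eval`.
#' @export
evaluation_set <- function(predictions, truths, vocabulary = NULL,
                           identity = NULL) {
  predictions <- as.matrix(predictions)
  truths <- as.matrix(truths)
  stopifnot(all(dim(predictions) == dim(truths)),
            all(truths %in% c(0, 1)))
  if (sum(truths) == 0) stop("evaluation set has no positive truth labels")
  if (!is.null(identity)) {
    stopifnot(length(identity) == nrow(predictions))
    if (any(identity < 0 | identity > 1)) stop("identities must lie in [0, 1]")
  }
  structure(list(predictions = predictions, truths = truths,
                 vocabulary = vocabulary, identity = identity),
            class = "coev_eval")
}

#' Protein-centric maximum F-score
#'
#' Scans decision thresholds `t` over a grid and returns the maximum
#' harmonic mean of average precision and recall. At each `t`, a protein's
#' predicted set is every class with score `>= t`; precision is averaged
#' over proteins with at least one prediction (the CAFA convention),
#' recall over all proteins with at least one true label. `F(t) = 0` when
#' `p + r = 0` or no protein predicts anything.
#'
#' @param ev An [evaluation_set()].
#' @param grid_step Threshold grid step (default 0.01).
#' @return One-row tibble: `fmax`, `threshold`, `precision`, `recall`.
#' @export
fmax <- function(ev, grid_step = 0.01) {
  stopifnot(inherits(ev, "coev_eval"))
  pred <- ev$predictions
  truth <- ev$truths
  has_truth <- rowSums(truth) > 0
  n_truth <- sum(has_truth)
  if (n_truth == 0) stop("no protein has a true label")
  best <- c(fmax = 0, threshold = 0, precision = 0, recall = 0)
  for (t in seq(0, 1, by = grid_step)) {
    called <- pred >= t & pred > 0  # a zero score is never a prediction
    npred <- rowSums(called)
    tp <- rowSums(called & truth == 1)
    covered <- npred > 0
    if (!any(covered)) next
    p <- mean((tp / npred)[covered])
    r <- sum((tp / pmax(rowSums(truth), 1))[has_truth]) / n_truth
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    if (f > best["fmax"]) best <- c(fmax = f, threshold = t, precision = p, recall = r)
  }
  tibble::tibble(fmax = best[["fmax"]], threshold = best[["threshold"]],
                 precision = best[["precision"]], recall = best[["recall"]])
}

# Area under the precision-recall curve for one term via the
# descending-score sweep with step interpolation (equivalent to average
# precision: sum over recall increments of the precision at that point).
#' @keywords internal
average_precision <- function(scores, labels) {
  n_pos <- sum(labels)
  if (n_pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  tp <- cumsum(labels)
  fp <- cumsum(1 - labels)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  # evaluate at distinct thresholds only (ties grouped)
  last_of_tie <- c(diff(scores) != 0, TRUE)
  prec <- prec[last_of_tie]
  rec <- rec[last_of_tie]
  sum(diff(c(0, rec)) * prec)
}

#' Term-centric area under the precision-recall curve
#'
#' `averaging = "macro_term"` computes one PR curve per function term
#' (terms without a positive example are skipped and counted) and averages
#' the areas; `"micro"` pools all (protein, term) pairs into one curve.
#' `integral = "literal"` instead integrates the product `p(t) * r(t)`
#' over the threshold grid (a printed-formula variant retained for
#' comparison; not the standard PR area).
#'
#' @param ev An [evaluation_set()].
#' @param averaging `"macro_term"` (default) or `"micro"`.
#' @param integral `"pr_curve"` (default) or `"literal"`.
#' @param grid_step Threshold grid for the literal integral.
#' @return One-row tibble: `aupr`, `n_terms`, `n_skipped`.
#' @export
aupr <- function(ev, averaging = c("macro_term", "micro"),
                 integral = c("pr_curve", "literal"), grid_step = 0.01) {
  stopifnot(inherits(ev, "coev_eval"))
  averaging <- match.arg(averaging)
  integral <- match.arg(integral)
  pred <- ev$predictions
  truth <- ev$truths
  if (integral == "literal") {
    ts <- seq(0, 1, by = grid_step)
    scores <- as.vector(pred)
    labels <- as.vector(truth)
    pr <- vapply(ts, function(t) {
      called <- scores >= t
      tp <- sum(called & labels == 1)
      p <- if (sum(called) > 0) tp / sum(called) else NA_real_
      r <- tp / sum(labels)
      c(p, r)
    }, numeric(2))
    ok <- !is.na(pr[1, ])
    val <- sum(diff(ts[ok]) * (pr[1, ok] * pr[2, ok])[-1])
    return(tibble::tibble(aupr = abs(val), n_terms = ncol(pred), n_skipped = 0L))
  }
  if (averaging == "micro") {
    val <- average_precision(as.vector(pred), as.vector(truth))
    return(tibble::tibble(aupr = val, n_terms = ncol(pred), n_skipped = 0L))
  }
  per_term <- vapply(seq_len(ncol(pred)), function(j)
    average_precision(pred[, j], truth[, j]), numeric(1))
  tibble::tibble(aupr = mean(per_term, na.rm = TRUE),
                 n_terms = sum(!is.na(per_term)),
                 n_skipped = sum(is.na(per_term)))
}

#' Matthews correlation coefficient over pooled confusion counts
#'
#' Predictions are binarized at `cutoff`, pooled over all (protein, term)
#' pairs, and scored as
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; a zero
#' denominator yields 0.
#'
#' @param ev An [evaluation_set()], or an already-binary prediction matrix
#'   together with `truths`.
#' @param cutoff Binarization cutoff (default 0.5).
#' @param truths Binary truth matrix when `ev` is a plain matrix.
#' @return Scalar MCC in `[-1, 1]`.
#' @export
mcc_score <- function(ev, cutoff = 0.5, truths = NULL) {
  if (inherits(ev, "coev_eval")) {
    pred <- ev$predictions >= cutoff
    truth <- ev$truths == 1
  } else {
    stopifnot(!is.null(truths))
    pred <- as.matrix(ev) >= cutoff
    truth <- as.matrix(truths) == 1
  }
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Bootstrap a metric over proteins
#'
#' Resamples proteins with replacement `n_boot` times and recomputes the
#' metric; deterministic given `seed`. A degenerate resample with no
#' positive truth yields `NA` and is dropped from the mean/sd summary.
#'
#' @param ev An [evaluation_set()].
#' @param metric Function taking an evaluation set and returning a scalar
#'   (or one-row tibble whose first column is taken).
#' @param n_boot Number of bootstrap replicates (>= 2; the reported
#'   experiments use 10 and 50).
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, and the tibble `replicates`.
#' @export
bootstrap_metric <- function(ev, metric, n_boot = 10, seed = 1) {
  stopifnot(inherits(ev, "coev_eval"), n_boot >= 2)
  n <- nrow(ev$predictions)
  vals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(ev$truths[idx, , drop = FALSE]) == 0) return(NA_real_)
      sub <- evaluation_set(ev$predictions[idx, , drop = FALSE],
                            ev$truths[idx, , drop = FALSE],
                            vocabulary = ev$vocabulary)
      out <- metric(sub)
      if (is.data.frame(out)) out <- out[[1]][1]
      as.numeric(out)
    }, numeric(1))
  })
  reps <- tibble::tibble(replicate = seq_len(n_boot), value = vals)
  list(mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals, na.rm = TRUE),
       replicates = reps)
}

#' Identity-stratified evaluation
#'
#' Evaluates the metric on the subset of proteins whose maximum sequence
#' identity to the training set is at or below each threshold; empty
#' strata are reported as missing.
#'
#' @param ev An [evaluation_set()] carrying per-protein identities.
#' @param metric Function as in [bootstrap_metric()].
#' @param thresholds Identity thresholds (default the benchmark ladder
#'   0.30, 0.40, 0.50, 0.70, 0.95).
#' @return Tibble with `threshold`, `n_proteins`, `value`.
#' @export
identity_stratified <- function(ev, metric,
                                thresholds = c(0.30, 0.40, 0.50, 0.70, 0.95)) {
  stopifnot(inherits(ev, "coev_eval"))
  if (is.null(ev$identity)) stop("evaluation set carries no identity values")
  rows <- lapply(thresholds, function(tau) {
    idx <- which(ev$identity <= tau)
    if (length(idx) == 0 || sum(ev$truths[idx, , drop = FALSE]) == 0) {
      return(tibble::tibble(threshold = tau, n_proteins = length(idx),
                            value = NA_real_))
    }
    sub <- evaluation_set(ev$predictions[idx, , drop = FALSE],
                          ev$truths[idx, , drop = FALSE],
                          vocabulary = ev$vocabulary)
    out <- metric(sub)
    if (is.data.frame(out)) out <- out[[1]][1]
    tibble::tibble(threshold = tau, n_proteins = length(idx),
                   value = as.numeric(out))
  })
  dplyr::bind_rows(rows)
}
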