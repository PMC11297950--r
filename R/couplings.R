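#' Coupling matrix object
#'
#' Symmetric `L x L` matrix of residue-residue evolutionary coupling
#' strengths with zero diagonal. When `normalized`, entries lie in `[0, 1]`
#' with the maximum off-diagonal entry equal to 1 (unless all-zero).
#'
#' @param scores Symmetric numeric matrix with zero diagonal.
#' @param normalized Logical flag.
#' @return An object of class `coupling_matrix`.
#' @export
coupling_matrix <- function(scores, normalized = FALSE) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  if (max(abs(scores - t(scores))) > 1e-9) stop("coupling matrix must be symmetric")
  if (max(abs(diag(scores))) > 1e-12) stop("coupling matrix must have zero diagonal")
  structure(list(scores = scores, normalized = isTRUE(normalized)),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("coupling_matrix: L = %d, %snormalized, max = %.4g\n",
              nrow(x$scores), if (x$normalized) "" else "not ",
              max(x$scores)))
  invisible(x)
}

#' Infer evolutionary couplings by mean-field direct coupling analysis
#'
#' Builds the connected-correlation matrix
#' `C_ij(a,b) = f_ij(a,b) - f_i(a) f_j(b)` over the first `q - 1 = 20`
#' states (the gap state is excluded to avoid gap-driven couplings),
#' estimates pair couplings as the negative inverse `e = -C^{-1}`, moves
#' each `20 x 20` pair block to the zero-sum gauge, and scores pair `(i,j)`
#' by the Frobenius norm of its gauged block. Scores are background-corrected
#' by the average-product correction (APC)
#' `score(i,j) - mean_i(score) * mean_j(score) / mean(score)`; negative
#' corrected values are clipped to zero and the diagonal is zero.
#'
#' @param freqs A `coev_freqs` object with `lambda > 0` (the pseudocount
#'   regularizes the matrix inversion).
#' @return A raw (unnormalized) [coupling_matrix].
#' @export
infer_couplings <- function(freqs) {
  L <- freqs$L; q <- freqs$q; qa <- q - 1L
  if (L < 2) stop("need at least two alignment columns")
  keep <- as.vector(vapply(seq_len(L), function(i) (i - 1L) * q + seq_len(qa),
                           integer(qa)))
  C <- freqs$f2[keep, keep] -
    tcrossprod(as.vector(t(freqs$f1[, seq_len(qa), drop = FALSE])))
  e <- tryCatch(-solve(C), error = function(err) {
    stop("covariance matrix is singular; increase the pseudocount lambda ",
         "(currently ", freqs$lambda, ")")
  })
  fn <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    ri <- (i - 1L) * qa + seq_len(qa)
    for (j in seq((i + 1L), L)) {
      blk <- e[ri, (j - 1L) * qa + seq_len(qa)]
      blk <- blk - outer(rowMeans(blk), rep(1, qa)) -
        outer(rep(1, qa), colMeans(blk)) + mean(blk)
      fn[i, j] <- fn[j, i] <- sqrt(sum(blk^2))
    }
  }
  score <- apc_correct(fn)
  coupling_matrix(score, normalized = FALSE)
}

# Average-product correction with clipping at zero.
#' @keywords internal
apc_correct <- function(fn) {
  L <- nrow(fn)
  row_mean <- rowSums(fn) / (L - 1)
  all_mean <- sum(fn) / (L * (L - 1))
  if (all_mean <= 0) return(fn)
  s <- fn - outer(row_mean, row_mean) / all_mean
  s[s < 0] <- 0
  diag(s) <- 0
  (s + t(s)) / 2
}

#' Normalize a coupling matrix to [0, 1]
#'
#' Divides all entries by the maximum off-diagonal entry, so the strongest
#' coupling becomes 1. An all-zero matrix is returned unchanged (flagged
#' normalized) rather than triggering a division by zero.
#'
#' @param C A [coupling_matrix].
#' @return A normalized [coupling_matrix].
#' @export
normalize_couplings <- function(C) {
  stopifnot(inherits(C, "coupling_matrix"))
  m <- max(C$scores)
  s <- if (m > 0) C$scores / m else C$scores
  coupling_matrix(s, normalized = TRUE)
}

#' Threshold a normalized coupling matrix into a binary adjacency
#'
#' Entries at or above `threshold` become edges (the `>=` convention, used
#' throughout for thresholds); the diagonal stays zero.
#'
#' @param C A normalized [coupling_matrix].
#' @param threshold Edge threshold in `[0, 1]` (default 0.2).
#' @return A binary `L x L` adjacency matrix with attributes `source` and
#'   `threshold`.
#' @export
threshold_adjacency <- function(C, threshold = 0.2) {
  stopifnot(inherits(C, "coupling_matrix"))
  if (!C$normalized) stop("threshold_adjacency expects a normalized coupling matrix")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  A <- (C$scores >= threshold) * 1
  diag(A) <- 0
  structure(A, source = "EVC", threshold = threshold)
}

#' Coupling matrix as a tidy edge table
#'
#' @param C A [coupling_matrix].
#' @param min_score Keep pairs with score at least this value (default 0,
#'   keeping all pairs).
#' @return Tibble with 1-based columns `i`, `j` (`i < j`) and `score`.
#' @export
coupling_edges <- function(C, min_score = 0) {
  stopifnot(inherits(C, "coupling_matrix"))
  L <- nrow(C$scores)
  idx <- which(upper.tri(C$scores), arr.ind = TRUE)
  out <- tibble::tibble(i = idx[, 1], j = idx[, 2],
                        score = C$scores[idx])
  out <- out[out$score >= min_score, ]
  out[order(-out$score), ]
}

#' Write a coupling matrix as an edge-list TSV
#'
#' @param C A [coupling_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_couplings <- function(C, path) {
  readr::write_tsv(coupling_edges(C), path)
  invisible(path)
}

#' Write a binary adjacency as an edge-list TSV
#'
#' @param A Binary adjacency matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(A, path) {
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(i = idx[, 1], j = idx[, 2]), path)
  invisible(path)
}
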