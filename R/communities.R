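#' Detect residue communities by spectral analysis of the coupling matrix
#'
#' Eigendecomposes the normalized coupling matrix and keeps the eigenvectors
#' whose eigenvalues rise above a noise threshold. In `"auto"` mode the
#' threshold is estimated from `n_null` permutation nulls: each null
#' shuffles the entries within every column and re-symmetrizes, destroying
#' community structure while preserving the score distribution; the
#' threshold is the largest *second* eigenvalue across nulls (a null's
#' leading eigenvalue is the Perron mode set by overall coupling density,
#' which carries no community signal). Retained eigenvectors are varimax-
#' rotated to localize them (degenerate eigenvalues from equal-sized blocks
#' otherwise yield arbitrarily mixed basis vectors), then residue `i` joins
#' community `k* = argmax_k |v_k(i)|` provided `|v_k*(i)| >= loading_cutoff`
#' (default `1/sqrt(L)`, the RMS loading of a flat eigenvector). Membership
#' strength is `|v_k*(i)| / max_j |v_k*(j)|` within the community.
#' Communities with fewer than 2 members are dropped.
#'
#' @param C A normalized [coupling_matrix].
#' @param max_k Maximum number of communities to retain (default 10).
#' @param eig_threshold `"auto"` (permutation null) or a fixed numeric
#'   eigenvalue threshold.
#' @param loading_cutoff Minimum absolute eigenvector loading for
#'   membership; `NULL` (default) means `1/sqrt(L)`.
#' @param n_null Number of permutation nulls in auto mode (default 20).
#' @param seed Seed for the permutation nulls (default 1).
#' @return An object of class `coev_communities`: list with `members`
#'   (tibble: `community`, `residue` 1-based, `strength`), `L`, `n_communities`,
#'   `eig_threshold`.
#' @export
detect_communities <- function(C, max_k = 10, eig_threshold = "auto",
                               loading_cutoff = NULL, n_null = 20, seed = 1) {
  stopifnot(inherits(C, "coupling_matrix"))
  S <- C$scores
  L <- nrow(S)
  empty <- function(thr) {
    structure(list(members = tibble::tibble(community = integer(),
                                            residue = integer(),
                                            strength = numeric()),
                   L = L, n_communities = 0L, eig_threshold = thr),
              class = "coev_communities")
  }
  if (L < 3) {
    warning("matrix too small for community detection (L < 3)")
    return(empty(NA_real_))
  }
  if (is.null(loading_cutoff)) loading_cutoff <- 1 / sqrt(L)
  eig <- eigen(S, symmetric = TRUE)
  if (identical(eig_threshold, "auto")) {
    thr <- withr::with_seed(seed, {
      max(vapply(seq_len(n_null), function(b) {
        P <- apply(S, 2, sample)
        P <- (P + t(P)) / 2
        ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
        ev[2]
      }, numeric(1)))
    })
  } else {
    thr <- as.numeric(eig_threshold)
  }
  k <- min(max_k, sum(eig$values > thr))
  if (k < 1) return(empty(thr))
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  if (k >= 2) V <- V %*% stats::varimax(V, normalize = FALSE)$rotmat
  absV <- abs(V)
  assign_k <- max.col(absV, ties.method = "first")
  load <- absV[cbind(seq_len(L), assign_k)]
  assigned <- load >= loading_cutoff
  members <- tibble::tibble(community = assign_k[assigned],
                            residue = which(assigned),
                            strength = load[assigned])
  # per-community strength normalization; drop communities of fewer than 2
  keep_ids <- names(which(table(members$community) >= 2))
  members <- members[members$community %in% as.integer(keep_ids), , drop = FALSE]
  if (nrow(members) > 0) {
    members$strength <- members$strength /
      stats::ave(members$strength, members$community, FUN = max)
    # relabel communities 1..n in order of appearance
    members$community <- match(members$community, unique(members$community))
    members <- members[order(members$community, members$residue), ]
  }
  structure(list(members = members, L = L,
                 n_communities = length(unique(members$community)),
                 eig_threshold = thr),
            class = "coev_communities")
}

#' @export
print.coev_communities <- function(x, ...) {
  cat(sprintf("coev_communities: %d communities over L = %d residues (eig threshold %.3g)\n",
              x$n_communities, x$L, x$eig_threshold))
  if (x$n_communities > 0) {
    sizes <- table(x$members$community)
    cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy accessors for community sets
#'
#' `tidy()` returns the membership table; `glance()` a one-row summary.
#'
#' @param x A `coev_communities` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.coev_communities <- function(x, ...) x$members

#' @rdname tidy.coev_communities
#' @export
glance.coev_communities <- function(x, ...) {
  tibble::tibble(n_communities = x$n_communities, L = x$L,
                 n_assigned = nrow(x$members),
                 eig_threshold = x$eig_threshold)
}

#' Tidy a coupling matrix into its edge table
#'
#' @param x A [coupling_matrix].
#' @param ... Passed to [coupling_edges()].
#' @return Tibble of pairs `i < j` with scores, strongest first.
#' @export
tidy.coupling_matrix <- function(x, ...) coupling_edges(x, ...)

#' Residue-community adjacency
#'
#' Connects residues `i` and `j` when they share a community and
#' `min(strength(i), strength(j)) >= threshold`.
#'
#' @param rcs A `coev_communities` object.
#' @param threshold Strength threshold (default 0.2).
#' @return Binary `L x L` adjacency matrix with attributes `source` and
#'   `threshold`.
#' @export
rc_adjacency <- function(rcs, threshold = 0.2) {
  stopifnot(inherits(rcs, "coev_communities"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  A <- matrix(0, rcs$L, rcs$L)
  m <- rcs$members
  if (nrow(m) > 0) {
    for (cid in unique(m$community)) {
      sub <- m[m$community == cid & m$strength >= threshold, ]
      if (nrow(sub) >= 2) {
        A[as.matrix(expand.grid(sub$residue, sub$residue))] <- 1
      }
    }
  }
  diag(A) <- 0
  structure(A, source = "RC", threshold = threshold)
}

#' Write residue communities as TSV
#'
#' @param rcs A `coev_communities` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_communities <- function(rcs, path) {
  readr::write_tsv(rcs$members, path)
  invisible(path)
}
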