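#' Multiple sequence alignment object
#'
#' A `coev_msa` holds `M` aligned sequences of identical length `L` over the
#' 20 amino acids, the gap character `-`, and `X` for unknown residues. One
#' row is designated the query (target) sequence; all downstream statistics
#' are indexed on its columns.
#'
#' @param ali Character matrix (`M x L`) of single uppercase characters.
#' @param ids Character vector of sequence identifiers.
#' @param query_index Row index of the query sequence (default 1).
#' @return An object of class `coev_msa` with fields `ali`, `ids`,
#'   `query_index`.
#' @export
coev_msa <- function(ali, ids = NULL, query_index = 1L) {
  stopifnot(is.matrix(ali), nrow(ali) >= 1, ncol(ali) >= 1)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(ali)))
  stopifnot(length(ids) == nrow(ali))
  query_index <- as.integer(query_index)
  stopifnot(query_index >= 1, query_index <= nrow(ali))
  bad <- !(ali %in% ALPHABET)
  if (any(bad)) ali[bad] <- UNK
  structure(list(ali = ali, ids = as.character(ids), query_index = query_index),
            class = "coev_msa")
}

#' @export
print.coev_msa <- function(x, ...) {
  cat(sprintf("coev_msa: %d sequences x %d columns (query: %s)\n",
              nrow(x$ali), ncol(x$ali), x$ids[x$query_index]))
  invisible(x)
}

#' @export
dim.coev_msa <- function(x) dim(x$ali)

#' Read a multiple sequence alignment
#'
#' Reads FASTA or A3M alignment files. In the A3M dialect, lowercase letters
#' and `.` mark insertion columns relative to the query's match states; they
#' are removed so that every row has the query's match-column length. In
#' plain FASTA, lowercase is uppercased and `.` is read as a gap. Characters
#' outside the amino-acid alphabet are mapped to `X`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"a3m"`.
#' @param query_index Row index of the query/target sequence (default 1).
#' @return A [coev_msa] object.
#' @export
read_msa <- function(path, format = c("fasta", "a3m"), query_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("empty alignment file: ", path)
  ids <- names(recs)
  seqs <- as.character(recs)
  if (format == "a3m") {
    # drop insertion states (lowercase and '.') so rows align on match columns
    seqs <- vapply(seqs, function(s) gsub("[a-z.]", "", s), character(1),
                   USE.NAMES = FALSE)
  } else {
    seqs <- toupper(gsub("\\.", GAP, seqs))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    off <- which(lens != lens[query_index])[1]
    stop(sprintf(
      "unequal alignment lengths after %s normalization: record '%s' has %d columns, query has %d",
      format, ids[off], lens[off], lens[query_index]))
  }
  ali <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  coev_msa(ali, ids = ids, query_index = query_index)
}

#' Write an alignment as FASTA
#'
#' @param msa A [coev_msa].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  seqs <- apply(msa$ali, 1, paste, collapse = "")
  x <- Biostrings::BStringSet(setNames(seqs, msa$ids))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Remove gap-rich sequences from an alignment
#'
#' Drops every row whose gap fraction strictly exceeds `max_gap_fraction`
#' (rows at exactly the boundary are retained). The query row is always
#' kept, whatever its gap content, because downstream coupling indices must
#' cover the full target sequence.
#'
#' @param msa A [coev_msa].
#' @param max_gap_fraction Maximum tolerated gap fraction per row
#'   (default 0.8, i.e. sequences with over 80% gaps are removed).
#' @return A trimmed [coev_msa]; row order is preserved.
#' @export
trim_msa <- function(msa, max_gap_fraction = 0.8) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1)
  gap_frac <- rowMeans(msa$ali == GAP)
  keep <- gap_frac <= max_gap_fraction
  keep[msa$query_index] <- TRUE
  if (sum(keep) == 1 && nrow(msa$ali) > 1) {
    warning("all non-query sequences removed by gap trimming")
  }
  new_query <- sum(keep[seq_len(msa$query_index)])
  coev_msa(msa$ali[keep, , drop = FALSE], ids = msa$ids[keep],
           query_index = new_query)
}

# Sparse one-hot encoding over the Q_STATES frequency states; 'X' becomes
# 1/20 fractional mass on each amino-acid state.
#' @keywords internal
msa_onehot <- function(msa) {
  codes <- matrix(encode_letters(msa$ali), nrow = nrow(msa$ali))
  M <- nrow(codes); L <- ncol(codes)
  unk <- codes == match(UNK, ALPHABET)
  row_idx <- rep(seq_len(M), L)
  col_pos <- rep(seq_len(L), each = M)
  known <- !as.vector(unk)
  i <- row_idx[known]
  j <- (col_pos[known] - 1L) * Q_STATES + as.vector(codes)[known]
  x <- rep(1, length(i))
  if (any(unk)) {
    iu <- row_idx[!known]
    pu <- col_pos[!known]
    i <- c(i, rep(iu, each = 20L))
    j <- c(j, as.vector(vapply(seq_along(iu), function(k) {
      (pu[k] - 1L) * Q_STATES + seq_len(20L)
    }, integer(20L))))
    x <- c(x, rep(1 / 20, 20L * length(iu)))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(M, L * Q_STATES))
}

#' Redundancy-correcting sequence weights
#'
#' Standard DCA-style reweighting: each sequence gets weight `1 / n_s`,
#' where `n_s` counts alignment rows (itself included) whose pairwise
#' identity to it is at least `identity_threshold`. Identity is the
#' fraction of columns with identical symbols (gaps included).
#'
#' @param msa A [coev_msa] (normally trimmed first).
#' @param identity_threshold Clustering identity threshold (default 0.8).
#' @return Numeric vector of `M` weights in (0, 1].
#' @export
compute_weights <- function(msa, identity_threshold = 0.8) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  codes <- matrix(encode_letters(msa$ali), nrow = nrow(msa$ali))
  M <- nrow(codes); L <- ncol(codes)
  # exact-match counts via sparse indicator crossproduct over all 22 symbols
  n_sym <- length(ALPHABET)
  X <- Matrix::sparseMatrix(
    i = rep(seq_len(M), L),
    j = (rep(seq_len(L), each = M) - 1L) * n_sym + as.vector(codes),
    x = 1, dims = c(M, L * n_sym))
  matches <- Matrix::tcrossprod(X)
  similar <- as.matrix(matches) / L >= identity_threshold
  1 / rowSums(similar)
}

#' Weighted single-site and pairwise frequencies
#'
#' Computes pseudocount-regularized frequencies over `q = 21` states (20
#' amino acids plus gap). Single-site:
#' `f_i(a) = lambda/q + (1 - lambda) * c_i(a) / Meff`; pairwise:
#' `f_ij(a,b) = lambda/q^2 + (1 - lambda) * c_ij(a,b) / Meff` for `i != j`,
#' while the diagonal blocks satisfy `f_ii(a,b) = f_i(a) * 1[a == b]`.
#' `Meff` is the sum of the sequence weights.
#'
#' @param msa A [coev_msa].
#' @param weights Sequence weights from [compute_weights()]; defaults to
#'   uniform weights.
#' @param lambda Pseudocount weight in `[0, 1]` (default 0.5, the usual
#'   mean-field DCA choice).
#' @return An object of class `coev_freqs`: list with `f1` (`L x q` matrix),
#'   `f2` (`(L*q) x (L*q)` matrix of pairwise blocks), `weights`,
#'   `effective_depth`, `lambda`, `L`, `q`.
#' @export
msa_frequencies <- function(msa, weights = NULL, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1)
  M <- nrow(msa$ali); L <- ncol(msa$ali)
  if (is.null(weights)) weights <- rep(1, M)
  stopifnot(length(weights) == M, all(weights > 0))
  meff <- sum(weights)
  X <- msa_onehot(msa)
  q <- Q_STATES
  c1 <- as.vector(Matrix::crossprod(X, weights)) / meff
  f1 <- matrix(lambda / q + (1 - lambda) * c1, nrow = L, ncol = q, byrow = TRUE)
  Xw <- X * sqrt(weights)
  c2 <- as.matrix(Matrix::crossprod(Xw)) / meff
  f2 <- lambda / q^2 + (1 - lambda) * c2
  # diagonal blocks carry single-site marginals, not products
  for (i in seq_len(L)) {
    idx <- (i - 1L) * q + seq_len(q)
    blk <- matrix(0, q, q)
    diag(blk) <- f1[i, ]
    f2[idx, idx] <- blk
  }
  structure(list(f1 = f1, f2 = f2, weights = weights,
                 effective_depth = meff, lambda = lambda, L = L, q = q),
            class = "coev_freqs")
}

#' @export
print.coev_freqs <- function(x, ...) {
  cat(sprintf("coev_freqs: L = %d, q = %d, Meff = %.2f, lambda = %.2f\n",
              x$L, x$q, x$effective_depth, x$lambda))
  invisible(x)
}

#' Per-column conservation scores
#'
#' Conservation of column `i` is `1 - H(f_i) / log(q)`, where `H` is the
#' Shannon entropy of the column's state frequencies over `q = 21` states.
#' A fully conserved column scores 1; a uniform column scores 0.
#'
#' @param freqs A `coev_freqs` object from [msa_frequencies()].
#' @return A tibble with columns `position` (1-based) and `conservation`.
#' @export
conservation <- function(freqs) {
  f <- freqs$f1
  h <- apply(f, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  tibble::tibble(position = seq_len(nrow(f)),
                 conservation = 1 - h / log(freqs$q))
}

#' Write conservation scores as TSV
#'
#' @param cons Tibble from [conservation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(cons, path) {
  readr::write_tsv(cons, path)
  invisible(path)
}
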