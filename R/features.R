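#' One-hot per-residue features
#'
#' Each residue is encoded as a length-21 indicator (20 amino acids + gap
#' slot); `X` is spread uniformly as 1/20 over the amino-acid slots, so
#' every row sums to 1.
#'
#' @param sequence Amino-acid string over the 20 amino acids, `X`, `-`.
#' @return `L x 21` matrix with attribute `featurizer = "onehot"`.
#' @export
onehot_features <- function(sequence) {
  letters_vec <- strsplit(sequence, "", fixed = TRUE)[[1]]
  codes <- encode_letters(letters_vec)
  L <- length(codes)
  out <- matrix(0, L, Q_STATES)
  unk_code <- match(UNK, ALPHABET)
  for (i in seq_len(L)) {
    if (codes[i] == unk_code) {
      out[i, seq_len(20)] <- 1 / 20
    } else {
      out[i, codes[i]] <- 1
    }
  }
  colnames(out) <- ALPHABET[seq_len(Q_STATES)]
  structure(out, featurizer = "onehot")
}

#' Seeded random-projection per-residue features
#'
#' Every symbol of the alphabet is mapped to a fixed `D`-vector drawn from
#' a seeded standard normal; residue `i`'s feature row is its letter's
#' vector. The map depends only on `(letter, seed)`, never on position, so
#' identical sequences give identical matrices and permuted sequences give
#' row-permuted matrices. This is the desk-scale stand-in for an external
#' protein-language-model embedding (whose published width is 1280).
#'
#' @param sequence Amino-acid string.
#' @param D Feature dimension (default 1280; synthetic experiments in this
#'   package use 32).
#' @param seed Integer seed for the letter-to-vector map.
#' @return `L x D` matrix with attribute `featurizer = "randproj"`.
#' @export
randproj_features <- function(sequence, D = 1280, seed = 1) {
  stopifnot(D >= 1)
  letters_vec <- strsplit(sequence, "", fixed = TRUE)[[1]]
  codes <- encode_letters(letters_vec)
  table <- withr::with_seed(as.integer(seed),
                            matrix(stats::rnorm(length(ALPHABET) * D),
                                   nrow = length(ALPHABET)))
  structure(table[codes, , drop = FALSE], featurizer = "randproj")
}

#' Load externally computed per-residue features
#'
#' Reads a whitespace- or tab-delimited numeric matrix (one residue per
#' row), e.g. a protein-language-model embedding exported as text.
#'
#' @param path Path to the matrix file.
#' @param expected_L Expected number of rows (protein length).
#' @return `L x D` matrix with attribute `featurizer = "external"`.
#' @export
load_external_features <- function(path, expected_L) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.numeric(m) || anyNA(m)) {
    stop("feature file contains non-numeric cells: ", path)
  }
  if (nrow(m) != expected_L) {
    stop(sprintf("feature file has %d rows but the protein has %d residues",
                 nrow(m), expected_L))
  }
  dimnames(m) <- NULL
  structure(m, featurizer = "external")
}
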