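#' Specification for a synthetic alignment
#'
#' Describes an MSA generator with per-column background distributions
#' (Dirichlet-distributed over the 20 amino acids), optional planted
#' covarying column pairs, optional conserved positions, and an i.i.d. gap
#' rate. Covariation is implemented as a bijective letter map: with
#' probability `rho`, column `j`'s letter is a fixed permutation image of
#' column `i`'s letter, otherwise it is drawn from its own background.
#' This yields analytically controllable mutual information without a
#' full Potts sampler.
#'
#' @param L Alignment length.
#' @param M Number of sequences.
#' @param dirichlet Dirichlet concentration for column backgrounds
#'   (default 1 = uniform simplex; large values approach uniform letter
#'   usage).
#' @param planted_pairs Data frame with columns `i`, `j`, `rho`; pairs
#'   must be disjoint.
#' @param conserved Data frame with columns `pos`, `prob` (dominant-letter
#'   probability).
#' @param gap_rate I.i.d. per-cell gap probability (default 0).
#' @param seed Integer seed.
#' @return A list of class `coev_msa_spec`.
#' @export
msa_spec <- function(L, M, dirichlet = 1, planted_pairs = NULL,
                     conserved = NULL, gap_rate = 0, seed = 1) {
  stopifnot(L >= 1, M >= 1, dirichlet > 0, gap_rate >= 0, gap_rate < 1)
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    stopifnot(all(c("i", "j", "rho") %in% names(planted_pairs)),
              all(planted_pairs$i >= 1), all(planted_pairs$j <= L),
              all(planted_pairs$rho >= 0), all(planted_pairs$rho <= 1))
    idx <- c(planted_pairs$i, planted_pairs$j)
    if (anyDuplicated(idx)) stop("planted pairs must be disjoint")
  }
  if (!is.null(conserved)) {
    conserved <- as.data.frame(conserved)
    stopifnot(all(c("pos", "prob") %in% names(conserved)),
              all(conserved$pos >= 1), all(conserved$pos <= L),
              all(conserved$prob >= 0), all(conserved$prob <= 1))
  }
  structure(list(L = as.integer(L), M = as.integer(M), dirichlet = dirichlet,
                 planted_pairs = planted_pairs, conserved = conserved,
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "coev_msa_spec")
}

#' Generate a synthetic alignment with planted covariation
#'
#' @param spec A [msa_spec()].
#' @return A [coev_msa] (row 1 is the query). Deterministic given the
#'   spec's seed.
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "coev_msa_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$L; M <- spec$M
    # per-column backgrounds from a Dirichlet(concentration) draw
    bg <- vapply(seq_len(L), function(i) {
      g <- stats::rgamma(20, shape = spec$dirichlet)
      g / sum(g)
    }, numeric(20))
    if (!is.null(spec$conserved)) {
      for (r in seq_len(nrow(spec$conserved))) {
        pos <- spec$conserved$pos[r]
        pr <- spec$conserved$prob[r]
        dom <- sample.int(20, 1)
        p <- rep((1 - pr) / 19, 20)
        p[dom] <- pr
        bg[, pos] <- p
      }
    }
    ali <- matrix("", M, L)
    for (i in seq_len(L)) {
      ali[, i] <- AA20[sample.int(20, M, replace = TRUE, prob = bg[, i])]
    }
    if (!is.null(spec$planted_pairs)) {
      for (r in seq_len(nrow(spec$planted_pairs))) {
        i <- spec$planted_pairs$i[r]
        j <- spec$planted_pairs$j[r]
        rho <- spec$planted_pairs$rho[r]
        bij <- sample(AA20)  # fixed bijection for this pair
        names(bij) <- AA20
        linked <- stats::runif(M) < rho
        ali[linked, j] <- bij[ali[linked, i]]
      }
    }
    if (spec$gap_rate > 0) {
      gap_mask <- matrix(stats::runif(M * L) < spec$gap_rate, M, L)
      ali[gap_mask] <- GAP
    }
    coev_msa(ali, ids = paste0("synth", seq_len(M)), query_index = 1L)
  })
}

#' Specification for a synthetic labelled protein dataset
#'
#' Each of `F` function labels is governed by a motif rule at designated
#' residue positions: the label is 1 iff every motif position carries a
#' letter from its allowed set (then flipped with probability
#' `noise_rate`). Motif positions of each label form a planted community
#' (a fully connected block) in both channel adjacencies, on top of sparse
#' random background edges, so site recovery can be validated against a
#' known ground truth.
#'
#' @param n_proteins Number of proteins.
#' @param L Protein length (fixed; default 60).
#' @param n_labels Number of function labels `F` (default 4).
#' @param motifs Optional list of `F` data frames with columns `pos` and
#'   `letters` (comma-free string of allowed letters). If `NULL`, each
#'   label gets `sites_per_label` disjoint random positions, each allowing
#'   a random set of `letterset_size` letters.
#' @param sites_per_label Motif positions per label when auto-generating
#'   (default 3, a planted community triangle).
#' @param letterset_size Size of the allowed-letter set when
#'   auto-generating; one shared set per label across its positions
#'   (default 13; with 3 sites this gives a class prevalence of about
#'   (13/20)^3 ~ 0.27).
#' @param D Feature dimension for the random-projection featurizer
#'   (default 32).
#' @param noise_rate Label flip probability in `[0, 0.5)` (default 0).
#' @param bg_edge_prob Background edge probability per channel (default
#'   0.01).
#' @param signal_amplitude Scale of the additive motif signature relative
#'   to the unit-variance letter features (default 1).
#' @param seed Integer seed.
#' @return A list of class `coev_function_spec`.
#' @export
function_spec <- function(n_proteins, L = 60, n_labels = 4, motifs = NULL,
                          sites_per_label = 3, letterset_size = 13,
                          D = 32, noise_rate = 0, bg_edge_prob = 0.01,
                          signal_amplitude = 1, seed = 1) {
  stopifnot(n_proteins >= 1, L >= 2, n_labels >= 1,
            noise_rate >= 0, noise_rate < 0.5,
            bg_edge_prob >= 0, bg_edge_prob <= 1, D >= 1)
  if (!is.null(motifs)) {
    stopifnot(length(motifs) == n_labels)
    for (m in motifs) {
      m <- as.data.frame(m)
      stopifnot(all(c("pos", "letters") %in% names(m)),
                all(m$pos >= 1), all(m$pos <= L))
    }
  } else {
    stopifnot(sites_per_label * n_labels <= L, letterset_size >= 1,
              letterset_size <= 20)
  }
  stopifnot(signal_amplitude >= 0)
  structure(list(n_proteins = as.integer(n_proteins), L = as.integer(L),
                 n_labels = as.integer(n_labels), motifs = motifs,
                 sites_per_label = as.integer(sites_per_label),
                 letterset_size = as.integer(letterset_size),
                 D = as.integer(D), noise_rate = noise_rate,
                 bg_edge_prob = bg_edge_prob,
                 signal_amplitude = signal_amplitude,
                 seed = as.integer(seed)),
            class = "coev_function_spec")
}

# Fixed per-(label, position) signature vectors, seeded.
#' @keywords internal
motif_signatures <- function(motifs, D, signature_seed) {
  withr::with_seed(as.integer(signature_seed), {
    lapply(motifs, function(m)
      matrix(stats::rnorm(nrow(m) * D), nrow(m), D))
  })
}

# Dataset node features: letter randproj plus, for every satisfied motif
# rule, the label's signature added at its motif positions.
#' @keywords internal
dataset_features <- function(sequence, D, feature_seed, motifs, signatures,
                             amplitude) {
  X <- unclass(randproj_features(sequence, D = D, seed = feature_seed))
  seq_letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (c in seq_along(motifs)) {
    if (motif_satisfied(seq_letters, motifs[[c]])) {
      X[motifs[[c]]$pos, ] <- X[motifs[[c]]$pos, ] +
        amplitude * signatures[[c]]
    }
  }
  unname(X)
}

#' @keywords internal
motif_satisfied <- function(seq_letters, motif) {
  all(vapply(seq_len(nrow(motif)), function(r) {
    grepl(substr(seq_letters[motif$pos[r]], 1, 1), motif$letters[r],
          fixed = TRUE)
  }, logical(1)))
}

#' Generate a synthetic labelled protein dataset
#'
#' Sequences are sampled uniformly over the 20 amino acids; labels follow
#' the motif rules; both channel adjacencies carry the planted motif
#' blocks of every label plus independent sparse background edges.
#' Node features are position-independent letter embeddings from
#' [randproj_features()] with a dataset-wide letter map; when a protein's
#' sequence satisfies a label's motif rule, a fixed per-(label, position)
#' signature vector (amplitude `signal_amplitude`) is added to the
#' features of that label's motif residues. The signature is the
#' synthetic counterpart of the contextual signal a protein-language-model
#' embedding carries at a realized functional constellation; without some
#' such position-resolved signal the labels are not identifiable by any
#' permutation-equivariant network, because background edges whose
#' letters match the motif sets are isomorphic to the true motif block.
#' Label noise flips labels only, never signatures (annotation noise, not
#' embedding noise). Proteins are split train/validation/test in
#' proportions 70/15/15.
#'
#' @param spec A [function_spec()].
#' @return List with `dataset` (a [coev_dataset()]), `sites` (tibble:
#'   `label`, `position` — the ground-truth functional residues per
#'   label), and `motifs` (the realized motif rules).
#' @export
generate_function_dataset <- function(spec) {
  stopifnot(inherits(spec, "coev_function_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$L
    nf <- spec$n_labels
    motifs <- spec$motifs
    if (is.null(motifs)) {
      pos_pool <- sample.int(L, spec$sites_per_label * nf)
      motifs <- lapply(seq_len(nf), function(c) {
        pos <- sort(pos_pool[(c - 1) * spec$sites_per_label +
                               seq_len(spec$sites_per_label)])
        allowed <- paste(sample(AA20, spec$letterset_size), collapse = "")
        data.frame(pos = pos, letters = allowed)  # one shared set per label
      })
    } else {
      motifs <- lapply(motifs, as.data.frame)
    }
    # degenerate-class-balance guard on 1000 trial draws
    trial <- matrix(AA20[sample.int(20, 1000 * L, replace = TRUE)], 1000, L)
    for (c in seq_len(nf)) {
      rate <- mean(apply(trial, 1, motif_satisfied, motif = motifs[[c]]))
      margin <- 2 * sqrt(0.05 * 0.95 / 1000)  # Monte-Carlo slack at the bound
      if (rate < 0.05 - margin || rate > 0.95 + margin) {
        stop(sprintf(
          "motif rule for label %d has satisfaction rate %.3f outside [0.05, 0.95]",
          c, rate))
      }
    }
    feature_seed <- sample.int(2^30, 1)
    signature_seed <- sample.int(2^30, 1)
    signatures <- motif_signatures(motifs, spec$D, signature_seed)
    vocab <- paste0("FN:", sprintf("%04d", seq_len(nf)))
    block_edges <- matrix(0, L, L)
    for (c in seq_len(nf)) {
      pos <- motifs[[c]]$pos
      block_edges[as.matrix(expand.grid(pos, pos))] <- 1
    }
    diag(block_edges) <- 0
    proteins <- lapply(seq_len(spec$n_proteins), function(n) {
      seq_letters <- AA20[sample.int(20, L, replace = TRUE)]
      labels <- vapply(motifs, function(m)
        as.integer(motif_satisfied(seq_letters, m)), integer(1))
      if (spec$noise_rate > 0) {
        flip <- stats::runif(nf) < spec$noise_rate
        labels[flip] <- 1L - labels[flip]
      }
      rand_adj <- function() {
        A <- matrix(0, L, L)
        up <- which(upper.tri(A))
        on <- up[stats::runif(length(up)) < spec$bg_edge_prob]
        A[on] <- 1
        A <- A + t(A)
        A <- pmax(A, block_edges)
        diag(A) <- 0
        A
      }
      protein_graph(
        features = dataset_features(paste(seq_letters, collapse = ""),
                                    D = spec$D, feature_seed = feature_seed,
                                    motifs = motifs, signatures = signatures,
                                    amplitude = spec$signal_amplitude),
        adj_evc = rand_adj(), adj_rc = rand_adj(),
        labels = labels, id = sprintf("prot%05d", n),
        sequence = paste(seq_letters, collapse = ""))
    })
    n <- spec$n_proteins
    split <- rep("train", n)
    if (n >= 3) {
      cut1 <- floor(0.70 * n)
      cut2 <- floor(0.85 * n)
      split[(cut1 + 1):cut2] <- "validation"
      split[(cut2 + 1):n] <- "test"
    }
    sites <- dplyr::bind_rows(lapply(seq_len(nf), function(c)
      tibble::tibble(label = vocab[c], position = motifs[[c]]$pos)))
    list(dataset = coev_dataset(proteins, vocab, split),
         sites = sites, motifs = motifs, feature_seed = feature_seed,
         signature_seed = signature_seed)
  })
}

#' Generate a random evaluation-set fixture
#'
#' Truths are i.i.d. Bernoulli(0.2); predictions interpolate between the
#' truth and uniform noise: `quality * truth + (1 - quality) * U(0,1)`,
#' clipped to `[0, 1]`. `quality = 1` is a perfect predictor.
#'
#' @param N Number of proteins.
#' @param F Number of terms.
#' @param quality Real in `[0, 1]`.
#' @param seed Integer seed.
#' @return An [evaluation_set()].
#' @export
generate_metric_fixture <- function(N, F, quality, seed = 1) {
  stopifnot(N >= 1, F >= 1, quality >= 0, quality <= 1)
  withr::with_seed(as.integer(seed), {
    truths <- matrix(stats::rbinom(N * F, 1, 0.2), N, F)
    if (sum(truths) == 0) truths[1, 1] <- 1
    preds <- quality * truths + (1 - quality) * matrix(stats::runif(N * F), N, F)
    preds <- pmin(pmax(preds, 0), 1)
    evaluation_set(preds, truths,
                   vocabulary = paste0("T", sprintf("%03d", seq_len(F))))
  })
}
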