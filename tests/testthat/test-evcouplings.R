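test_that("coupling_matrix enforces symmetry and zero diagonal", {
  expect_error(coupling_matrix(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  bad <- diag(2)
  expect_error(coupling_matrix(bad), "diagonal")
  ok <- coupling_matrix(matrix(c(0, 2, 2, 0), 2, 2))
  expect_false(ok$normalized)
})

test_that("planted strongly covarying pairs dominate the APC scores", {
  pairs <- data.frame(i = c(5, 20), j = c(12, 33), rho = 0.95)
  msa <- generate_msa(msa_spec(L = 40, M = 1500, planted_pairs = pairs,
                               seed = 101))
  fr <- msa_frequencies(msa, compute_weights(msa))
  C <- infer_couplings(fr)
  ed <- coupling_edges(normalize_couplings(C))
  top2 <- paste(ed$i[1:2], ed$j[1:2])
  expect_setequal(top2, c("5 12", "20 33"))
})

test_that("i.i.d. alignments yield near-zero APC scores relative to signal", {
  null_msa <- generate_msa(msa_spec(L = 30, M = 1500, seed = 7))
  fr <- msa_frequencies(null_msa, compute_weights(null_msa))
  null_raw <- infer_couplings(fr)$scores
  planted <- generate_msa(msa_spec(
    L = 30, M = 1500, planted_pairs = data.frame(i = 4, j = 19, rho = 0.9),
    seed = 7))
  frp <- msa_frequencies(planted, compute_weights(planted))
  Cp <- infer_couplings(frp)
  # the planted pair separates clearly from the background of its own matrix
  bg <- Cp$scores
  bg[4, 19] <- bg[19, 4] <- 0
  expect_gt(Cp$scores[4, 19], 3 * max(bg))
  # and from everything an i.i.d. alignment of the same size produces
  expect_gt(Cp$scores[4, 19], 3 * max(null_raw))
})

test_that("APC correction lowers the high quantiles of null coupling scores", {
  # property over several seeds: 99th percentile of APC scores below that of
  # uncorrected Frobenius scores on i.i.d. alignments
  wins <- vapply(1:10, function(s) {
    msa <- generate_msa(msa_spec(L = 20, M = 400, seed = 200 + s))
    fr <- msa_frequencies(msa, compute_weights(msa))
    qa <- fr$q - 1L
    keep <- as.vector(vapply(seq_len(fr$L),
                             function(i) (i - 1L) * fr$q + seq_len(qa),
                             integer(qa)))
    Cm <- fr$f2[keep, keep] -
      tcrossprod(as.vector(t(fr$f1[, seq_len(qa), drop = FALSE])))
    e <- -solve(Cm)
    fn <- matrix(0, fr$L, fr$L)
    for (i in seq_len(fr$L - 1)) {
      for (j in (i + 1):fr$L) {
        blk <- e[(i - 1) * qa + seq_len(qa), (j - 1) * qa + seq_len(qa)]
        blk <- sweep(sweep(blk, 1, rowMeans(blk)), 2, colMeans(blk)) + mean(blk)
        fn[i, j] <- fn[j, i] <- sqrt(sum(blk^2))
      }
    }
    apc <- infer_couplings(fr)$scores
    up <- upper.tri(fn)
    unname(quantile(apc[up], 0.99) < quantile(fn[up], 0.99))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("couplings are invariant to row permutation and equivariant to column permutation", {
  pairs <- data.frame(i = 2, j = 9, rho = 0.8)
  msa <- generate_msa(msa_spec(L = 12, M = 300, planted_pairs = pairs, seed = 5))
  w <- compute_weights(msa)
  base <- infer_couplings(msa_frequencies(msa, w))$scores
  rowp <- withr::with_seed(1, sample(nrow(msa$ali)))
  msa_r <- coev_msa(msa$ali[rowp, ], query_index = which(rowp == 1))
  got_r <- infer_couplings(msa_frequencies(msa_r, w[rowp]))$scores
  expect_equal(got_r, base, tolerance = 1e-9)
  colp <- withr::with_seed(2, sample(ncol(msa$ali)))
  msa_c <- coev_msa(msa$ali[, colp])
  got_c <- infer_couplings(msa_frequencies(msa_c, w))$scores
  expect_equal(got_c, base[colp, colp], tolerance = 1e-8)
})

test_that("the smallest L = 2 alignment yields a single symmetric score", {
  msa <- coev_msa(rbind(c("A", "C"), c("C", "A"), c("A", "C"), c("D", "E")))
  C <- infer_couplings(msa_frequencies(msa, lambda = 0.5))
  expect_equal(dim(C$scores), c(2L, 2L))
  expect_equal(C$scores[1, 2], C$scores[2, 1])
  expect_equal(diag(C$scores), c(0, 0))
})

test_that("normalize_couplings scales the maximum to one and handles zeros", {
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 4; m[1, 3] <- m[3, 1] <- 1
  n <- normalize_couplings(coupling_matrix(m))
  expect_equal(max(n$scores), 1)
  expect_equal(n$scores[1, 3], 0.25)
  expect_true(n$normalized)
  z <- normalize_couplings(coupling_matrix(matrix(0, 3, 3)))
  expect_equal(z$scores, matrix(0, 3, 3))
  expect_true(z$normalized)
})

test_that("threshold_adjacency uses the >= convention and validates inputs", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.19
  m[1, 3] <- m[3, 1] <- 0.20
  m[2, 3] <- m[3, 2] <- 1
  C <- coupling_matrix(m, normalized = TRUE)
  A <- threshold_adjacency(C, 0.2)
  expect_equal(A[1, 2], 0)
  expect_equal(A[1, 3], 1)
  expect_equal(A[2, 3], 1)
  expect_equal(diag(unclass(A)), rep(0, 3))
  expect_true(isSymmetric(unclass(A)[1:3, 1:3]))
  # threshold 0 keeps every nonzero pair; threshold 1 only maximal ones
  expect_equal(sum(threshold_adjacency(C, 0)), 6)
  expect_equal(sum(threshold_adjacency(C, 1)), 2)
  expect_error(threshold_adjacency(C, 1.2), "\\[0, 1\\]")
  expect_error(threshold_adjacency(coupling_matrix(m), 0.2), "normalized")
})

test_that("singular covariance at lambda = 0 advises a larger pseudocount", {
  degenerate <- coev_msa(matrix(rep(c("A", "C"), 5), 2, 5, byrow = FALSE))
  fr <- msa_frequencies(degenerate, lambda = 0)
  expect_error(infer_couplings(fr), "lambda")
})

test_that("coupling edge lists round-trip through TSV", {
  m <- matrix(0, 4, 4); m[1, 3] <- m[3, 1] <- 0.9; m[2, 4] <- m[4, 2] <- 0.4
  C <- coupling_matrix(m, normalized = TRUE)
  f <- tempfile(fileext = ".tsv")
  write_couplings(C, f)
  got <- read.delim(f)
  expect_equal(got$score[1], 0.9)
  expect_equal(nrow(got), 6)  # all upper-triangle pairs retained
})
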