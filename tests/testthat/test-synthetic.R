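test_that("planted covariation maximizes inter-column mutual information", {
  mi <- function(x, y) {
    tab <- table(x, y)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    sum(p[p > 0] * log(p[p > 0] / outer(px, py)[p > 0]))
  }
  msa <- generate_msa(msa_spec(L = 15, M = 1200,
                               planted_pairs = data.frame(i = 4, j = 11, rho = 1),
                               seed = 21))
  mis <- matrix(0, 15, 15)
  for (i in 1:14) for (j in (i + 1):15) {
    mis[i, j] <- mi(msa$ali[, i], msa$ali[, j])
  }
  expect_equal(unname(which(mis == max(mis), arr.ind = TRUE)[1, ]), c(4L, 11L))
  # a rho = 0.9 pair still separates cleanly from an unplanted alignment
  msa9 <- generate_msa(msa_spec(L = 15, M = 1200,
                                planted_pairs = data.frame(i = 4, j = 11, rho = 0.9),
                                seed = 22))
  null_msa <- generate_msa(msa_spec(L = 15, M = 1200, seed = 23))
  mi_planted <- mi(msa9$ali[, 4], msa9$ali[, 11])
  null_mis <- c()
  for (i in 1:14) for (j in (i + 1):15) {
    null_mis <- c(null_mis, mi(null_msa$ali[, i], null_msa$ali[, j]))
  }
  expect_gt(mi_planted, max(null_mis))
})

test_that("generated alignments respect gap rate and conserved positions", {
  spec <- msa_spec(L = 12, M = 800, conserved = data.frame(pos = 5, prob = 0.9),
                   seed = 31)
  msa <- generate_msa(spec)
  expect_false(any(msa$ali == "-"))
  freq <- max(table(msa$ali[, 5])) / 800
  expect_lt(abs(freq - 0.9), 3 * sqrt(0.9 * 0.1 / 800) + 0.01)
  gappy <- generate_msa(msa_spec(L = 12, M = 500, gap_rate = 0.2, seed = 32))
  expect_lt(abs(mean(gappy$ali == "-") - 0.2), 0.02)
})

test_that("msa generation is a pure function of its spec", {
  spec <- msa_spec(L = 10, M = 50, gap_rate = 0.1, seed = 12)
  expect_identical(generate_msa(spec)$ali, generate_msa(spec)$ali)
  other <- generate_msa(msa_spec(L = 10, M = 50, gap_rate = 0.1, seed = 13))
  expect_false(identical(generate_msa(spec)$ali, other$ali))
})

test_that("explicit single-letter motif rules label proteins exactly", {
  motifs <- list(data.frame(pos = 5, letters = "C"))
  gen <- generate_function_dataset(
    function_spec(n_proteins = 300, L = 12, n_labels = 1, motifs = motifs,
                  noise_rate = 0, bg_edge_prob = 0, seed = 41))
  labels <- vapply(gen$dataset$proteins, function(g) g$labels, integer(1))
  at5 <- vapply(gen$dataset$proteins, function(g)
    substr(g$sequence, 5, 5) == "C", logical(1))
  expect_equal(labels, as.integer(at5))
  # prevalence near the 1/20 binomial expectation
  expect_lt(abs(mean(labels) - 0.05), 0.05)
})

test_that("class prevalence tracks the analytic motif expectation", {
  gen <- generate_function_dataset(function_spec(n_proteins = 2000, seed = 42))
  labs <- do.call(rbind, lapply(gen$dataset$proteins, function(g) g$labels))
  expect_true(all(abs(colMeans(labs) - (13 / 20)^3) < 0.05))
})

test_that("degenerate motif rules are rejected", {
  motifs <- list(data.frame(pos = c(2, 4, 6), letters = "A"))  # rate 20^-3
  expect_error(generate_function_dataset(
    function_spec(n_proteins = 10, L = 8, n_labels = 1, motifs = motifs,
                  seed = 1)), "satisfaction rate")
})

test_that("function datasets are reproducible and carry planted structure", {
  spec <- function_spec(n_proteins = 40, L = 20, n_labels = 2, seed = 77)
  g1 <- generate_function_dataset(spec)
  g2 <- generate_function_dataset(spec)
  expect_identical(lapply(g1$dataset$proteins, `[[`, "sequence"),
                   lapply(g2$dataset$proteins, `[[`, "sequence"))
  expect_identical(g1$dataset$proteins[[5]]$features,
                   g2$dataset$proteins[[5]]$features)
  expect_identical(g1$sites, g2$sites)
  # motif positions form cliques in both channel adjacencies
  for (lab in unique(g1$sites$label)) {
    pos <- g1$sites$position[g1$sites$label == lab]
    for (g in g1$dataset$proteins[1:3]) {
      expect_true(all(g$adj_evc[t(combn(pos, 2))] == 1))
      expect_true(all(g$adj_rc[t(combn(pos, 2))] == 1))
    }
  }
  # labels flip at the requested noise rate relative to the rule's truth
  noisy <- generate_function_dataset(
    function_spec(n_proteins = 1500, L = 20, n_labels = 1,
                  noise_rate = 0.2, seed = 78))
  rule <- noisy$motifs[[1]]
  truth <- vapply(noisy$dataset$proteins, function(g) {
    letters_vec <- strsplit(g$sequence, "")[[1]]
    as.integer(all(vapply(seq_len(nrow(rule)), function(r)
      grepl(letters_vec[rule$pos[r]], rule$letters[r], fixed = TRUE),
      logical(1))))
  }, integer(1))
  observed <- vapply(noisy$dataset$proteins, function(g) g$labels, integer(1))
  expect_lt(abs(mean(observed != truth) - 0.2), 0.04)
})

test_that("motif signatures are added exactly at functional residues of positive proteins", {
  gen <- generate_function_dataset(function_spec(n_proteins = 120, L = 10,
                                                 n_labels = 1, D = 16,
                                                 sites_per_label = 2,
                                                 noise_rate = 0, seed = 9))
  ds <- gen$dataset
  pos <- gen$motifs[[1]]$pos
  labels <- vapply(ds$proteins, function(g) g$labels, integer(1))
  resid <- lapply(ds$proteins, function(g)
    g$features - unclass(randproj_features(g$sequence, D = 16,
                                           seed = gen$feature_seed)))
  neg <- resid[labels == 0]
  pospro <- resid[labels == 1]
  expect_gt(length(pospro), 1)
  # negatives carry no signature anywhere
  expect_true(all(vapply(neg, function(r) max(abs(r)) < 1e-12, logical(1))))
  # positives carry one shared signature, only at the motif positions
  expect_equal(pospro[[1]][pos, ], pospro[[2]][pos, ], tolerance = 1e-12)
  off <- setdiff(1:10, pos)
  expect_true(max(abs(pospro[[1]][off, ])) < 1e-12)
  expect_gt(max(abs(pospro[[1]][pos, ])), 0.1)
})
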