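test_that("a zero-weight classification head yields an all-zero profile", {
  g <- toy_graph(L = 7, D = 4, seed = 2)
  model <- dual_gcn(D = 4, n_classes = 2, hidden = 4, seed = 3)
  model$par$W_fc2[] <- 0
  prof <- activation_scores(model, g, 1)
  expect_equal(prof$score, rep(0, 7))
  expect_equal(prof$raw, rep(0, 7))
  expect_equal(call_functional_sites(prof), integer(0))
})

test_that("neuron weights match central finite differences of the class score", {
  g <- toy_graph(L = 6, D = 5, seed = 4)
  model <- dual_gcn(D = 5, n_classes = 3, hidden = 4, seed = 6)
  prof <- activation_scores(model, g, 2)
  alpha <- attr(prof, "alpha")
  fmap <- forward_dual_gcn(g, model)$feature_map
  # head-only re-evaluation: Y_c as a function of the feature map
  head_prob <- function(fm) {
    p <- model$par
    pooled <- colSums(fm)
    z1 <- pmax(as.numeric(pooled %*% p$W_fc1) + p$b_fc1, 0)
    z2 <- as.numeric(z1 %*% p$W_fc2) + p$b_fc2
    1 / (1 + exp(-z2[2]))
  }
  L <- nrow(fmap)
  eps <- 1e-5
  withr::with_seed(8, {
    for (k in sample(ncol(fmap), 6)) {
      i <- sample(L, 1)
      up <- fmap; up[i, k] <- up[i, k] + eps
      dn <- fmap; dn[i, k] <- dn[i, k] - eps
      fd <- (head_prob(up) - head_prob(dn)) / (2 * eps)
      # alpha_k equals dY/dF_ik for every residue i (sum pooling)
      expect_equal(alpha[k], fd, tolerance = 1e-3)
    }
  })
})

test_that("non-degenerate profiles are normalized to a maximum of one", {
  g <- toy_graph(L = 10, D = 4, seed = 5)
  model <- dual_gcn(D = 4, n_classes = 2, hidden = 6, seed = 9)
  prof <- activation_scores(model, g, 1)
  expect_true(all(prof$score >= 0 & prof$score <= 1))
  if (max(prof$raw) > 0) expect_equal(max(prof$score), 1)
  expect_true(all(prof$raw >= 0))
})

test_that("normalized profiles are invariant to compensated feature-map rescaling", {
  # scaling the channel outputs by c and the first FC weights by 1/c leaves
  # the normalized profile unchanged
  g <- toy_graph(L = 8, D = 4, seed = 7)
  model <- dual_gcn(D = 4, n_classes = 2, hidden = 4, seed = 10)
  for (nm in names(model$par)) {
    if (startsWith(nm, "b") && grepl("evc|rc", nm)) model$par[[nm]][] <- 0
  }
  base <- activation_scores(model, g, 1)
  scaled <- model
  cfac <- 3.7
  scaled$par$W3_evc <- scaled$par$W3_evc * cfac
  scaled$par$W3_rc <- scaled$par$W3_rc * cfac
  scaled$par$W_fc1 <- scaled$par$W_fc1 / cfac
  got <- activation_scores(scaled, g, 1)
  expect_equal(got$score, base$score, tolerance = 1e-8)
})

test_that("site calling applies the >= 0.5 convention", {
  prof <- structure(tibble::tibble(residue = 1:3, score = c(0.1, 0.5, 0.9),
                                   raw = c(0.1, 0.5, 0.9)),
                    class = c("coev_profile", class(tibble::tibble())))
  expect_equal(call_functional_sites(prof), c(2L, 3L))
  expect_equal(call_functional_sites(prof, cutoff = 0), 1:3)
  zero <- structure(tibble::tibble(residue = 1:3, score = rep(0, 3),
                                   raw = rep(0, 3)),
                    class = c("coev_profile", class(tibble::tibble())))
  expect_equal(call_functional_sites(zero), integer(0))
})

test_that("site agreement scores perfect, random and degenerate references", {
  mk <- function(scores) {
    structure(tibble::tibble(residue = seq_along(scores), score = scores,
                             raw = scores),
              class = c("coev_profile", class(tibble::tibble())))
  }
  ref <- c(2, 5, 8)
  perfect <- mk(as.numeric(1:10 %in% ref))
  pa <- site_agreement(perfect, ref)
  expect_equal(pa$auroc, 1)
  expect_equal(pa$precision, 1)
  expect_equal(pa$recall, 1)
  # random scores hover near chance over repeated draws
  aurocs <- vapply(1:20, function(s) {
    withr::with_seed(s, site_agreement(mk(runif(40)), c(3, 11, 25))$auroc)
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.12)
  # reference = all residues: recall equals the fraction called
  all_ref <- site_agreement(mk(c(0.9, 0.2, 0.7, 0.1)), 1:4)
  expect_equal(all_ref$recall, 2 / 4)
  expect_error(site_agreement(perfect, c(1, 99)), "out of range")
  expect_error(site_agreement(perfect, integer(0)), "empty")
})

test_that("pROC-based AUROC agrees with the rank-statistic formula", {
  withr::with_seed(13, {
    scores <- runif(30)
    ref <- sample(30, 7)
    prof <- structure(tibble::tibble(residue = 1:30, score = scores,
                                     raw = scores),
                      class = c("coev_profile", class(tibble::tibble())))
    got <- site_agreement(prof, ref)$auroc
    expect_equal(got, auroc_rank(scores, as.integer(1:30 %in% ref)),
                 tolerance = 1e-12)
  })
})

test_that("profiles write as TSV with sequence and call columns", {
  g <- toy_graph(L = 5, D = 4, seed = 3)
  model <- dual_gcn(D = 4, n_classes = 2, hidden = 3, seed = 4)
  prof <- activation_scores(model, g, 1)
  f <- tempfile(fileext = ".tsv")
  write_profile(prof, f, sequence = "ACDEF")
  got <- read.delim(f)
  expect_equal(names(got), c("residue", "aa", "score", "called"))
  expect_equal(got$aa, c("A", "C", "D", "E", "F"))
  expect_equal(got$called, as.integer(got$score >= 0.5))
})

test_that("class selection validates names and indices", {
  g <- toy_graph(L = 5, D = 4, seed = 3)
  model <- dual_gcn(D = 4, n_classes = 2, hidden = 3,
                    vocabulary = c("GO:1", "GO:2"), seed = 4)
  expect_error(activation_scores(model, g, "GO:9"), "not in the model vocabulary")
  expect_error(activation_scores(model, g, 5), "out of range")
  prof <- activation_scores(model, g, "GO:2")
  expect_equal(attr(prof, "class_label"), "GO:2")
})
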