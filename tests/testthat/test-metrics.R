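test_that("fmax is exact on perfect and empty predictors", {
  truth <- matrix(c(1, 0, 1, 1), 2, 2)
  perfect <- evaluation_set(truth, truth)
  expect_equal(fmax(perfect)$fmax, 1)
  none <- evaluation_set(matrix(0, 2, 2), truth)
  expect_equal(fmax(none)$fmax, 0)
})

test_that("fmax matches the brute-force threshold-scan oracle exactly", {
  # a hand-checkable toy case plus 100 random fixtures
  truth <- rbind(c(1, 0), c(1, 1))
  pred <- rbind(c(0.9, 0.6), c(0.8, 0.1))
  ev <- evaluation_set(pred, truth)
  expect_equal(fmax(ev)$fmax, fmax_oracle(pred, truth))
  withr::with_seed(31, {
    for (case in 1:100) {
      n <- sample(2:6, 1); f <- sample(2:4, 1)
      truth <- matrix(rbinom(n * f, 1, 0.4), n, f)
      if (sum(truth) == 0) truth[1, 1] <- 1
      pred <- matrix(round(runif(n * f), 2), n, f)
      ev <- evaluation_set(pred, truth)
      expect_identical(fmax(ev)$fmax, fmax_oracle(pred, truth))
    }
  })
})

test_that("fmax errors when no protein carries a true label", {
  expect_error(evaluation_set(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "no positive truth")
})

test_that("aupr is exact for perfect predictors and matches the oracle on toys", {
  truth <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
  perfect <- evaluation_set(truth, truth)
  expect_equal(aupr(perfect)$aupr, 1)
  expect_equal(aupr(perfect, "micro")$aupr, 1)
  # 6-pair toy case against the all-threshold oracle, term by term
  withr::with_seed(17, {
    for (case in 1:50) {
      n <- 6
      scores <- round(runif(n), 2)
      labels <- rbinom(n, 1, 0.5)
      if (sum(labels) == 0) labels[2] <- 1
      ev <- evaluation_set(matrix(scores), matrix(labels))
      expect_equal(aupr(ev)$aupr, aupr_oracle_term(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("aupr of label-independent scores approaches the prevalence", {
  ev <- generate_metric_fixture(N = 3000, F = 4, quality = 0, seed = 5)
  expect_lt(abs(aupr(ev)$aupr - 0.2), 0.04)
  expect_lt(abs(aupr(ev, "micro")$aupr - 0.2), 0.04)
})

test_that("aupr is invariant to protein order and improves when a false positive drops", {
  ev <- generate_metric_fixture(N = 200, F = 3, quality = 0.5, seed = 9)
  perm <- withr::with_seed(1, sample(200))
  ev_perm <- evaluation_set(ev$predictions[perm, ], ev$truths[perm, ])
  expect_equal(aupr(ev_perm)$aupr, aupr(ev)$aupr, tolerance = 1e-12)
  # push one false positive's score below every true positive's score
  pred <- ev$predictions
  j <- 1
  fp <- which(ev$truths[, j] == 0 & pred[, j] > 0.5)[1]
  pred2 <- pred
  pred2[fp, j] <- 0
  before <- aupr(evaluation_set(pred, ev$truths))$aupr
  after <- aupr(evaluation_set(pred2, ev$truths))$aupr
  expect_gte(after, before)
})

test_that("the literal threshold-integral variant is available and bounded", {
  ev <- generate_metric_fixture(N = 100, F = 3, quality = 1, seed = 2)
  lit <- aupr(ev, integral = "literal")$aupr
  expect_true(lit >= 0 && lit <= 1)
})

test_that("mcc matches hand-computed confusion counts and symmetries", {
  truth <- matrix(c(rep(1, 8), rep(0, 4)), 3, 4)
  expect_equal(mcc_score(evaluation_set(truth, truth)), 1)
  expect_equal(mcc_score(evaluation_set(1 - truth, truth)), -1)
  # TP=6 TN=3 FP=1 FN=2 -> (18-2)/sqrt(7*8*4*5) = 16/sqrt(1120)
  pred <- matrix(c(1, 1, 1, 1, 1, 1, 0, 0, 1, 0, 0, 0), 3, 4)
  tr <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0), 3, 4)
  expect_equal(mcc_score(pred, truths = tr), 16 / sqrt(1120), tolerance = 1e-12)
  expect_equal(mcc_score(pred, truths = tr), 0.4781, tolerance = 1e-4)
  # symmetric under simultaneous inversion
  expect_equal(mcc_score(1 - pred, truths = 1 - tr),
               mcc_score(pred, truths = tr), tolerance = 1e-12)
  # zero denominator -> 0
  expect_equal(mcc_score(matrix(1, 2, 2), truths = matrix(c(1, 1, 0, 1), 2, 2)), 0)
})

test_that("bootstrap is reproducible and degenerate for perfect predictors", {
  ev <- generate_metric_fixture(N = 50, F = 3, quality = 1, seed = 3)
  for (nb in c(10, 50)) {
    b1 <- bootstrap_metric(ev, function(e) fmax(e)$fmax, n_boot = nb, seed = 7)
    b2 <- bootstrap_metric(ev, function(e) fmax(e)$fmax, n_boot = nb, seed = 7)
    expect_identical(b1$replicates, b2$replicates)
    expect_equal(nrow(b1$replicates), nb)
    expect_equal(b1$sd, 0)
    expect_equal(b1$mean, 1)
  }
  noisy <- generate_metric_fixture(N = 40, F = 3, quality = 0.5, seed = 4)
  b <- bootstrap_metric(noisy, function(e) fmax(e)$fmax, n_boot = 10, seed = 1)
  expect_true(b$mean >= min(b$replicates$value, na.rm = TRUE))
  expect_true(b$mean <= max(b$replicates$value, na.rm = TRUE))
})

test_that("identity stratification equals direct subset evaluation", {
  ev0 <- generate_metric_fixture(N = 60, F = 3, quality = 0.8, seed = 6)
  ident <- withr::with_seed(2, runif(60))
  ev <- evaluation_set(ev0$predictions, ev0$truths, identity = ident)
  out <- identity_stratified(ev, function(e) fmax(e)$fmax,
                             thresholds = c(0.4, 0.95))
  for (r in 1:2) {
    idx <- which(ident <= out$threshold[r])
    sub <- evaluation_set(ev0$predictions[idx, ], ev0$truths[idx, ])
    expect_equal(out$value[r], fmax(sub)$fmax)
  }
  # identities all below every threshold reproduce the full-set metric
  flat <- evaluation_set(ev0$predictions, ev0$truths,
                         identity = rep(0.2, 60))
  strat <- identity_stratified(flat, function(e) fmax(e)$fmax)
  expect_true(all(strat$value == fmax(ev0)$fmax))
  # thresholds below the minimum identity are missing
  high <- evaluation_set(ev0$predictions, ev0$truths,
                         identity = rep(0.9, 60))
  miss <- identity_stratified(high, function(e) fmax(e)$fmax,
                              thresholds = c(0.3))
  expect_true(is.na(miss$value))
  expect_error(evaluation_set(ev0$predictions, ev0$truths,
                              identity = rep(1.5, 60)), "\\[0, 1\\]")
})

test_that("metric fixtures are seeded and quality-calibrated", {
  a <- generate_metric_fixture(N = 30, F = 2, quality = 0.7, seed = 11)
  b <- generate_metric_fixture(N = 30, F = 2, quality = 0.7, seed = 11)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$truths, b$truths)
  expect_equal(fmax(generate_metric_fixture(50, 3, 1, seed = 1))$fmax, 1)
})
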