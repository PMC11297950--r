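# Shared fixture builders. All fixtures are generated in code; file-based
# fixtures are written to tempdirs at test time.

write_fasta_fixture <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

# small alignment with a known gap structure
toy_msa <- function() {
  coev_msa(rbind(
    strsplit("ACDEFGHIKL", "")[[1]],
    strsplit("ACDEFGHIKV", "")[[1]],
    strsplit("ACDEF-----", "")[[1]],
    strsplit("MNPQRSTVWY", "")[[1]]),
    ids = c("query", "s2", "s3", "s4"))
}

# deterministic two-block coupling matrix (within-block score 1)
two_block_matrix <- function(block = 10, L = 2 * block) {
  S <- matrix(0, L, L)
  S[seq_len(block), seq_len(block)] <- 1
  S[(block + 1):(2 * block), (block + 1):(2 * block)] <- 1
  diag(S) <- 0
  coupling_matrix(S, normalized = TRUE)
}

# small random protein graph with labels
toy_graph <- function(L = 8, D = 5, F = 3, seed = 1, labels = NULL) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(L * D), L, D)
    rand_adj <- function() {
      A <- matrix(0, L, L)
      up <- which(upper.tri(A))
      A[sample(up, max(1, length(up) %/% 4))] <- 1
      A <- A + t(A)
      diag(A) <- 0
      (A > 0) * 1
    }
    protein_graph(X, rand_adj(), rand_adj(),
                  labels = labels %||% rbinom(F, 1, 0.5))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent dense-loop GCN layer oracle: s_ij = sum_k sum_l A[i,k] H[k,l] W[l,j]
gcn_layer_oracle <- function(H, A_norm, W, b = NULL, relu_act = TRUE) {
  L <- nrow(H); dout <- ncol(W)
  out <- matrix(0, L, dout)
  for (i in seq_len(L)) {
    for (j in seq_len(dout)) {
      acc <- 0
      for (k in seq_len(L)) {
        for (l in seq_len(ncol(H))) {
          acc <- acc + A_norm[i, k] * H[k, l] * W[l, j]
        }
      }
      if (!is.null(b)) acc <- acc + b[j]
      out[i, j] <- if (relu_act) max(0, acc) else acc
    }
  }
  out
}

# independent forward oracle: plain dense matrix chain, no sparse code shared
# with the implementation
forward_oracle <- function(graph, model) {
  p <- model$par
  nadj <- function(A) {
    Ah <- A + diag(nrow(A))
    d <- rowSums(Ah)
    Ah / sqrt(outer(d, d))
  }
  chan <- function(A, ch) {
    H <- graph$features
    for (k in 1:3) {
      H <- pmax(A %*% H %*% p[[paste0("W", k, "_", ch)]] +
                  matrix(p[[paste0("b", k, "_", ch)]], nrow(H),
                         length(p[[paste0("b", k, "_", ch)]]), byrow = TRUE), 0)
    }
    H
  }
  fmap <- cbind(chan(nadj(graph$adj_evc), "evc"), chan(nadj(graph$adj_rc), "rc"))
  pooled <- colSums(fmap)
  z1 <- pmax(as.numeric(pooled %*% p$W_fc1) + p$b_fc1, 0)
  z2 <- as.numeric(z1 %*% p$W_fc2) + p$b_fc2
  1 / (1 + exp(-z2))
}

# brute-force protein-centric Fmax oracle (independent loop implementation)
fmax_oracle <- function(pred, truth, step = 0.01) {
  best <- 0
  for (t in seq(0, 1, by = step)) {
    ps <- c(); rs <- c()
    for (i in seq_len(nrow(pred))) {
      called <- which(pred[i, ] >= t & pred[i, ] > 0)
      true_set <- which(truth[i, ] == 1)
      if (length(called) > 0) {
        ps <- c(ps, length(intersect(called, true_set)) / length(called))
      }
      if (length(true_set) > 0) {
        rs <- c(rs, length(intersect(called, true_set)) / length(true_set))
      }
    }
    if (length(ps) == 0) next
    p <- mean(ps); r <- mean(rs)
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    best <- max(best, f)
  }
  best
}

# brute-force per-term average precision over all distinct thresholds
aupr_oracle_term <- function(scores, labels) {
  if (sum(labels) == 0) return(NA_real_)
  ts <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  area <- 0
  for (t in ts) {
    called <- scores >= t
    tp <- sum(called & labels == 1)
    p <- tp / sum(called)
    r <- tp / sum(labels)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# rank-statistic AUROC (Mann-Whitney), independent of pROC
auroc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# adjusted Rand index between two hard partitions (vectors of labels)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
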