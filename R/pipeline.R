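#' Run configuration for the command pipeline
#'
#' Collects the thresholds and model settings shared by the pipeline
#' commands. Defaults follow the published settings: EVC and RC edge
#' thresholds 0.2, site-calling cutoff 0.5, dropout 0.3.
#'
#' @param evc_threshold,rc_threshold Edge thresholds in `[0, 1]`.
#' @param site_cutoff Residue site-calling cutoff.
#' @param max_gap_fraction Gap-trimming bound (rows with more gaps are
#'   removed).
#' @param identity_threshold Sequence-reweighting identity threshold.
#' @param lambda Frequency pseudocount.
#' @param hidden,fc_hidden,dropout Model settings.
#' @param featurizer `"randproj"` or `"onehot"`.
#' @param D Feature dimension for `randproj`.
#' @param train Training configuration from [train_config()].
#' @param seed Master seed.
#' @return A list of class `coev_run_config`.
#' @export
run_config <- function(evc_threshold = 0.2, rc_threshold = 0.2,
                       site_cutoff = 0.5, max_gap_fraction = 0.8,
                       identity_threshold = 0.8, lambda = 0.5,
                       hidden = 512, fc_hidden = hidden, dropout = 0.3,
                       featurizer = c("randproj", "onehot"), D = 32,
                       train = train_config(), seed = 1) {
  featurizer <- match.arg(featurizer)
  for (v in c(evc_threshold, rc_threshold, site_cutoff)) {
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]")
  }
  structure(list(evc_threshold = evc_threshold, rc_threshold = rc_threshold,
                 site_cutoff = site_cutoff,
                 max_gap_fraction = max_gap_fraction,
                 identity_threshold = identity_threshold, lambda = lambda,
                 hidden = hidden, fc_hidden = fc_hidden, dropout = dropout,
                 featurizer = featurizer, D = as.integer(D), train = train,
                 seed = as.integer(seed)),
            class = "coev_run_config")
}

#' @keywords internal
write_provenance <- function(path, step, config_list) {
  jsonlite::write_json(
    list(tool = "coevnet", step = step,
         package_version = as.character(utils::packageVersion("coevnet")),
         config = config_list),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Compute evolutionary signatures from an alignment
#'
#' End-to-end statistics stage: read, trim, reweight, frequencies,
#' couplings, normalization, thresholded EVC adjacency, residue
#' communities and RC adjacency, conservation. Writes `trimmed.fasta`,
#' `couplings.tsv`, `evc_adjacency.tsv`, `communities.tsv`,
#' `rc_adjacency.tsv`, `conservation.tsv` and `provenance.json` into
#' `out_dir`. Deterministic given the config seed: re-running is
#' byte-identical.
#'
#' @param msa_path Alignment file path.
#' @param out_dir Output directory (created if missing).
#' @param format `"fasta"` or `"a3m"`.
#' @param config A [run_config()].
#' @return Invisible list with the in-memory results (`msa`, `couplings`,
#'   `evc_adjacency`, `communities`, `rc_adjacency`, `conservation`).
#' @export
run_signatures <- function(msa_path, out_dir, format = c("fasta", "a3m"),
                           config = run_config()) {
  format <- match.arg(format)
  stopifnot(inherits(config, "coev_run_config"))
  msa <- read_msa(msa_path, format = format)
  msa <- trim_msa(msa, max_gap_fraction = config$max_gap_fraction)
  w <- compute_weights(msa, identity_threshold = config$identity_threshold)
  fr <- msa_frequencies(msa, w, lambda = config$lambda)
  C <- normalize_couplings(infer_couplings(fr))
  A_evc <- threshold_adjacency(C, threshold = config$evc_threshold)
  rcs <- detect_communities(C, seed = config$seed)
  A_rc <- rc_adjacency(rcs, threshold = config$rc_threshold)
  cons <- conservation(fr)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_msa(msa, file.path(out_dir, "trimmed.fasta"))
  write_couplings(C, file.path(out_dir, "couplings.tsv"))
  write_adjacency(A_evc, file.path(out_dir, "evc_adjacency.tsv"))
  write_communities(rcs, file.path(out_dir, "communities.tsv"))
  write_adjacency(A_rc, file.path(out_dir, "rc_adjacency.tsv"))
  write_conservation(cons, file.path(out_dir, "conservation.tsv"))
  write_provenance(file.path(out_dir, "provenance.json"), "signatures",
                   list(msa = basename(msa_path), format = format,
                        max_gap_fraction = config$max_gap_fraction,
                        identity_threshold = config$identity_threshold,
                        lambda = config$lambda,
                        evc_threshold = config$evc_threshold,
                        rc_threshold = config$rc_threshold,
                        seed = config$seed))
  invisible(list(msa = msa, couplings = C, evc_adjacency = A_evc,
                 communities = rcs, rc_adjacency = A_rc,
                 conservation = cons))
}

#' Simulate a labelled protein dataset to disk
#'
#' Writes a dataset directory: `manifest.tsv` (protein_id, sequence,
#' labels comma-separated, split), `vocabulary.txt`, `sites.tsv` (ground
#' truth functional residues per label), per-protein edge lists under
#' `edges/`, and `dataset.json` (generator settings incl. the feature
#' seed needed to reproduce node features).
#'
#' @param out_dir Output directory.
#' @param spec A [function_spec()].
#' @return Invisible result of [generate_function_dataset()].
#' @export
run_simulate <- function(out_dir, spec = function_spec(n_proteins = 200)) {
  gen <- generate_function_dataset(spec)
  ds <- gen$dataset
  dir.create(file.path(out_dir, "edges"), recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(
    protein_id = vapply(ds$proteins, function(g) g$id, character(1)),
    sequence = vapply(ds$proteins, function(g) g$sequence, character(1)),
    labels = vapply(ds$proteins, function(g)
      paste(ds$vocabulary[g$labels == 1], collapse = ","), character(1)),
    split = ds$split)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  writeLines(ds$vocabulary, file.path(out_dir, "vocabulary.txt"))
  readr::write_tsv(gen$sites, file.path(out_dir, "sites.tsv"))
  for (g in ds$proteins) {
    write_adjacency(g$adj_evc, file.path(out_dir, "edges",
                                         paste0(g$id, "_evc.tsv")))
    write_adjacency(g$adj_rc, file.path(out_dir, "edges",
                                        paste0(g$id, "_rc.tsv")))
  }
  write_provenance(file.path(out_dir, "dataset.json"), "simulate",
                   list(n_proteins = spec$n_proteins, L = spec$L,
                        n_labels = spec$n_labels, D = spec$D,
                        noise_rate = spec$noise_rate,
                        bg_edge_prob = spec$bg_edge_prob,
                        signal_amplitude = spec$signal_amplitude,
                        feature_seed = gen$feature_seed,
                        signature_seed = gen$signature_seed,
                        motifs = lapply(gen$motifs, function(m)
                          list(pos = m$pos, letters = m$letters)),
                        seed = spec$seed))
  invisible(gen)
}

#' Read a dataset directory written by [run_simulate()]
#'
#' @param dir Dataset directory.
#' @return A [coev_dataset()].
#' @export
read_dataset_dir <- function(dir) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE,
                              na = character())
  vocab <- readLines(file.path(dir, "vocabulary.txt"))
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  D <- meta$config$D
  feature_seed <- meta$config$feature_seed
  motifs <- lapply(meta$config$motifs, function(m)
    data.frame(pos = unlist(m$pos), letters = unlist(m$letters)))
  signatures <- motif_signatures(motifs, D, meta$config$signature_seed)
  amplitude <- meta$config$signal_amplitude
  read_adj <- function(path, L) {
    e <- readr::read_tsv(path, show_col_types = FALSE)
    A <- matrix(0, L, L)
    if (nrow(e) > 0) {
      A[cbind(e$i, e$j)] <- 1
      A[cbind(e$j, e$i)] <- 1
    }
    A
  }
  proteins <- lapply(seq_len(nrow(manifest)), function(r) {
    seqc <- manifest$sequence[r]
    L <- nchar(seqc)
    lab_ids <- strsplit(manifest$labels[r], ",", fixed = TRUE)[[1]]
    protein_graph(
      features = dataset_features(seqc, D = D, feature_seed = feature_seed,
                                  motifs = motifs, signatures = signatures,
                                  amplitude = amplitude),
      adj_evc = read_adj(file.path(dir, "edges",
                                   paste0(manifest$protein_id[r], "_evc.tsv")), L),
      adj_rc = read_adj(file.path(dir, "edges",
                                  paste0(manifest$protein_id[r], "_rc.tsv")), L),
      labels = as.integer(vocab %in% lab_ids),
      id = manifest$protein_id[r], sequence = seqc)
  })
  coev_dataset(proteins, vocab, manifest$split)
}

#' Train a model on a simulated dataset directory
#'
#' @param data_dir Dataset directory from [run_simulate()].
#' @param out_dir Output directory for `model.json` and
#'   `training_log.tsv`.
#' @param config A [run_config()]; its `train` element drives the
#'   optimizer.
#' @return Invisible `coev_fit`.
#' @export
run_train <- function(data_dir, out_dir, config = run_config(hidden = 32)) {
  ds <- read_dataset_dir(data_dir)
  fit <- train_dual_gcn(ds, hidden = config$hidden,
                        fc_hidden = config$fc_hidden,
                        dropout = config$dropout, config = config$train)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_model(fit, file.path(out_dir, "model.json"))
  readr::write_tsv(fit$log, file.path(out_dir, "training_log.tsv"))
  invisible(fit)
}

#' Predict annotations for a dataset directory
#'
#' @param data_dir Dataset directory.
#' @param model_path Path to a `model.json` from [run_train()].
#' @param out_path Output TSV (protein_id, term_id, score).
#' @param split Which split to score (default `"test"`; `NULL` = all).
#' @return Invisible tibble of predictions.
#' @export
run_predict <- function(data_dir, model_path, out_path, split = "test") {
  ds <- read_dataset_dir(data_dir)
  model <- read_model(model_path)
  probs <- predict_graphs(model, ds, split = split)
  out <- tibble::tibble(
    protein_id = rep(rownames(probs), times = ncol(probs)),
    term_id = rep(colnames(probs), each = nrow(probs)),
    score = as.vector(probs))
  readr::write_tsv(out, out_path)
  invisible(out)
}

#' Residue-level site profiles for a dataset directory
#'
#' Writes one TSV per (protein, predicted class) pair whose prediction
#' probability reaches `min_prob`.
#'
#' @param data_dir Dataset directory.
#' @param model_path Path to `model.json`.
#' @param out_dir Output directory for profile TSVs.
#' @param split Which split (default `"test"`).
#' @param min_prob Minimum class probability for writing a profile
#'   (default 0.5).
#' @param cutoff Site-calling cutoff (default 0.5).
#' @return Invisible tibble listing the files written.
#' @export
run_sites <- function(data_dir, model_path, out_dir, split = "test",
                      min_prob = 0.5, cutoff = 0.5) {
  ds <- read_dataset_dir(data_dir)
  model <- read_model(model_path)
  idx <- if (is.null(split)) seq_along(ds$proteins) else
    which(ds$split == split)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in idx) {
    g <- ds$proteins[[i]]
    probs <- forward_dual_gcn(g, model)$probabilities
    for (c in which(probs >= min_prob)) {
      prof <- activation_scores(model, g, c)
      f <- file.path(out_dir, sprintf("%s_%s.tsv", g$id,
                                      gsub("[^A-Za-z0-9]", "_",
                                           ds$vocabulary[c])))
      write_profile(prof, f, sequence = g$sequence, cutoff = cutoff)
      rows[[length(rows) + 1]] <- tibble::tibble(
        protein_id = g$id, term_id = ds$vocabulary[c], file = f)
    }
  }
  invisible(dplyr::bind_rows(rows))
}

#' Evaluate predictions against a dataset directory
#'
#' Reads a prediction TSV from [run_predict()], assembles the evaluation
#' set from the dataset's truth labels, and writes a JSON report with
#' protein-centric Fmax, term-centric AUPR (macro and micro) and MCC.
#' The report header records that no ontology-graph propagation of terms
#' is performed before scoring.
#'
#' @param data_dir Dataset directory.
#' @param predictions_path Prediction TSV.
#' @param out_path Output JSON report path.
#' @param split Which split the predictions cover (default `"test"`).
#' @return Invisible list with the report contents.
#' @export
run_eval <- function(data_dir, predictions_path, out_path, split = "test") {
  ds <- read_dataset_dir(data_dir)
  preds <- readr::read_tsv(predictions_path, show_col_types = FALSE)
  idx <- if (is.null(split)) seq_along(ds$proteins) else
    which(ds$split == split)
  ids <- vapply(ds$proteins[idx], function(g) g$id, character(1))
  mat <- matrix(0, length(ids), length(ds$vocabulary),
                dimnames = list(ids, ds$vocabulary))
  keep <- preds$protein_id %in% ids & preds$term_id %in% ds$vocabulary
  preds <- preds[keep, ]
  mat[cbind(preds$protein_id, preds$term_id)] <- preds$score
  truth <- dataset_labels(ds, idx)
  ev <- evaluation_set(mat, truth, vocabulary = ds$vocabulary)
  fm <- fmax(ev)
  report <- list(
    note = "scores compare raw term assignments; no ontology propagation applied",
    n_proteins = length(ids), n_terms = length(ds$vocabulary),
    fmax = fm$fmax, fmax_threshold = fm$threshold,
    precision = fm$precision, recall = fm$recall,
    aupr_macro = aupr(ev)$aupr, aupr_micro = aupr(ev, "micro")$aupr,
    mcc = mcc_score(ev))
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
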