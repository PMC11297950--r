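# coevnet

Protein function annotation from sequence alone, for computational
biologists who have an alignment but no structure. coevnet combines two
levels of evolutionary statistics with graph deep learning:

1. **Evolutionary couplings (EVCs).** From a multiple sequence alignment,
   residue–residue couplings are inferred by regularized mean-field direct
   coupling analysis: connected correlations over 21 states (20 amino acids
   + gap), couplings `e = -C^{-1}`, zero-sum gauge, Frobenius-norm pair
   scores, average-product correction. Normalized scores ≥ 0.2 become the
   edges of the first graph channel.
2. **Residue communities (RCs).** Spectral analysis of the coupling matrix
   (eigenvalues above a permutation-null threshold, varimax-rotated
   eigenvectors, loading-based membership) groups strongly coupled residues
   into communities; co-membership with strength ≥ 0.2 defines the second
   channel.
3. **Dual-channel GCN.** Per-residue features (one-hot, seeded random
   projection, or an external language-model embedding of width 1280) pass
   through three graph-convolution layers per channel,
   `H' = σ(D̂^{-1/2}(A+I)D̂^{-1/2} H W)`, the channels are concatenated,
   sum-pooled over residues, and two fully connected layers emit per-class
   sigmoid probabilities for multi-label EC/GO-style annotation. Training
   minimizes the multi-label cross-entropy (mean over proteins, sum over
   classes) with Adam (lr 2e-4, weight decay 2e-5, batch 64, ≤500 epochs,
   early stopping), implemented with hand-derived backpropagation over
   block-diagonal sparse batches.
4. **Residue-level attribution.** Gradient-weighted class activation maps
   over the concatenated channel feature map score every residue's
   importance for a predicted function, `S_i = ReLU(Σ_k α_k F_ik)` with
   `α_k = (1/L) Σ_i ∂Y^c/∂F_ik`; residues with normalized scores ≥ 0.5 are
   called functional sites.

Evaluation follows CAFA practice: protein-centric Fmax, term-centric AUPR,
MCC, bootstrap summaries, identity-stratified robustness. Seeded synthetic
generators (alignments with planted covarying pairs; labelled proteins with
planted functional residues) make the whole pipeline testable offline.

## Worked example

```r
library(coevnet)

# synthetic alignment with two planted covarying pairs
msa <- generate_msa(msa_spec(L = 40, M = 1500, seed = 101,
                             planted_pairs = data.frame(i = c(5, 20),
                                                        j = c(12, 33),
                                                        rho = 0.95)))
msa <- trim_msa(msa)                      # drop rows with >80% gaps
w   <- compute_weights(msa)               # redundancy reweighting
fr  <- msa_frequencies(msa, w)            # pseudocount frequencies
C   <- normalize_couplings(infer_couplings(fr))
head(tidy(C), 3)
#> # A tibble: 3 × 3
#>       i     j  score
#>   <int> <int>  <dbl>
#> 1     5    12 1
#> 2    20    33 0.963
#> 3    15    37 0.0143
```

The two planted pairs are the top two couplings, with scores an order of
magnitude above the background; `threshold_adjacency(C, 0.2)` keeps exactly
such pairs as graph edges. Communities and conservation come from
`detect_communities(C)` and `conservation(fr)`; `run_signatures()` runs the
whole statistics stage on an alignment file and writes TSV/JSON artifacts.

End-to-end on a synthetic function dataset:

```r
gen <- generate_function_dataset(function_spec(n_proteins = 1000, seed = 3))
fit <- train_dual_gcn(gen$dataset, hidden = 32,
                      config = train_config(seed = 5))
probs <- predict(fit, gen$dataset, split = "test")
truth <- do.call(rbind, lapply(
  gen$dataset$proteins[gen$dataset$split == "test"], `[[`, "labels"))
ev <- evaluation_set(probs, truth, vocabulary = gen$dataset$vocabulary)
fmax(ev)
#> # A tibble: 1 × 4
#>    fmax threshold precision recall
#>   <dbl>     <dbl>     <dbl>  <dbl>
#> 1     1      0.09         1      1
```

Held-out Fmax reaches 1.0 on this noiseless task (AUPR 1.0 and MCC 1.0 in
the same run). Residue attribution recovers the planted functional sites;
for a held-out protein, the residues called at the 0.5 cutoff are exactly
the designated sites of its function label:

```r
g <- gen$dataset$proteins[[901]]               # a held-out protein
prof <- activation_scores(fit, g, which(g$labels == 1)[1])
call_functional_sites(prof)                    # residues with score >= 0.5
#> [1]  8 31 43
ref <- gen$sites$position[gen$sites$label ==
                            gen$dataset$vocabulary[which(g$labels == 1)[1]]]
site_agreement(prof, ref)
#> # A tibble: 1 × 5
#>   auroc precision recall n_called n_reference
#>   <dbl>     <dbl>  <dbl>    <int>       <int>
#> 1     1         1      1        3           3
```

A thin command-line front end over these functions ships in
`inst/cli/coevnet.R` with subcommands `signatures`, `simulate`, `train`,
`predict`, `sites`, and `eval`.

## Package layout

- `R/` — msa I/O and statistics, coupling inference, communities,
  featurizers, the GCN and its training loop, Grad-CAM attribution,
  metrics, synthetic generators, pipeline commands.
- `tests/testthat/` — unit, property and acceptance suites (oracle
  implementations live in `helper-fixtures.R`).
- `vignettes/coevnet-methods.Rmd` — model, assumptions, and design
  decisions.
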