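---
title: "Statistics-informed graph networks for protein function annotation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistics-informed graph networks for protein function annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevnet)
```

coevnet annotates protein function from sequence alone. The pipeline has
three stages: (1) evolutionary statistics — from a multiple sequence
alignment it infers residue–residue evolutionary couplings and groups
strongly coupled residues into communities; (2) a dual-channel stacked
graph convolutional network (GCN) that reads per-residue features over the
two derived graphs and emits multi-label function probabilities (EC- or
GO-style); (3) residue-level attribution by gradient-weighted class
activation maps, turning a protein-level prediction into a per-residue
functional-importance profile. This vignette records the model, its
assumptions, and every numerically consequential design choice.

## Evolutionary statistics

**Alignment preprocessing.** Rows whose gap fraction strictly exceeds 0.8
are removed (a row at exactly 80% gaps is kept); the query row is always
retained so that coupling indices cover the full target sequence. Sequences
are reweighted by the standard redundancy correction: weight
$w_s = 1/|\{t : \mathrm{id}(s,t) \ge 0.8\}|$. The 80% identity threshold is
a package default, exposed in `run_config()`.

**Frequencies.** Single-site and pairwise frequencies are computed over
$q = 21$ states (20 amino acids plus gap — keeping the gap as a state
stabilizes the inversion below) with a pseudocount mixture
$f = \lambda/q + (1-\lambda)\,\hat f$ and $\lambda = 0.5$, the usual
mean-field choice. Unknown residues (`X`) contribute $1/20$ fractional
counts to each amino-acid state so they cannot generate spurious couplings.

**Couplings.** `infer_couplings()` is a mean-field direct coupling
analysis: the connected-correlation matrix
$C_{ij}(a,b) = f_{ij}(a,b) - f_i(a) f_j(b)$ is assembled over the first 20
states (the gap state is excluded from scoring to avoid gap-driven
couplings), couplings are $e = -C^{-1}$, each pair block is moved to the
zero-sum gauge, scored by its Frobenius norm, and background-corrected with
the average-product correction (APC),
$s_{ij} \leftarrow s_{ij} - s_{i\cdot} s_{\cdot j} / s_{\cdot\cdot}$,
clipping negatives at zero. Mean-field inversion was chosen over
pseudo-likelihood because it is deterministic, fast at desk scale, and
well characterized; the estimator sits behind a single function so an
alternative can be swapped in. Scores are normalized per protein by the
maximum off-diagonal entry (whether normalization should instead be global
is undocumented upstream; per-protein is the conservative choice and is
flagged in the object). Edges enter the EVC channel when the normalized
score is $\ge 0.2$; boundary cases use $\ge$ throughout the package,
matching the $\ge 0.5$ residue-site convention.

**Residue communities.** `detect_communities()` eigendecomposes the
normalized coupling matrix and must decide (a) how many eigenvectors carry
structure and (b) which residues belong to each community.

* *Eigenvalue threshold.* We compare against permutation nulls: each null
  shuffles every column of the matrix and re-symmetrizes, preserving the
  score distribution while destroying structure. The threshold is the
  largest **second** eigenvalue across 20 seeded nulls. The null's leading
  eigenvalue is deliberately ignored: for a nonnegative matrix it is a
  Perron mode that tracks mean coupling density, and it is present whether
  or not communities exist. (Using the nulls' leading eigenvalue would make
  detection impossible precisely in the strongest case — e.g. two dense
  blocks tiling the matrix, where the block eigenvalue equals the average
  degree and therefore equals the null's Perron eigenvalue.)
* *Rotation.* Retained eigenvectors are varimax-rotated before assignment.
  Equal-sized blocks produce degenerate eigenvalues whose eigenbasis is
  arbitrary up to rotation; varimax localizes the basis, in the same
  spirit as the rotation/ICA step of statistical coupling analysis.
* *Membership.* Residue $i$ joins the community of its largest absolute
  loading provided that loading is at least $1/\sqrt{L}$ — the RMS loading
  of a flat eigenvector. A stricter $2/\sqrt{L}$ cutoff was considered and
  rejected: it silently forbids communities larger than $L/4$ residues
  (a uniform block of $s$ residues has loadings $1/\sqrt{s}$), which
  contradicts the intended behavior on block-structured matrices.
  The cutoff is exposed as `loading_cutoff`.
* Membership strength is the loading normalized by the community's largest
  loading; communities with fewer than two members are dropped; assignment
  is hard (one community per residue), with the rotation making the
  degenerate-block case deterministic in practice.

The RC channel connects two residues when they share a community and both
strengths are $\ge 0.2$.

## The dual-channel GCN

Node features are an $L \times D$ matrix: one-hot letters, seeded
random-projection letter embeddings, or an externally computed embedding
loaded from a plain text matrix (a pretrained protein language model is
the intended source at $D = 1280$; the package deliberately does not bundle
one, and synthetic experiments use $D = 32$).

Each channel applies three GCN layers
$H^{(k+1)} = \sigma(\hat D^{-1/2} \hat A \hat D^{-1/2} H^{(k)} W^{(k)} + b^{(k)})$
with $\hat A = A + I$; channel 1 propagates over the EVC adjacency,
channel 2 over the RC adjacency, with fully independent weights (nothing
suggests sharing). The two $L \times h$ outputs are concatenated into the
residue-resolved feature map (retained for attribution), sum-pooled over
residues, passed through one ReLU fully connected layer, dropout 0.3, a
second fully connected layer, and a per-class sigmoid. The hidden width
defaults to 512; desk-scale experiments here use 32.

Two documented choices:

* **Sigmoid, not softmax.** The training loss is a multi-label binary
  cross-entropy (mean over proteins, sum over classes) and EC/GO
  assignment is inherently multi-label, so the output nonlinearity is a
  per-class sigmoid; a `softmax` flag exists for the single-label variant.
* **ReLU** is used for all hidden activations (unspecified upstream; it is
  also what the attribution step assumes), and biases are included on all
  layers, initialized at zero; weights are seeded Glorot-uniform.

**Training.** Adam (lr $2\times10^{-4}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-6}$) with decoupled L2 weight decay
$2\times10^{-5}$ applied to weight matrices only, batch size 64, at most
500 epochs, early stopping on validation loss with patience 20 (patience is
a package default; only the existence of early stopping is prescribed).
Gradients are computed by hand-derived backpropagation through the exact
forward graph; proteins in a batch are stacked into one block-diagonal
sparse graph, which makes the per-epoch cost linear in the corpus size.
Training is bitwise reproducible given the seed. Note that the stated
learning rate is calibrated against a ~42k-protein corpus; on the small
synthetic corpora used in tests the same settings simply take more epochs,
and test fixtures that only probe convergence mechanics scale the rate up
in proportion.

## Residue-level attribution

For class $c$, the neuron weights are
$\alpha_k = \tfrac1L \sum_i \partial Y^c / \partial F^k_i$ — because the
pooling is a sum, this equals the gradient with respect to the pooled
feature, computed in closed form through the head. Raw scores are
$\mathrm{ReLU}(\sum_k \alpha_k F^k_i)$, normalized per protein to
$[0, 1]$ by the maximum (the normalization scope is a package choice; the
0.5 site-calling cutoff operates on the normalized profile). The gradient
is taken on the post-sigmoid probability by default (`target = "logit"`
switches). The feature map is taken at the channel-concatenation layer —
the only residue-resolved layer after the channels merge.

## Evaluation

`fmax()` is the protein-centric maximum F-score over a 0.01 threshold
grid; precision averages only over proteins with at least one prediction
at the threshold (CAFA convention), recall over all proteins with a true
label, and a score of exactly zero is never counted as a prediction (so an
all-zero predictor scores 0). `aupr()` is the term-centric area under the
precision–recall curve by descending-score sweep with step interpolation,
macro-averaged over terms with at least one positive (micro pooling
available); the printed-formula variant $\int p(t) r(t)\,dt$ is retained
behind `integral = "literal"` for comparison but is not the standard PR
area and is not the default. `mcc_score()` pools confusion counts over all
(protein, term) pairs at a 0.5 cutoff. Bootstrap summaries resample
proteins with replacement (10 or 50 replicates in the reported
experiments); identity-stratified evaluation filters proteins by maximum
identity to the training set at the 30/40/50/70/95% ladder. No
ontology-graph propagation of terms is performed before scoring, and every
report says so in its header.

## Synthetic data: what it emulates and what it does not

`generate_msa()` samples alignment rows column-independently from
Dirichlet-drawn backgrounds, plants covarying column pairs via a bijective
letter map applied with probability $\rho$ (giving analytically
controllable mutual information without a Potts sampler), supports
conserved columns and i.i.d. gaps. It deliberately does **not** simulate
phylogenetic correlation between rows, so sequence reweighting is exercised
only lightly by the tests.

`generate_function_dataset()` builds labelled proteins for end-to-end
tests: uniform sequences; per-label motif rules (by default three
designated positions sharing one allowed-letter set of 13, prevalence
$\approx (13/20)^3 \approx 0.27$); the label is the rule indicator, flipped
at the annotation-noise rate. Both channel adjacencies contain each label's
motif positions as a planted clique plus sparse background edges
(probability 0.01 per pair), so community structure marks the functional
residues. Node features are position-independent letter embeddings
**plus a contextual motif signature**: when a protein satisfies a label's
rule, a fixed per-(label, position) signature vector (amplitude 1, the
scale of the letter features) is added at that label's motif residues.

The signature deserves justification, because it is the one place where
the generator does more than the obvious. With position-independent
letter features and anonymous background edges, the task "which residues
caused the label" is formally unidentifiable for any
permutation-equivariant network with sum pooling: a background edge (or
triangle) whose letters happen to fall in the motif's allowed set is
*isomorphic* to the true motif, and we verified empirically that training
under those conditions plateaus at base-rate predictions across two orders
of magnitude of learning rate. Real pipelines do not face this problem
because contextual language-model embeddings differ at functional
constellations — that is precisely the premise for using them. The
additive signature reproduces that property in the minimal way, while
keeping labels letter-caused and letting annotation noise flip labels
without touching features. Consequently the end-to-end tests validate the
optimization loop, the dual-channel propagation and the attribution
machinery against a known ground truth — they do not (and cannot) show
that sum-pooled GCNs localize functional sites from position-free letter
features alone, and they say nothing about performance on real proteins.

`generate_metric_fixture()` produces Bernoulli(0.2) truths with
predictions interpolating between truth and uniform noise, for metric
calibration tests.

## Problem sizes and numerical choices

Deterministic equation-level tests run on 2–10-node graphs against dense
loop oracles (tolerances $10^{-6}$/$10^{-5}$; attribution gradients are
checked against central finite differences at relative error $10^{-3}$).
Coupling-recovery experiments use $L = 50$, $M = 2000$, five planted pairs
at $\rho = 0.9$ over 20 seeds. The end-to-end experiment uses the
$n = 2000$, $L = 60$, $D = 32$, $h = 32$, $F = 4$ noiseless task for
held-out Fmax, with the epoch budget capped at 300 (validation loss
converges near epoch 250–310 at these sizes); the attribution-recovery
distribution comes from ten independent replicate trainings at $n = 500$
with batch size 16 and 100 epochs — on a corpus 1/80th the size of the
one the published learning rate was tuned for, the smaller batch keeps
per-epoch optimizer work comparable. These sizes are the package's
choice of experiment scale. Degenerate inputs are handled explicitly:
all-zero coupling matrices normalize to themselves and yield zero
communities; empty community sets yield empty adjacencies; an all-zero
attribution profile stays all-zero rather than being rescaled; a zero
denominator in MCC returns 0; bootstrap replicates whose resample has no
positive label are dropped from the summary.

## Known limitations

* The community construction (spectral + permutation null + varimax) is a
  documented substitute for an upstream tool whose internals are not
  public; it is isolated behind `detect_communities()` for replacement.
* Mean-field DCA degrades on shallow or highly redundant alignments; the
  pseudocount guards invertibility but not estimation quality.
* No GO-hierarchy propagation, no semantic-similarity metrics.
* The CLI covers simulation-backed workflows end to end; training on real
  corpora expects the user to assemble the dataset directory (or call the
  R functions directly with their own `protein_graph` objects).
* Pure-R training is practical to a few thousand proteins at $L \le 100$;
  beyond that, expect minutes-per-epoch.
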