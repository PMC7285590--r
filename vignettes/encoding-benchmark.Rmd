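---
title: "Benchmarking amino-acid encodings: models, generators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking amino-acid encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

How much of a sequence model's performance comes from the *information
content* of its amino-acid encoding (the geometry relating residues to one
another) versus mere *distinguishability* (each residue having a unique
vector)? `aabench` compares five encoding families on two tasks:

* **Classical, frozen**: one-hot (20-d), a frequency-normalized BLOSUM62
  (20-d), and the VHSE8 physicochemical descriptors (8-d).
* **Learned**: a trainable embedding matrix, initialized uniformly on
  $[-0.05, 0.05]$ and updated by backpropagation with the rest of the model.
* **Random frozen**: the same initialization, never updated — the control
  that supplies distinguishability with deliberately arbitrary geometry.

Every encoding is a $21 \times d$ matrix: row 0 is the padding token, rows
1–20 the amino acids in alphabetical one-letter order. The padding row is
all zeros for the classical schemes (padding carries no signal) but is a
real, analyzable vector for the random/learned schemes, and it is included
in all embedding-space analyses.

# Models

Three reference architectures, implemented from scratch in C++
(RcppArmadillo) because no deep-learning framework is available in the
target environment; all gradients are verified against finite differences
in the test suite.

* **LSTM affinity model** — embedding → 12-unit LSTM → 1 sigmoid unit.
  Mean absolute error, Adam, batch 256, input length 26.
* **CNN-LSTM affinity model** — as above with a convolution (36 filters,
  width 9, stride 1, ReLU) between embedding and LSTM. A width-9 kernel
  over a length-26 input yields 18 positions.
* **Siamese pair model** — two weight-sharing convolutional encoders (four
  modules of conv → ReLU → batch norm → average pooling, the fourth with
  global average pooling) feeding an MLP head with one sigmoid unit;
  binary cross-entropy, Adam, batch 1024, input length 1000.

Choices the cited architectures leave open, fixed here and configurable:

* Per-module Siamese filters/kernels are not printed in the source's main
  text; defaults are 32/64/128/256 filters, kernels 9/7/5/5, pool width 3.
* The pair head default concatenates the two branch vectors through one
  128-unit ReLU layer. A `combiner = "symmetric"` option (element-wise
  product + absolute difference) guarantees exact invariance to input
  order; concatenation stays the default to remain close to the cited
  design, and the symmetry test runs under the symmetric combiner.
* Adam uses its canonical defaults (learning rate $10^{-3}$, $\beta_1 =
  0.9$, $\beta_2 = 0.999$); none are stated in the source.
* Non-embedding weights are Glorot-uniform; LSTM forget-gate bias is 1.
* Padding tokens are **not** masked from the recurrent/convolutional
  layers, consistent with treating the padding vector as a real row.
* Validation for the affinity task uses a seeded 5-fold assignment; the
  desk profile trains against fold 1 only (single split) to fit the CPU
  budget. Per-fold and averaged summaries are both derivable from the
  tidy histories.

# The BLOSUM62 "frequency normalized" form

The classical BLOSUM62 scores are rounded half-bit log-odds
$s_{ab} = \mathrm{round}\,2\log_2\!\frac{q_{ab}}{p_a p_b}$ of target
substitution frequencies $q$ against backgrounds $p$. The encoding wants
the row-stochastic conditionals $P(b\,|\,a) = q_{ab}/p_a$. Since the $q$
table itself is not shipped anywhere in the offline environment, we recover
$(p, \lambda)$ from the score matrix (from Biostrings) by solving the
consistency system

$$\sum_b p_b e^{\lambda s_{ab}} = 1 \ \ \forall a, \qquad \sum_a p_a = 1$$

with Newton's method (machine precision in ~5 iterations, $\lambda \approx
0.324$), then set $P(b\,|\,a) = p_b e^{\lambda s_{ab}}$. Rows sum to 1
exactly by construction; the implied unrounded scores agree with the
integer matrix to within the rounding half-unit (asserted in the tests);
the recovered backgrounds match published BLOSUM62 frequencies to rounding
error. This is a documented stand-in, not a byte-match of any particular
software package's table.

# What the synthetic generators emulate — and what they don't

The benchmark's empirical datasets (measured peptide affinities; curated
binary interaction pairs) cannot be redistributed, so both tasks run on
seeded generators whose *statistical structure* matches what the analyses
need, with all rates stated up front.

**Peptide affinity.** Peptides of length 13–25, residues drawn by a
group-biased composition (group uniform over the six physicochemical
groups, residue uniform within group). Ground truth: the best (max over
contiguous 9-mer windows) mean positional group weight, squashed with a
logistic (slope 8, midpoint 0.24); observed affinity adds
$\mathcal{N}(0, 0.05)$ noise, clipped to $[0,1]$ — targets must stay in
the sigmoid output range. The default weight table is *position-smooth*:
every position ranks the groups identically (aromatic 1.0 > hydrophobic
0.6 > neutral polar 0.2 > basic −0.4 > special −0.6 > acidic −0.8),
terminal positions slightly stronger. Two calibration facts, fixed before
any acceptance measurement: the positive fraction at the 0.426 binder
threshold is ≈0.51 (Monte-Carlo), and a 12-unit LSTM with one-hot encoding
reaches validation AUC > 0.94 on noiseless data within 25 epochs. An
earlier draft with strongly position-specific anchor weights was *not*
learnable by these small models at desk scale (AUC plateau ≈0.69) and was
replaced — the task's difficulty is a design parameter here, and the
published phenomena only reproduce when the models can actually learn the
signal. Affinity depending on physicochemical groups is also what makes
the embedding-space clustering analysis testable.

**Protein pairs.** Proteins of uniform random length (100–1000 over a
uniform residue background) carry 1–3 verbatim-embedded motifs from a
library with a perfect-matching compatibility map; a pair interacts iff it
carries a compatible motif pair. Near-duplicate "homologs" (per-residue
point mutation) exercise the identity filter. Negatives are sampled
uniformly from non-interacting pairs — the pipeline excludes *all*
compatible pairs from the negative pool, not only the emitted positives,
so `label_noise = 0` really yields noiseless labels and a substring +
lookup classifier is Bayes-optimal with accuracy 1.

**Not emulated**: HLA pocket energetics, multi-allele structure,
real homology (the blastp identity filter is replaced by a shared-5-mer
fraction with the same 40% threshold — monotone in identity, deterministic,
desk-scale), realistic interaction network topology. A green test
establishes that the *pipeline reproduces the qualitative phenomena on data
with the stated structure*, not that it would match any published AUC on
the real datasets.

# Numerical and procedural choices

* **IC50 normalization**: $1 - \log(\mathrm{IC50})/\log(50000)$, clipped to
  $[0,1]$ — the convention that maps 500 nM to 0.426 at three decimals.
  Note 0.426 is a rounded threshold: it sits at 498.05 nM exactly, so IC50
  in (498.05, 500) nM classifies as non-binder. Ties at the threshold
  count as binders (`>=`).
* **Padding side**: head (leading zeros); over-long peptides keep their
  last 26 tokens (head-end trimming). Both operations are idempotent.
* **Train/test split**: protein-level, $\lceil 0.9n \rceil$ training;
  homology filtering removes test proteins with shared-5-mer identity
  strictly above 0.40 to any training protein.
* **AUC**: Mann–Whitney with midranks; exactly equals brute-force pair
  counting (tested on 200 random instances).
* **Repetition summaries**: sample (n−1) standard deviation.
* **Clustering**: average linkage on Euclidean distances; `hclust`'s
  first-index tie-breaking makes leaf orders deterministic. Dendrogram
  structure is comparable across encodings but not leaf-for-leaf identical
  to any published heat-map ordering.
* **Group cohesion test**: statistic = mean between-group − mean
  within-group distance over the 20 amino-acid rows (padding excluded —
  it has no group); one-sided permutation p with +1 smoothing. Calibration
  is verified by Monte-Carlo under the null in the test suite.
* **Per-cell grid seeds**: a stable 31-bit polynomial hash of (base seed,
  cell coordinates), so cells are independent and individually
  reproducible; grid runs are resumable from a manifest and re-running an
  interrupted grid yields the identical table.
* **"Best" AUC** for scheme comparisons is the maximum validation AUC over
  epochs, since schemes reach their maxima at different times.

# Desk-scale profiles

The reference runs (3000 epochs affinity / 50 epochs pairs, batch 1024,
GPU) are far beyond a 1-CPU test budget. The shipped defaults and tests
use documented scaled-down profiles: 2000 peptides / 60-epoch runs for the
affinity experiments; 400 proteins of length 100–300 (padded to 300) /
2000 pairs / small filter counts for pair-task integration tests. Epoch
counts and sizes are configuration, not constants; the full-scale settings
remain the config defaults (`lstm_config()`, `siamese_config()`).

# Known limitations

* Determinism is guaranteed per platform (one BLAS, one libstdc++), not
  bitwise across platforms.
* The Adam state does not persist across separate `train_model()` calls.
* The Siamese batch-norm normalizes the two stacked branches jointly
  during training; inference uses running statistics and is per-sample
  deterministic.
* `run_grid()` keeps one prepared dataset in memory; grids over very large
  synthetic worlds should shard by config.
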