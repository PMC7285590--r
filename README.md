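# aabench

Benchmarking amino-acid encoding schemes for sequence-based prediction
models, for computational biologists asking a deceptively simple question:
when a neural network reads protein sequence, how much does the *encoding*
of each residue matter — its information content (the geometry relating
amino acids) versus its mere distinguishability (each residue having a
unique vector)?

The package compares, on equal footing:

| family | schemes | trainable |
|---|---|---|
| classical | one-hot (20-d), frequency-normalized BLOSUM62 (20-d), VHSE8 (8-d) | no |
| learned | embedding matrix, uniform $[-0.05, 0.05]$ init, backprop-updated | yes |
| random frozen | same init, never updated (distinguishability-only control) | no |

across two tasks and three architectures:

* **peptide binding affinity** (HLA class II style regression, targets in
  $[0,1]$): embedding → LSTM(12) → sigmoid, MAE loss; optionally with a
  convolution block (36 filters, width 9, stride 1) before the LSTM;
* **protein–protein interaction** from sequence pairs: a Siamese
  convolutional encoder (four conv → ReLU → batch-norm → average-pool
  modules, global average pooling last) with a shared parameter set and an
  MLP head, binary cross-entropy.

Every encoding is a $21 \times d$ matrix (padding token at row 0, then the
20 amino acids alphabetically). Peptides are tokenized, head-trimmed/padded
to 26; proteins are length-filtered to 100–1000, zero-padded to 1000. IC50
values normalize as $1 - \log(\mathrm{IC50})/\log(50000)$, binarized at the
conventional 0.426 (≙ 500 nM) binder threshold. The PPI pipeline does a
90/10 protein-level split, removes test proteins with >40% shared-5-mer
identity to the training set, and balances negatives 1:1 by uniform
sampling. The networks are implemented in C++ (RcppArmadillo) with Adam;
all gradients are finite-difference-verified in the test suite.

Because the original empirical datasets are external, the package ships
seeded synthetic generators with motif-driven ground truth — peptides
scored by a 9-mer-core physicochemical motif, proteins interacting iff
they carry compatible embedded sequence motifs — so the entire benchmark
(encoding × dimension × architecture × data-fraction grids, plus the
embedding-space distance/clustering analysis) runs end-to-end offline.
See `vignettes/encoding-benchmark.Rmd` for the models, the generator
design and every numerical choice.

## Worked example

Train a 4-dimensional learned embedding on synthetic peptide-affinity data
and ask whether the learnt embedding space organizes amino acids along
physicochemical lines:

```r
library(aabench)

peps <- generate_peptide_dataset(n = 1000, motif = binding_motif(),
                                 noise_sd = 0.05, seed = 7)
head(peps, 3)
#>                    peptide   affinity true_affinity
#> 1   TYHFSEPVEQESECVGYKWHYM 0.54712573     0.5088880
#> 2          CADKRKSVPENGTDV 0.06023916     0.0671628
#> 3 SSEWFVKQQQEWHETLSTPEQGPD 0.75836854     0.7506763

prep  <- prepare_peptides(peps)                      # tokenize, pad/trim to 26
folds <- rep(1:5, length.out = 1000)
train <- prepared_dataset(prep$inputs[folds != 1, ], prep$targets[folds != 1])
val   <- prepared_dataset(prep$inputs[folds == 1, ], prep$targets[folds == 1])

spec  <- embedding_spec("learned", dim = 4, seed = 7)
model <- build_lstm_model(spec, lstm_config(epochs = 40), seed = 7)
fit   <- train_model(model, train, val, epochs = 40, seed = 7)

h <- as.data.frame(fit$history)
max(h$value[h$metric == "val_auc"])
#> best validation AUC over 40 epochs: 0.931

ana <- analyze_embedding(extract_embedding(fit$model),
                         n_permutations = 999, seed = 7)
#> group cohesion: statistic = 0.179, p = 0.001
```

A best validation AUC of 0.931 (labels binarized at 0.426) says the tiny
4-d learned embedding supports nearly the same discrimination as a 20-d
classical encoding on this data. The cohesion statistic (mean
between-group minus mean within-group Euclidean distance over the
physicochemical partition) is positive with permutation p = 0.001: after
training, residues of the same side-chain group really sit closer together
— the model rediscovered chemistry from affinities alone. For reference,
the same analysis on the shipped VHSE8 descriptors gives statistic 1.588
(p = 0.001), and on one-hot exactly 0 (all residues equidistant).

Higher-level drivers reproduce the benchmark's figure-style experiments:
`experiment_fig1()` (learned vs classical curves), `experiment_fig4()`
(random-frozen embeddings across dimensions 1–32), `experiment_fig2()`
(accuracy vs training-data fraction for the Siamese model), and
`run_grid()` for arbitrary seeded, resumable grids. A CLI wraps them:

```sh
Rscript -e 'aabench::bench_cli()' simulate-hla --n 2000 --seed 1 --out-dir out/
Rscript -e 'aabench::bench_cli()' fig4 --dims 1,2,4,8,16,32 --epochs 60 --out-dir out/
```

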