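test_that("tokenize maps residues to indices and reports bad characters", {
  expect_identical(as.integer(tokenize("AAA")), c(1L, 1L, 1L))
  expect_identical(attr(tokenize("ACDY"), "original_length"), 4L)
  expect_error(tokenize("AXA"), "position 2")
  expect_error(tokenize("A-A"), "position 2")  # pad symbol is not a residue
  expect_error(tokenize(""), "non-empty")
  s <- "MKWVTFISLLFLFSSAYS"
  expect_identical(detokenize(tokenize(s)), s)
})

test_that("peptides are left-padded or head-trimmed to exactly 26", {
  t9 <- tokenize(strrep("A", 9))
  out <- pad_trim_peptide(t9)
  expect_length(out, 26L)
  expect_identical(out, c(rep(0L, 17), rep(1L, 9)))
  t30 <- seq_len(30) %% 20 + 1L
  expect_identical(pad_trim_peptide(t30), as.integer(t30[5:30]))
  t26 <- rep(2L, 26)
  expect_identical(pad_trim_peptide(t26), t26)
  expect_identical(pad_trim_peptide(pad_trim_peptide(t9)),
                   pad_trim_peptide(t9))  # idempotent
})

test_that("proteins are zero-padded to exactly 1000, never trimmed", {
  t100 <- rep(3L, 100)
  out <- pad_protein(t100)
  expect_length(out, 1000L)
  expect_identical(out, c(rep(0L, 900), t100))
  t1000 <- rep(4L, 1000)
  expect_identical(pad_protein(t1000), t1000)
  expect_error(pad_protein(rep(1L, 1001)), "length_filter")
})

test_that("IC50 normalization matches the NetMHC convention", {
  expect_equal(round(normalize_ic50(500), 3), 0.426)
  expect_equal(normalize_ic50(1), 1.0)
  expect_equal(normalize_ic50(50000), 0.0)
  expect_error(normalize_ic50(0), "positive")
  x <- normalize_ic50(c(2, 10, 100, 1000, 20000))
  expect_true(all(diff(x) < 0))  # strictly decreasing
  # binarize o normalize: binders below, non-binders above the cut-off.
  # 0.426 is the rounded form of normalize_ic50(500) = 0.42565, so the
  # printed threshold sits at 498.05 nM; test outside that rounding sliver.
  expect_identical(binarize_affinity(normalize_ic50(c(490, 502))),
                   c(1L, 0L))
  expect_identical(binarize_affinity(c(0.426, 0, 1)), c(1L, 0L, 1L))
})

test_that("length filter keeps the inclusive 100..1000 band in order", {
  p <- data.frame(id = paste0("p", 1:5),
                  sequence = strrep("A", c(99, 100, 500, 1000, 1001)))
  kept <- length_filter(p)
  expect_identical(kept$id, c("p2", "p3", "p4"))
  expect_identical(nrow(length_filter(p[0, ])), 0L)
  allpass <- p[2:4, ]
  expect_identical(length_filter(allpass), allpass)
})

test_that("protein split is disjoint, exhaustive, 90/10 and seeded", {
  p <- data.frame(id = sprintf("p%03d", 1:100), sequence = strrep("A", 100))
  sp <- split_proteins(p, 0.9, seed = 1)
  expect_identical(nrow(sp$train), 90L)
  expect_identical(nrow(sp$test), 10L)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  expect_setequal(c(sp$train$id, sp$test$id), p$id)
  expect_identical(split_proteins(p, 0.9, seed = 1), sp)
  expect_false(identical(split_proteins(p, 0.9, seed = 2), sp))
})

test_that("k-mer identity matches hand-enumerated cases", {
  expect_equal(kmer_identity("ACDEFGHIK", "ACDEFGHIK"), 1.0)
  expect_equal(kmer_identity(strrep("A", 20), strrep("C", 20)), 0.0)
  # ABCDEFGH vs ABCDEXYZ, k = 5: shared {ABCDE} of 4 distinct 5-mers each
  expect_equal(kmer_identity("ABCDEFGH", "ABCDEXYZ", k = 5), 0.25)
  expect_equal(kmer_identity("ABCDEFGH", "ABCDEXYZ"),
               kmer_identity("ABCDEXYZ", "ABCDEFGH"))  # symmetric
  expect_error(kmer_identity("ABC", "ABCDE"), "at least k")
})

test_that("homology filter removes copies, keeps independent proteins", {
  set.seed(11)
  rnd <- function(L) paste(sample(aa_residues(), L, TRUE), collapse = "")
  train <- data.frame(id = paste0("t", 1:5),
                      sequence = vapply(rep(500, 5), rnd, character(1)))
  test <- data.frame(id = paste0("q", 1:4),
                     sequence = c(train$sequence[2],
                                  vapply(rep(500, 3), rnd, character(1))))
  out <- homology_filter(test, train)
  expect_identical(out$id, c("q2", "q3", "q4"))  # exact copy removed
  expect_identical(homology_filter(test, train[0, ]), test)
  # subset property and monotonicity in the training set
  more <- rbind(train, data.frame(id = "t6", sequence = test$sequence[3]))
  out2 <- homology_filter(test, more)
  expect_true(all(out2$id %in% out$id))
  expect_lt(nrow(out2), nrow(out))
})

test_that("negative balancing yields an exact 1:1 set without collisions", {
  ids <- sprintf("p%03d", 1:40)
  pos <- data.frame(id_a = ids[1:30], id_b = ids[11:40])
  out <- balance_negatives(pos, ids, seed = 3)
  expect_identical(nrow(out), 60L)
  expect_identical(sum(out$label == 1L), 30L)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  negs <- out[out$label == 0L, ]
  expect_false(any(key(negs$id_a, negs$id_b) %in% key(pos$id_a, pos$id_b)))
  expect_false(anyDuplicated(key(negs$id_a, negs$id_b)) > 0)
  expect_false(any(negs$id_a == negs$id_b))
  # infeasible when the universe is exhausted
  tiny <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"))
  expect_error(balance_negatives(tiny, c("a", "b", "c"), seed = 1),
               "infeasible")
})

test_that("fraction subsetting preserves pairing and seeds", {
  x <- matrix(seq_len(1000 * 4), 1000, 4)
  ds <- prepared_dataset(x, seq_len(1000) / 1000)
  s <- subset_fraction(ds, 0.25, seed = 5)
  expect_length(s, 250L)
  # pairing preserved: row i of inputs still matches target i
  expect_identical(s$inputs[, 1] / 1000, s$targets)
  expect_identical(subset_fraction(ds, 1.0, seed = 9), ds)
  expect_identical(subset_fraction(ds, 0.25, 5)$targets, s$targets)
  expect_error(subset_fraction(ds, 0, 1), "fraction")
  expect_error(subset_fraction(ds, 1.2, 1), "fraction")
})

test_that("prepare_peptides and prepare_pairs build conformant matrices", {
  peps <- generate_peptide_dataset(30, binding_motif(), seed = 2)
  prep <- prepare_peptides(peps)
  expect_identical(dim(prep$inputs), c(30L, 26L))
  expect_identical(prep$targets, peps$affinity)
  lib <- generate_motif_library(2, 8, seed = 1)
  gen <- generate_ppi_dataset(12, c(100L, 150L), lib, 6, 0, seed = 3)
  pp <- prepare_pairs(gen$pairs, gen$proteins, target_length = 150L)
  expect_identical(dim(pp$inputs$a), c(6L, 150L))
  expect_identical(dim(pp$inputs$b), c(6L, 150L))
  bad <- gen$pairs
  bad$id_a[1] <- "nope"
  expect_error(prepare_pairs(bad, gen$proteins, 150L), "unknown protein")
})

test_that("dataset files round-trip through their plain-text formats", {
  tmp <- tempfile(fileext = ".tsv")
  peps <- generate_peptide_dataset(20, binding_motif(), seed = 6)
  write_peptide_dataset(peps, tmp, config = list(n = 20, seed = 6))
  expect_true(startsWith(readLines(tmp, n = 1), "#n=20"))
  back <- read_peptide_dataset(tmp)
  expect_identical(back$peptide, peps$peptide)
  expect_equal(back$affinity, peps$affinity, tolerance = 1e-6)
  lib <- generate_motif_library(2, 8, seed = 1)
  gen <- generate_ppi_dataset(10, c(100L, 150L), lib, 4, 0, seed = 3)
  fa <- tempfile(fileext = ".fasta")
  write_protein_fasta(gen$proteins, fa)
  prot <- read_protein_fasta(fa)
  expect_identical(prot$sequence, gen$proteins$sequence)
  pt <- tempfile(fileext = ".tsv")
  write_pair_dataset(gen$pairs, pt)
  expect_identical(read_pair_dataset(pt), gen$pairs)
})
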