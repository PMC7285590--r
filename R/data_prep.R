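#' Tokenize a residue string
#'
#' Maps each residue to its alphabet index (A = 1 ... Y = 20). The original
#' length is kept as an attribute so padding can be undone for inspection.
#'
#' @param sequence non-empty residue string.
#' @param alphabet the token alphabet, see [aa_alphabet()].
#' @return Integer vector of token indices with attribute `original_length`.
#' @export
tokenize <- function(sequence, alphabet = aa_alphabet()) {
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  idx <- match(res, alphabet) - 1L
  if (anyNA(idx) || any(idx == 0L)) {
    bad <- which(is.na(idx) | idx == 0L)[1]
    stop("unknown residue '", res[bad], "' at position ", bad, call. = FALSE)
  }
  structure(idx, original_length = length(idx))
}

#' @rdname tokenize
#' @param tokens integer token vector.
#' @export
detokenize <- function(tokens, alphabet = aa_alphabet()) {
  paste(alphabet[as.integer(tokens) + 1L][tokens != 0L], collapse = "")
}

#' Pad or trim a peptide to the fixed model length
#'
#' Shorter peptides are left-padded with the padding token 0; longer ones
#' are trimmed from the head end, keeping the last `target_length` tokens.
#'
#' @param tokens integer token vector.
#' @param target_length fixed length, default 26.
#' @return Integer vector of length `target_length`.
#' @export
pad_trim_peptide <- function(tokens, target_length = 26L) {
  tokens <- as.integer(tokens)
  n <- length(tokens)
  if (n == 0L) stop("empty token list", call. = FALSE)
  if (n >= target_length) {
    tokens[(n - target_length + 1L):n]
  } else {
    c(rep(0L, target_length - n), tokens)
  }
}

#' Zero-pad a protein to the fixed model length
#'
#' Left-pads with token 0 up to `target_length`. Longer inputs are an error:
#' over-long proteins must have been removed upstream by [length_filter()].
#'
#' @inheritParams pad_trim_peptide
#' @param target_length fixed length, default 1000.
#' @export
pad_protein <- function(tokens, target_length = 1000L) {
  tokens <- as.integer(tokens)
  n <- length(tokens)
  if (n < 1L) stop("empty token list", call. = FALSE)
  if (n > target_length) {
    stop("protein of length ", n, " exceeds ", target_length,
         "; length_filter() was skipped upstream", call. = FALSE)
  }
  c(rep(0L, target_length - n), tokens)
}

#' Normalize an IC50 to a [0, 1] affinity score
#'
#' The NetMHC-family convention `1 - log(IC50) / log(50000)` (IC50 in nM),
#' clipped to `[0, 1]`; 500 nM maps to 0.426 (3 decimals), the conventional
#' binder threshold.
#'
#' @param ic50_nM positive IC50 value(s) in nM.
#' @export
normalize_ic50 <- function(ic50_nM) {
  if (any(ic50_nM <= 0)) stop("IC50 must be positive", call. = FALSE)
  pmin(pmax(1 - log(ic50_nM) / log(50000), 0), 1)
}

#' Binarize a normalized affinity at the binder threshold
#'
#' Scores at or above the threshold (default 0.426, i.e. IC50 <= 500 nM)
#' are binders (1); ties at the threshold count as positive.
#'
#' @param score affinity score(s) in `[0, 1]`.
#' @param threshold binder threshold.
#' @return Integer label(s) in `{0, 1}`.
#' @export
binarize_affinity <- function(score, threshold = 0.426) {
  as.integer(score >= threshold)
}

#' Keep proteins within the modelled length band
#'
#' Removes proteins strictly shorter than `min_len` or strictly longer than
#' `max_len`; input order is preserved.
#'
#' @param proteins protein `data.frame` with a `sequence` column.
#' @param min_len,max_len inclusive length bounds, defaults 100 and 1000.
#' @export
length_filter <- function(proteins, min_len = 100L, max_len = 1000L) {
  n <- nchar(proteins$sequence)
  proteins[n >= min_len & n <= max_len, , drop = FALSE]
}

#' Protein-level train/test split
#'
#' Seeded shuffle then a disjoint, exhaustive split with `ceiling(frac * n)`
#' proteins in the training set. Splitting at the protein level (not the
#' pair level) is what makes the downstream homology filter meaningful.
#'
#' @param proteins protein `data.frame`.
#' @param train_frac training fraction, default 0.9.
#' @param seed integer seed.
#' @return List with `train` and `test` `data.frame`s.
#' @export
split_proteins <- function(proteins, train_frac = 0.9, seed) {
  stopifnot(nrow(proteins) >= 2L)
  n <- nrow(proteins)
  ord <- with_seed(seed, sample.int(n))
  n_train <- ceiling(train_frac * n)
  list(train = proteins[sort(ord[seq_len(n_train)]), , drop = FALSE],
       test = proteins[sort(ord[-seq_len(n_train)]), , drop = FALSE])
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Shared k-mer sequence identity
#'
#' `|shared distinct k-mers| / min(|distinct k-mers of a|, |of b|)`; a
#' symmetric, desk-scale stand-in for alignment-based percent identity
#' (monotone in sequence identity, 1 for identical sequences).
#'
#' @param seq_a,seq_b residue strings of length >= `k`.
#' @param k k-mer width, default 5.
#' @return Identity in `[0, 1]`.
#' @export
kmer_identity <- function(seq_a, seq_b, k = 5L) {
  if (nchar(seq_a) < k || nchar(seq_b) < k) {
    stop("sequences must be at least k = ", k, " residues long", call. = FALSE)
  }
  ka <- .kmer_set(seq_a, k)
  kb <- .kmer_set(seq_b, k)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Remove test proteins homologous to the training set
#'
#' Drops every test protein whose [kmer_identity()] to any training protein
#' strictly exceeds `threshold` (default 40%). Deterministic; the surviving
#' set is always a subset of the input test set.
#'
#' @param test_proteins,train_proteins protein `data.frame`s.
#' @param threshold identity threshold, default 0.40.
#' @param k k-mer width.
#' @export
homology_filter <- function(test_proteins, train_proteins, threshold = 0.40,
                            k = 5L) {
  if (nrow(test_proteins) == 0L || nrow(train_proteins) == 0L) {
    return(test_proteins)
  }
  train_sets <- lapply(train_proteins$sequence, .kmer_set, k = k)
  keep <- vapply(test_proteins$sequence, function(s) {
    ks <- .kmer_set(s, k)
    for (ts in train_sets) {
      ident <- length(intersect(ks, ts)) / min(length(ks), length(ts))
      if (ident > threshold) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
  test_proteins[keep, , drop = FALSE]
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Balance positives with uniformly sampled negative pairs
#'
#' Appends exactly `nrow(positive_pairs)` negative pairs sampled uniformly
#' from the unordered non-self pairs of `protein_ids` that are not in the
#' positive set, without duplicates, giving a 1:1 class ratio.
#'
#' @param positive_pairs `data.frame` with `id_a`, `id_b` (labels forced
#'   to 1 in the output).
#' @param protein_ids character vector of ids to sample negatives from.
#' @param seed integer seed.
#' @param exclude_pairs optional `data.frame` of additional pairs that must
#'   not be drawn as negatives (e.g. known interactions that were not
#'   emitted as positives); defaults to `positive_pairs` alone.
#' @return `data.frame` with `id_a`, `id_b`, `label`; positives first.
#' @export
balance_negatives <- function(positive_pairs, protein_ids, seed,
                              exclude_pairs = NULL) {
  n_pos <- nrow(positive_pairs)
  n_ids <- length(protein_ids)
  n_universe <- n_ids * (n_ids - 1) / 2
  in_universe <- function(p) {
    p[p$id_a %in% protein_ids & p$id_b %in% protein_ids, , drop = FALSE]
  }
  pu <- in_universe(positive_pairs)
  forbidden <- unique(c(
    .pair_key(pu$id_a, pu$id_b),
    if (!is.null(exclude_pairs)) {
      eu <- in_universe(exclude_pairs)
      .pair_key(eu$id_a, eu$id_b)
    }))
  if (n_universe - length(forbidden) < n_pos) {
    stop("infeasible: only ", n_universe - length(forbidden),
         " candidate negative pairs exist for ", n_pos, " positives",
         call. = FALSE)
  }
  neg_a <- character(0); neg_b <- character(0)
  with_seed(seed, {
    have <- character(0)
    while (length(neg_a) < n_pos) {
      need <- n_pos - length(neg_a)
      a <- protein_ids[sample.int(n_ids, 2L * need + 10L, replace = TRUE)]
      b <- protein_ids[sample.int(n_ids, 2L * need + 10L, replace = TRUE)]
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      key <- .pair_key(a, b)
      fresh <- !(key %in% forbidden) & !(key %in% have) & !duplicated(key)
      a <- a[fresh][seq_len(min(need, sum(fresh)))]
      b <- b[fresh][seq_len(min(need, sum(fresh)))]
      neg_a <- c(neg_a, a); neg_b <- c(neg_b, b)
      have <- c(have, .pair_key(a, b))
    }
  })
  rbind(
    data.frame(id_a = positive_pairs$id_a, id_b = positive_pairs$id_b,
               label = 1L, stringsAsFactors = FALSE),
    data.frame(id_a = neg_a, id_b = neg_b, label = 0L,
               stringsAsFactors = FALSE))
}

#' Prepared model-ready datasets
#'
#' A `prepared_dataset` couples model inputs (a token matrix for the peptide
#' task, or a list of two token matrices for the pair task) with targets and
#' provenance metadata (seed, fraction, split name).
#'
#' @param inputs token matrix (`n x L`) or `list(a =, b =)` of two such.
#' @param targets numeric targets in `[0, 1]` or integer labels.
#' @param metadata named list of provenance fields.
#' @export
prepared_dataset <- function(inputs, targets, metadata = list()) {
  n <- if (is.list(inputs)) nrow(inputs[[1]]) else nrow(inputs)
  if (n != length(targets)) {
    stop("inputs and targets must have equal length", call. = FALSE)
  }
  structure(list(inputs = inputs, targets = targets, metadata = metadata),
            class = "prepared_dataset")
}

#' @export
length.prepared_dataset <- function(x) length(x$targets)

#' @export
print.prepared_dataset <- function(x, ...) {
  cat(sprintf("<prepared_dataset> n=%d task=%s\n", length(x),
              if (is.list(x$inputs)) "pair" else "single"))
  invisible(x)
}

#' Prepare a peptide table for modelling
#'
#' Tokenizes every peptide and pads/trims it to the fixed length.
#'
#' @param peptides `data.frame` with `peptide` and `affinity` columns.
#' @param target_length fixed token length, default 26.
#' @param metadata provenance list stored on the result.
#' @return A [prepared_dataset()] whose inputs are an `n x target_length`
#'   integer matrix.
#' @export
prepare_peptides <- function(peptides, target_length = 26L, metadata = list()) {
  x <- t(vapply(peptides$peptide,
                function(p) pad_trim_peptide(tokenize(p), target_length),
                integer(target_length), USE.NAMES = FALSE))
  prepared_dataset(x, peptides$affinity, metadata)
}

#' Prepare protein pairs for modelling
#'
#' Tokenizes and zero-pads both proteins of every pair to the fixed length.
#'
#' @param pairs pair `data.frame` (`id_a`, `id_b`, `label`).
#' @param proteins protein `data.frame` (`id`, `sequence`).
#' @param target_length fixed token length, default 1000.
#' @param metadata provenance list stored on the result.
#' @export
prepare_pairs <- function(pairs, proteins, target_length = 1000L,
                          metadata = list()) {
  tok <- lapply(proteins$sequence,
                function(s) pad_protein(tokenize(s), target_length))
  tok <- do.call(rbind, tok)
  rownames(tok) <- proteins$id
  miss <- setdiff(unique(c(pairs$id_a, pairs$id_b)), proteins$id)
  if (length(miss) > 0L) {
    stop("pairs reference unknown protein ids: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  prepared_dataset(list(a = tok[pairs$id_a, , drop = FALSE],
                        b = tok[pairs$id_b, , drop = FALSE]),
                   as.integer(pairs$label), metadata)
}

#' Subset a prepared dataset to a fraction of its examples
#'
#' Uniform seeded subsample of size `round(fraction * n)` preserving the
#' input/target pairing; `fraction = 1` returns the dataset unchanged, in
#' its original order.
#'
#' @param dataset a [prepared_dataset()].
#' @param fraction in `(0, 1]`.
#' @param seed integer seed.
#' @export
subset_fraction <- function(dataset, fraction, seed) {
  stopifnot(inherits(dataset, "prepared_dataset"))
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) return(dataset)
  n <- length(dataset)
  keep <- with_seed(seed, sort(sample.int(n, round(fraction * n))))
  inputs <- if (is.list(dataset$inputs)) {
    lapply(dataset$inputs, function(m) m[keep, , drop = FALSE])
  } else {
    dataset$inputs[keep, , drop = FALSE]
  }
  md <- dataset$metadata
  md$fraction <- fraction
  md$subset_seed <- seed
  prepared_dataset(inputs, dataset$targets[keep], md)
}
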