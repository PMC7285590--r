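#' Amino-acid encoding matrices
#'
#' An `aa_encoding` is a 21 x d real matrix with one row per token of
#' [aa_alphabet()] (padding row first), a scheme name, and a `trainable`
#' flag. Classical schemes (one-hot, frequency-normalized BLOSUM62, VHSE8)
#' are frozen look-up tables; `random_frozen` draws every entry i.i.d.
#' uniform on `[-0.05, 0.05]` and freezes it; `learned` uses the same
#' initialization law but marks the matrix as a trainable model parameter.
#'
#' @name aa_encoding
NULL

new_aa_encoding <- function(values, scheme, trainable, seed = NA_integer_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != 21L) {
    stop("encoding matrix must have exactly 21 rows (pad + 20 amino acids), got ",
         nrow(values), call. = FALSE)
  }
  if (ncol(values) < 1L) stop("encoding dimension must be >= 1", call. = FALSE)
  if (!all(is.finite(values))) stop("encoding matrix contains non-finite values",
                                    call. = FALSE)
  rownames(values) <- aa_alphabet()
  structure(
    list(scheme = scheme, values = values, dim = ncol(values),
         trainable = isTRUE(trainable), seed = seed),
    class = "aa_encoding")
}

#' @export
print.aa_encoding <- function(x, ...) {
  cat(sprintf("<aa_encoding> scheme=%s dim=%d trainable=%s\n",
              x$scheme, x$dim, x$trainable))
  invisible(x)
}

#' @export
dim.aa_encoding <- function(x) dim(x$values)

#' One-hot encoding (20 dimensions)
#'
#' Each amino acid is a 20-dimensional unit vector; the padding row is all
#' zeros. Carries distinguishability but no inter-residue similarity: all
#' pairwise amino-acid distances equal `sqrt(2)`.
#'
#' @param alphabet character vector as returned by [aa_alphabet()].
#' @return An `aa_encoding` of dimension 20, frozen.
#' @export
build_one_hot <- function(alphabet = aa_alphabet()) {
  if (length(alphabet) != 21L || anyDuplicated(alphabet)) {
    stop("alphabet must hold 21 distinct tokens", call. = FALSE)
  }
  m <- rbind(0, diag(20))
  new_aa_encoding(m, "one_hot", trainable = FALSE)
}

#' Random frozen encoding
#'
#' Every entry (including the padding row) drawn i.i.d. uniform on
#' `[-0.05, 0.05]` and never updated: a control that supplies
#' distinguishability without information content.
#'
#' @param dim embedding dimension (>= 1).
#' @param seed integer seed; identical `(dim, seed)` give identical matrices.
#' @return Frozen `aa_encoding` of the requested dimension.
#' @export
build_random_frozen <- function(dim, seed) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1) {
    stop("invalid dimension: dim must be >= 1", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  dim <- as.integer(dim)
  vals <- with_seed(seed, matrix(stats::runif(21L * dim, -0.05, 0.05), 21L, dim))
  new_aa_encoding(vals, "random_frozen", trainable = FALSE, seed = as.integer(seed))
}

#' Initialize a learned (trainable) embedding
#'
#' Same initialization law as [build_random_frozen()] — the Keras embedding
#' default, uniform on `[-0.05, 0.05]` — but flagged trainable, so training
#' updates it by backpropagation along with the other network parameters.
#'
#' @inheritParams build_random_frozen
#' @export
init_learned <- function(dim, seed) {
  enc <- build_random_frozen(dim, seed)
  enc$scheme <- "learned"
  enc$trainable <- TRUE
  enc
}

#' Encode a token sequence as a numeric matrix
#'
#' Row j of the result is the encoding-matrix row of token j, giving an
#' `L x d` matrix for a length-`L` sequence under a `d`-dimensional scheme.
#'
#' @param tokens integer vector of token indices in `[0, 20]`, or a single
#'   character string of residues (tokenized internally; no padding symbol).
#' @param encoding an `aa_encoding`.
#' @return Numeric matrix of shape `(length(tokens), encoding$dim)`.
#' @export
encode_sequence <- function(tokens, encoding) {
  stopifnot(inherits(encoding, "aa_encoding"))
  if (is.character(tokens) && length(tokens) == 1L) {
    tokens <- token_to_index(strsplit(tokens, "")[[1]])
  }
  tokens <- as.integer(tokens)
  if (any(tokens < 0L | tokens > 20L)) {
    stop("unknown token index outside [0, 20]", call. = FALSE)
  }
  out <- encoding$values[tokens + 1L, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Serialize / deserialize an encoding matrix as TSV
#'
#' Layout: one header comment line
#' `#scheme=<name> dim=<d> trainable=<0|1> seed=<int|NA>`, then 21 rows
#' `token<TAB>v1...<TAB>vd` in alphabet order, values printed with 17
#' significant digits so a round-trip is exact to within 1e-12.
#'
#' @param encoding an `aa_encoding`.
#' @param path file path.
#' @return `load_matrix()` returns the reconstructed `aa_encoding`.
#' @export
save_matrix <- function(encoding, path) {
  stopifnot(inherits(encoding, "aa_encoding"))
  header <- sprintf("#scheme=%s dim=%d trainable=%d seed=%s",
                    encoding$scheme, encoding$dim, as.integer(encoding$trainable),
                    ifelse(is.na(encoding$seed), "NA", encoding$seed))
  rows <- vapply(seq_len(21L), function(i) {
    paste(c(aa_alphabet()[i],
            formatC(encoding$values[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname save_matrix
#' @export
load_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || !startsWith(lines[1], "#scheme=")) {
    stop("parse error at line 1: missing '#scheme=' header", call. = FALSE)
  }
  hdr <- strsplit(sub("^#", "", lines[1]), " ")[[1]]
  kv <- strsplit(hdr, "=")
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != 21L) {
    stop("parse error: expected 21 data rows, found ", length(body),
         " (line ", length(body) + 1L, ")", call. = FALSE)
  }
  d <- as.integer(meta[["dim"]])
  vals <- matrix(NA_real_, 21L, d)
  for (i in seq_len(21L)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != d + 1L || parts[1] != aa_alphabet()[i]) {
      stop("parse error at line ", i + 1L, ": expected token '",
           aa_alphabet()[i], "' with ", d, " values", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(v)) stop("parse error at line ", i + 1L, ": non-numeric value",
                       call. = FALSE)
    vals[i, ] <- v
  }
  seed <- if (meta[["seed"]] == "NA") NA_integer_ else as.integer(meta[["seed"]])
  new_aa_encoding(vals, meta[["scheme"]],
                  trainable = meta[["trainable"]] == "1", seed = seed)
}
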