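#' The token alphabet: padding plus the 20 canonical amino acids
#'
#' Index 0 is reserved for the padding symbol (printed as `"-"`); indices
#' 1 to 20 are the canonical amino acids in alphabetical one-letter order
#' (A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y). All token
#' matrices, encoding matrices and distance matrices in the package use this
#' fixed ordering, so the bijection token <-> index is stable across runs.
#'
#' @return Character vector of length 21; element 1 is the padding symbol, so
#'   `aa_alphabet()[i + 1]` is the token with index `i`.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  c("-", "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @return `aa_residues()` returns only the 20 amino-acid letters (indices
#'   1 to 20), without the padding symbol.
#' @export
aa_residues <- function() aa_alphabet()[-1]

# index of each token (padding = 0L), as a named integer vector
.token_index <- function() {
  ab <- aa_alphabet()
  stats::setNames(seq_along(ab) - 1L, ab)
}

#' Map tokens to indices and back
#'
#' @param tokens character vector of single-letter tokens.
#' @param indices integer vector of token indices in `[0, 20]`.
#' @return `token_to_index()` returns an integer vector; `index_to_token()`
#'   a character vector.
#' @export
token_to_index <- function(tokens) {
  idx <- .token_index()[tokens]
  if (anyNA(idx)) {
    bad <- tokens[is.na(idx)][1]
    stop("unknown token: '", bad, "'", call. = FALSE)
  }
  unname(idx)
}

#' @rdname token_to_index
#' @export
index_to_token <- function(indices) {
  indices <- as.integer(indices)
  if (any(indices < 0L | indices > 20L)) {
    stop("token index outside [0, 20]", call. = FALSE)
  }
  aa_alphabet()[indices + 1L]
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
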