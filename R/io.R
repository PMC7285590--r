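# Plain-text dataset interchange: peptide TSV (`peptide<TAB>affinity`
# [+ true_affinity]), protein FASTA, pair TSV (`id_a<TAB>id_b<TAB>label`).
# Generator/run configuration is echoed into `#key=value` comment lines so
# every artifact records its provenance.

.config_header <- function(config) {
  if (is.null(config) || length(config) == 0L) return(character(0))
  vapply(names(config), function(k) {
    sprintf("#%s=%s", k, paste(format(config[[k]]), collapse = ","))
  }, character(1))
}

#' Read and write dataset files
#'
#' @param peptides peptide `data.frame` as from [generate_peptide_dataset()].
#' @param path file path.
#' @param config optional named list echoed as `#key=value` header lines.
#' @return Readers return a `data.frame` (pairs/peptides) or a protein
#'   `data.frame` with `id` and `sequence` columns.
#' @name dataset_io
NULL

#' @rdname dataset_io
#' @export
write_peptide_dataset <- function(peptides, path, config = NULL) {
  hdr <- .config_header(config)
  cols <- intersect(c("peptide", "affinity", "true_affinity"), names(peptides))
  body <- c(paste(cols, collapse = "\t"),
            do.call(paste, c(unname(peptides[cols]), sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_peptide_dataset <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname dataset_io
#' @param proteins protein `data.frame` with `id` and `sequence`.
#' @export
write_protein_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  data.frame(id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname dataset_io
#' @param pairs pair `data.frame` with `id_a`, `id_b`, `label`.
#' @export
write_pair_dataset <- function(pairs, path, config = NULL) {
  hdr <- .config_header(config)
  body <- c("id_a\tid_b\tlabel",
            paste(pairs$id_a, pairs$id_b, pairs$label, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_pair_dataset <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
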