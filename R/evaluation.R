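#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney estimator with midrank handling of ties: the probability
#' that a random positive scores above a random negative, ties counted 0.5.
#' Equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores.
#' @param binary_labels labels in `{0, 1}`; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, binary_labels) {
  stopifnot(length(scores) == length(binary_labels))
  binary_labels <- as.integer(binary_labels)
  n1 <- sum(binary_labels == 1L)
  n0 <- sum(binary_labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("undefined AUC: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[binary_labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a score threshold
#'
#' @param scores numeric scores.
#' @param binary_labels labels in `{0, 1}`.
#' @param threshold scores `>= threshold` predict class 1; default 0.5.
#' @export
compute_accuracy <- function(scores, binary_labels, threshold = 0.5) {
  stopifnot(length(scores) == length(binary_labels))
  mean(as.integer(scores >= threshold) == as.integer(binary_labels))
}

#' Summarize metric values over repetitions
#'
#' Mean and sample standard deviation (n - 1 denominator) over repeated
#' runs, keeping the per-repetition values.
#'
#' @param values numeric vector, length >= 1.
#' @param metric metric name to record.
#' @return Object of class `metric_summary`.
#' @export
aggregate_repetitions <- function(values, metric = "metric") {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  structure(list(metric = metric, values = values, mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else 0,
                 n_repetitions = length(values)),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("<metric_summary> %s: mean=%.4f sd=%.4f (n=%d)\n",
              x$metric, x$mean, x$sd, x$n_repetitions))
  invisible(x)
}

#' Pairwise Euclidean distances between token vectors
#'
#' The 21 x 21 symmetric matrix of Euclidean distances between all rows of
#' an encoding matrix, padding row included, labelled in alphabet order.
#'
#' @param encoding an `aa_encoding` (or bare 21 x d matrix).
#' @return Object of class `aa_distance_matrix`: the labelled matrix with a
#'   `scheme` attribute.
#' @export
pairwise_distance_matrix <- function(encoding) {
  if (inherits(encoding, "aa_encoding")) {
    vals <- encoding$values
    scheme <- encoding$scheme
  } else {
    vals <- as.matrix(encoding)
    scheme <- "unknown"
  }
  if (nrow(vals) != 21L) stop("expected 21 rows", call. = FALSE)
  d <- as.matrix(stats::dist(vals, method = "euclidean"))
  dimnames(d) <- list(aa_alphabet(), aa_alphabet())
  attr(d, "scheme") <- scheme
  class(d) <- c("aa_distance_matrix", class(d))
  d
}

#' Agglomerative clustering of a token distance matrix
#'
#' Average-linkage (UPGMA by default) clustering, returning the merge tree
#' and a leaf order for heat-map rendering. Deterministic: `hclust` breaks
#' ties by first index.
#'
#' @param distance_matrix from [pairwise_distance_matrix()].
#' @param linkage linkage method passed to [stats::hclust()].
#' @return List with `order` (leaf labels), `merge`, `height` and the
#'   `hclust` object.
#' @export
hierarchical_cluster_order <- function(distance_matrix, linkage = "average") {
  m <- unclass(distance_matrix)
  attr(m, "scheme") <- NULL
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  list(order = hc$labels[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}

#' Export a dendrogram as Newick text
#'
#' @param cluster result of [hierarchical_cluster_order()].
#' @param path optional file path; omitted returns the string.
#' @export
dendrogram_newick <- function(cluster, path = NULL) {
  phy <- ape::as.phylo(cluster$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    invisible(path)
  } else {
    txt
  }
}

#' Write a distance matrix as labelled TSV
#'
#' @param distance_matrix from [pairwise_distance_matrix()].
#' @param path file path.
#' @export
write_distance_matrix <- function(distance_matrix, path) {
  m <- unclass(distance_matrix)
  attr(m, "scheme") <- NULL
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Permutation test of physicochemical group cohesion
#'
#' Statistic: mean between-group distance minus mean within-group distance
#' over the amino-acid rows (padding excluded - it has no group). Positive
#' values mean residues sit closer to their own group than to others. The
#' p-value is the one-sided permutation probability of a statistic at least
#' as large under random relabelling, with +1 smoothing:
#' `(1 + #{perm >= obs}) / (n_permutations + 1)`.
#'
#' @param distance_matrix from [pairwise_distance_matrix()] (21 x 21), or a
#'   20 x 20 amino-acid distance matrix with residue labels.
#' @param groups named character vector mapping residues to group labels,
#'   default [physicochemical_groups()]; every group must have >= 2 members.
#' @param n_permutations number of label permutations.
#' @param seed integer seed.
#' @return List with `statistic`, `p_value`, `n_permutations`.
#' @export
group_cohesion_test <- function(distance_matrix,
                                groups = physicochemical_groups(),
                                n_permutations = 1000L, seed = 1L) {
  m <- unclass(distance_matrix)
  attr(m, "scheme") <- NULL
  if (nrow(m) == 21L) m <- m[aa_residues(), aa_residues()]
  res <- rownames(m)
  g <- groups[res]
  if (anyNA(g)) stop("groups must cover all residues in the matrix",
                     call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("degenerate grouping: every group needs >= 2 members", call. = FALSE)
  }
  stat_fun <- function(lab) {
    same <- outer(lab, lab, "==")
    diag(same) <- NA
    mean(m[!same & !is.na(same)]) - mean(m[same & !is.na(same)])
  }
  obs <- stat_fun(g)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) stat_fun(sample(g)),
           numeric(1))
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_permutations + 1),
       n_permutations = n_permutations)
}
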