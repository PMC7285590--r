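#' Stable per-cell seed derivation
#'
#' Deterministic 31-bit hash of the base seed and the grid coordinates, so
#' every grid cell gets an independent, reproducible seed.
#'
#' @param base_seed integer base seed.
#' @param ... coordinate values (coerced to character).
#' @export
derive_seed <- function(base_seed, ...) {
  s <- paste(c(base_seed, ...), collapse = "|")
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  as.integer(max(h, 1))
}

#' Synthetic data source configurations
#'
#' Desk-scale defaults (deliberately smaller than the GPU-scale originals):
#' 2000 peptides for the affinity task; 400 proteins of length 100-300 and
#' 2000 positive pairs for the pair task, zero-padded to 300 tokens.
#'
#' @param n,n_proteins,n_positive dataset sizes.
#' @param noise_sd affinity observation noise.
#' @param length_range sequence length band.
#' @param n_motifs,motif_length motif library size for the pair task.
#' @param label_noise pair label flip probability.
#' @param input_length fixed token length for the pair task.
#' @param data_seed seed for data generation.
#' @export
hla_synthetic_config <- function(n = 2000L, noise_sd = 0.05,
                                 length_range = c(13L, 25L),
                                 data_seed = 2024L) {
  list(task = "hla", n = n, noise_sd = noise_sd, length_range = length_range,
       data_seed = data_seed)
}

#' @rdname hla_synthetic_config
#' @export
ppi_synthetic_config <- function(n_proteins = 400L,
                                 length_range = c(100L, 300L),
                                 n_motifs = 6L, motif_length = 8L,
                                 n_positive = 2000L, label_noise = 0,
                                 input_length = 300L, data_seed = 2024L) {
  list(task = "ppi", n_proteins = n_proteins, length_range = length_range,
       n_motifs = n_motifs, motif_length = motif_length,
       n_positive = n_positive, label_noise = label_noise,
       input_length = input_length, data_seed = data_seed)
}

# seeded 5-fold assignment; desk profile trains against fold `fold` as
# validation and the rest as training
.fold_assignment <- function(n, n_folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

# materialize train/validation prepared datasets for the affinity task
.hla_data <- function(config, n_folds = 5L, fold = 1L) {
  peps <- generate_peptide_dataset(config$n, binding_motif(),
                                   config$length_range, config$noise_sd,
                                   seed = config$data_seed)
  prep <- prepare_peptides(peps, metadata = list(data_seed = config$data_seed))
  folds <- .fold_assignment(config$n, n_folds, config$data_seed)
  train <- prepared_dataset(prep$inputs[folds != fold, , drop = FALSE],
                            prep$targets[folds != fold],
                            list(split = "train"))
  val <- prepared_dataset(prep$inputs[folds == fold, , drop = FALSE],
                          prep$targets[folds == fold],
                          list(split = "validation"))
  list(train = train, val = val)
}

# all unordered protein pairs carrying a compatible motif pair
.all_compatible_pairs <- function(proteins, lib) {
  n <- nrow(proteins)
  mid <- proteins$motif_ids
  out_a <- character(0); out_b <- character(0)
  for (i in seq_len(n - 1L)) {
    if (length(mid[[i]]) == 0L) next
    partners <- colnames(lib$compat)[colSums(lib$compat[mid[[i]], , drop = FALSE]) > 0]
    if (length(partners) == 0L) next
    for (j in seq((i + 1L), n)) {
      if (any(mid[[j]] %in% partners)) {
        out_a <- c(out_a, proteins$id[i]); out_b <- c(out_b, proteins$id[j])
      }
    }
  }
  data.frame(id_a = out_a, id_b = out_b, stringsAsFactors = FALSE)
}

# materialize the full pair-task pipeline: generate -> length filter ->
# 90/10 protein split -> homology filter -> per-split positives ->
# negative balancing -> tokenize/pad
.ppi_data <- function(config) {
  lib <- generate_motif_library(config$n_motifs, config$motif_length,
                                seed = config$data_seed)
  gen <- generate_ppi_dataset(config$n_proteins, config$length_range, lib,
                              config$n_positive, config$label_noise,
                              seed = config$data_seed)
  prot <- length_filter(gen$proteins, min_len = config$length_range[1],
                        max_len = config$input_length)
  sp <- split_proteins(prot, 0.9, seed = config$data_seed + 1L)
  test <- homology_filter(sp$test, sp$train)
  pos <- gen$pairs[gen$pairs$label == 1L, , drop = FALSE]
  in_train <- pos$id_a %in% sp$train$id & pos$id_b %in% sp$train$id
  in_test <- pos$id_a %in% test$id & pos$id_b %in% test$id
  # exclude every truly compatible pair from the negative pool, including
  # interactions that were not emitted among the n_positive sample
  truth <- .all_compatible_pairs(gen$proteins, lib)
  train_pairs <- balance_negatives(pos[in_train, ], sp$train$id,
                                   seed = config$data_seed + 2L,
                                   exclude_pairs = truth)
  test_pos <- pos[in_test, , drop = FALSE]
  if (nrow(test_pos) >= 1L && nrow(test) >= 3L) {
    test_pairs <- balance_negatives(test_pos, test$id,
                                    seed = config$data_seed + 3L,
                                    exclude_pairs = truth)
  } else {
    test_pairs <- train_pairs[0, ]
  }
  list(train = prepare_pairs(train_pairs, sp$train, config$input_length),
       val = prepare_pairs(test_pairs, test, config$input_length),
       proteins = prot, train_proteins = sp$train, test_proteins = test)
}

#' Benchmark grid configuration
#'
#' Declares the experimental grid: task, architectures, encoding schemes,
#' embedding dimensions (applied to `random_frozen` and `learned` only;
#' classical schemes keep their native dimension), training-data fractions,
#' repetitions and epochs. Every cell's seed is a deterministic function of
#' the base seed and the cell coordinates.
#'
#' @param task `"hla"` or `"ppi"`.
#' @param architectures subset of `"lstm"`, `"cnn_lstm"`, `"siamese_cnn"`.
#' @param schemes subset of `"one_hot"`, `"blosum62"`, `"vhse8"`,
#'   `"random_frozen"`, `"learned"`.
#' @param dims embedding dimensions for the learned/random schemes.
#' @param fractions training-data fractions in `(0, 1]`.
#' @param repetitions repeated runs per cell.
#' @param epochs training epochs per run.
#' @param base_seed integer base seed.
#' @param data a data-source config ([hla_synthetic_config()] or
#'   [ppi_synthetic_config()]).
#' @param batch_size,learning_rate optimizer settings for each run.
#' @export
grid_config <- function(task = c("hla", "ppi"), architectures = "lstm",
                        schemes = c("one_hot", "learned"),
                        dims = c(1L, 2L, 4L, 8L, 16L, 32L), fractions = 1.0,
                        repetitions = 1L, epochs = 50L, base_seed = 1L,
                        data = NULL, batch_size = NULL, learning_rate = 1e-3) {
  task <- match.arg(task)
  stopifnot(length(architectures) > 0, length(schemes) > 0,
            all(fractions > 0 & fractions <= 1), repetitions >= 1)
  ok_arch <- if (task == "hla") c("lstm", "cnn_lstm") else "siamese_cnn"
  if (!all(architectures %in% ok_arch)) {
    stop("architectures not valid for task ", task, call. = FALSE)
  }
  if (is.null(data)) {
    data <- if (task == "hla") hla_synthetic_config() else
      ppi_synthetic_config()
  }
  structure(list(task = task, architectures = architectures,
                 schemes = schemes, dims = as.integer(dims),
                 fractions = fractions, repetitions = as.integer(repetitions),
                 epochs = as.integer(epochs), base_seed = as.integer(base_seed),
                 data = data, batch_size = batch_size,
                 learning_rate = learning_rate),
            class = "grid_config")
}

# one (scheme, dim) axis: classical schemes collapse the dims axis
.scheme_dim_grid <- function(schemes, dims) {
  out <- list()
  for (s in schemes) {
    if (s %in% c("random_frozen", "learned")) {
      for (d in dims) out[[length(out) + 1L]] <- list(scheme = s, dim = d)
    } else {
      native <- c(one_hot = 20L, blosum62 = 20L, vhse8 = 8L)[[s]]
      out[[length(out) + 1L]] <- list(scheme = s, dim = native)
    }
  }
  out
}

.build_for_cell <- function(task, arch, scheme, dim, seed, epochs,
                            batch_size, learning_rate, input_length) {
  spec <- switch(scheme,
    learned = embedding_spec("learned", dim = dim, seed = seed),
    random_frozen = embedding_spec("frozen", "random_frozen", dim = dim,
                                   seed = seed),
    embedding_spec("frozen", scheme))
  if (task == "hla") {
    if (arch == "lstm") {
      cfg <- lstm_config(epochs = epochs,
                         batch_size = if (is.null(batch_size)) 256L else batch_size,
                         learning_rate = learning_rate)
      model <- build_lstm_model(spec, cfg, seed = seed)
    } else {
      cfg <- cnn_lstm_config(epochs = epochs,
                             batch_size = if (is.null(batch_size)) 256L else batch_size,
                             learning_rate = learning_rate)
      model <- build_cnn_lstm_model(spec, cfg, seed = seed)
    }
  } else {
    cfg <- siamese_config(input_length = input_length, epochs = epochs,
                          batch_size = if (is.null(batch_size)) 64L else batch_size,
                          learning_rate = learning_rate)
    model <- build_siamese_ppi_model(spec, cfg, seed = seed)
  }
  model
}

#' Run a benchmark grid
#'
#' Executes every cell of the grid (generate/load data, prepare, build,
#' train, evaluate) and returns one tidy row per
#' `(task, architecture, scheme, dim, fraction, repetition, epoch, metric)`.
#' With `out_dir` set, rows are appended incrementally and completed cells
#' are recorded in a manifest, so an interrupted run can be resumed with
#' `resume = TRUE` and yields the identical final table.
#'
#' @param grid a [grid_config()].
#' @param out_dir optional directory for incremental results + manifest.
#' @param resume skip cells already present in the manifest.
#' @param verbose emit one JSON log line per cell.
#' @return `data.frame` of benchmark rows (also written to
#'   `<out_dir>/results.csv` when `out_dir` is given).
#' @export
run_grid <- function(grid, out_dir = NULL, resume = FALSE, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_config"))
  data <- if (grid$task == "hla") .hla_data(grid$data) else .ppi_data(grid$data)
  input_length <- if (grid$task == "ppi") grid$data$input_length else 26L

  manifest_path <- results_path <- NULL
  done <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest_path <- file.path(out_dir, "manifest.txt")
    results_path <- file.path(out_dir, "results.csv")
    if (resume && file.exists(manifest_path)) {
      done <- readLines(manifest_path)
    } else {
      if (file.exists(manifest_path)) unlink(manifest_path)
      if (file.exists(results_path)) unlink(results_path)
    }
  }

  rows <- list()
  for (arch in grid$architectures) {
    for (sd in .scheme_dim_grid(grid$schemes, grid$dims)) {
      for (frac in grid$fractions) {
        for (rep in seq_len(grid$repetitions)) {
          cell <- paste(grid$task, arch, sd$scheme, sd$dim, frac, rep,
                        sep = ":")
          if (cell %in% done) next
          seed <- derive_seed(grid$base_seed, cell)
          res <- tryCatch({
            train <- subset_fraction(data$train, frac, seed)
            model <- .build_for_cell(grid$task, arch, sd$scheme, sd$dim, seed,
                                     grid$epochs, grid$batch_size,
                                     grid$learning_rate, input_length)
            fit <- train_model(model, train, data$val, epochs = grid$epochs,
                               seed = seed)
            h <- as.data.frame(fit$history)
            data.frame(task = grid$task, architecture = arch,
                       scheme = sd$scheme, dim = sd$dim, fraction = frac,
                       repetition = rep, epoch = h$epoch,
                       metric = paste(h$split, h$metric, sep = "_"),
                       value = h$value, seed = seed, cell = cell,
                       error = NA_character_, stringsAsFactors = FALSE)
          }, error = function(e) {
            data.frame(task = grid$task, architecture = arch,
                       scheme = sd$scheme, dim = sd$dim, fraction = frac,
                       repetition = rep, epoch = NA_integer_,
                       metric = "error", value = NA_real_, seed = seed,
                       cell = cell, error = conditionMessage(e),
                       stringsAsFactors = FALSE)
          })
          rows[[length(rows) + 1L]] <- res
          if (!is.null(out_dir)) {
            utils::write.table(res, results_path, sep = ",",
                               row.names = FALSE,
                               col.names = !file.exists(results_path),
                               append = file.exists(results_path))
            cat(cell, "\n", file = manifest_path, append = TRUE, sep = "")
          }
          if (verbose) {
            message(jsonlite::toJSON(list(event = "cell_done", cell = cell,
                                          seed = seed, rows = nrow(res)),
                                     auto_unbox = TRUE))
          }
        }
      }
    }
  }
  if (!is.null(out_dir) && file.exists(results_path)) {
    out <- utils::read.csv(results_path, stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  out
}

# best (maximum over epochs) value of one metric per run
.best_per_run <- function(results, metric) {
  res <- results[results$metric == metric & !is.na(results$value), ]
  if (nrow(res) == 0L) return(res)
  key <- interaction(res$architecture, res$scheme, res$dim, res$fraction,
                     res$repetition, drop = TRUE)
  do.call(rbind, lapply(split(res, key), function(d) {
    d <- d[which.max(d$value), ]
    d$epoch <- NULL
    d
  }))
}

#' Learned-versus-classical encoding comparison (affinity task)
#'
#' Trains LSTM affinity models for the classical schemes (one-hot,
#' BLOSUM62, VHSE8) and for learned embeddings at each requested dimension
#' on one synthetic dataset, and returns per-epoch validation-AUC curves
#' plus the best AUC per run.
#'
#' @param config an [hla_synthetic_config()].
#' @param dims learned-embedding dimensions.
#' @param epochs training epochs.
#' @param seed base seed.
#' @param repetitions repeated runs per scheme.
#' @param schemes encoding schemes to compare.
#' @return List with `curves` (tidy per-epoch rows) and `best`
#'   (best-epoch validation AUC per run).
#' @export
experiment_fig1 <- function(config = hla_synthetic_config(), dims = 4L,
                            epochs = 60L, seed = 1L, repetitions = 1L,
                            schemes = c("one_hot", "blosum62", "vhse8",
                                        "learned")) {
  grid <- grid_config("hla", "lstm",
                      schemes = schemes,
                      dims = dims, fractions = 1.0, repetitions = repetitions,
                      epochs = epochs, base_seed = seed, data = config)
  results <- run_grid(grid)
  list(curves = results[results$metric == "validation_val_auc", ],
       best = .best_per_run(results, "validation_val_auc"),
       results = results)
}

#' Random-frozen embeddings across dimensions (affinity task)
#'
#' Trains LSTM models whose embeddings are random frozen matrices at each
#' dimension, over several seeds; the embedding is never updated.
#'
#' @param config an [hla_synthetic_config()].
#' @param dims frozen-embedding dimensions.
#' @param epochs training epochs.
#' @param seeds base seeds (one full run per seed).
#' @return List with `curves`, `best` and a per-dimension summary of the
#'   best-epoch AUC (mean and sd over seeds).
#' @export
experiment_fig4 <- function(config = hla_synthetic_config(),
                            dims = c(1L, 2L, 4L, 8L, 16L, 32L), epochs = 60L,
                            seeds = 1:3) {
  all <- lapply(seeds, function(s) {
    grid <- grid_config("hla", "lstm", schemes = "random_frozen", dims = dims,
                        repetitions = 1L, epochs = epochs, base_seed = s,
                        data = config)
    res <- run_grid(grid)
    res$base_seed <- s
    res
  })
  results <- do.call(rbind, all)
  best <- do.call(rbind, lapply(split(results, results$base_seed), function(r) {
    b <- .best_per_run(r, "validation_val_auc")
    b$base_seed <- r$base_seed[1]
    b
  }))
  summary <- do.call(rbind, lapply(split(best, best$dim), function(d) {
    data.frame(dim = d$dim[1], mean_best_auc = mean(d$value),
               sd_best_auc = stats::sd(d$value), n = nrow(d))
  }))
  list(curves = results[results$metric == "validation_val_auc", ],
       best = best, summary = summary[order(summary$dim), ])
}

#' Accuracy versus training-data fraction (pair task)
#'
#' Trains the Siamese pair model at each training fraction with repeated
#' runs, and summarizes validation accuracy as mean and standard deviation
#' per scheme and fraction.
#'
#' @param config a [ppi_synthetic_config()].
#' @param schemes encoding schemes to compare.
#' @param dims embedding dimensions for the learned/random schemes.
#' @param fractions training fractions.
#' @param repetitions repeated runs per cell.
#' @param epochs training epochs.
#' @param seed base seed.
#' @export
experiment_fig2 <- function(config = ppi_synthetic_config(),
                            schemes = "learned", dims = 8L,
                            fractions = c(0.25, 0.5, 0.75, 1.0),
                            repetitions = 5L, epochs = 20L, seed = 1L) {
  grid <- grid_config("ppi", "siamese_cnn", schemes = schemes, dims = dims,
                      fractions = fractions, repetitions = repetitions,
                      epochs = epochs, base_seed = seed, data = config)
  results <- run_grid(grid)
  best <- .best_per_run(results, "validation_val_accuracy")
  summary <- do.call(rbind, lapply(
    split(best, interaction(best$scheme, best$dim, best$fraction, drop = TRUE)),
    function(d) {
      data.frame(scheme = d$scheme[1], dim = d$dim[1], fraction = d$fraction[1],
                 mean_accuracy = mean(d$value),
                 sd_accuracy = if (nrow(d) > 1) stats::sd(d$value) else 0,
                 n = nrow(d))
    }))
  rownames(summary) <- NULL
  list(results = results, best = best,
       summary = summary[order(summary$scheme, summary$fraction), ])
}

#' Embedding-space analysis of a matrix, model or file
#'
#' Chains the evaluation steps the package applies to a trained embedding:
#' pairwise Euclidean distances over all 21 token vectors (padding
#' included), average-linkage clustering, and the physicochemical group
#' cohesion permutation test (padding excluded).
#'
#' @param x an `aa_encoding`, an `aa_model`, or a path to a matrix TSV
#'   written by [save_matrix()].
#' @param n_permutations permutations for the cohesion test.
#' @param seed integer seed for the permutation test.
#' @param out_dir optional directory; writes `distance.tsv`,
#'   `dendrogram.nwk` and `cohesion.json`.
#' @return List with `distance`, `cluster`, `newick` and `cohesion`.
#' @export
analyze_embedding <- function(x, n_permutations = 1000L, seed = 1L,
                              out_dir = NULL) {
  enc <- if (inherits(x, "aa_model")) {
    extract_embedding(x)
  } else if (inherits(x, "aa_encoding")) {
    x
  } else if (is.character(x) && length(x) == 1L) {
    load_matrix(x)
  } else {
    stop("cannot resolve an encoding matrix from the given object",
         call. = FALSE)
  }
  d <- pairwise_distance_matrix(enc)
  cl <- hierarchical_cluster_order(d)
  coh <- group_cohesion_test(d, n_permutations = n_permutations, seed = seed)
  nwk <- dendrogram_newick(cl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_distance_matrix(d, file.path(out_dir, "distance.tsv"))
    writeLines(nwk, file.path(out_dir, "dendrogram.nwk"))
    jsonlite::write_json(
      list(scheme = enc$scheme, statistic = coh$statistic,
           p_value = coh$p_value, n_permutations = coh$n_permutations,
           tokens = aa_alphabet()),
      file.path(out_dir, "cohesion.json"), auto_unbox = TRUE, digits = NA)
  }
  list(distance = d, cluster = cl, newick = nwk, cohesion = coh,
       scheme = enc$scheme)
}
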