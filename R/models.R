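#' Embedding specification for a model
#'
#' Describes how the model's 21 x d embedding layer is populated: `learned`
#' initializes uniformly on `[-0.05, 0.05]` and updates by backpropagation;
#' `frozen` loads a fully specified encoding matrix verbatim and never
#' updates it.
#'
#' @param mode `"learned"` or `"frozen"`.
#' @param source for frozen mode: an `aa_encoding`, or one of the scheme
#'   names `"one_hot"`, `"blosum62"`, `"vhse8"`, `"random_frozen"`.
#' @param dim embedding dimension (learned and random_frozen modes).
#' @param seed integer seed for learned/random initialization.
#' @return Object of class `embedding_spec` with the resolved `encoding`.
#' @export
embedding_spec <- function(mode = c("learned", "frozen"), source = NULL,
                           dim = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "learned") {
    if (is.null(dim)) stop("learned mode requires dim", call. = FALSE)
    enc <- init_learned(dim, seed)
  } else {
    if (inherits(source, "aa_encoding")) {
      enc <- source
    } else if (is.character(source)) {
      enc <- switch(source,
        one_hot = build_one_hot(),
        blosum62 = build_blosum62(),
        vhse8 = build_vhse8(),
        random_frozen = {
          if (is.null(dim)) stop("random_frozen requires dim", call. = FALSE)
          build_random_frozen(dim, seed)
        },
        stop("unknown scheme: ", source, call. = FALSE))
    } else {
      stop("frozen mode requires a matrix or scheme name", call. = FALSE)
    }
    enc$trainable <- FALSE
  }
  structure(list(mode = mode, scheme = enc$scheme, dim = enc$dim,
                 seed = seed, encoding = enc),
            class = "embedding_spec")
}

#' Model configurations
#'
#' Hyperparameters of the three reference architectures. The affinity models
#' share: a 12-unit LSTM, one sigmoid output unit, mean-absolute-error loss,
#' Adam (learning rate 1e-3), batch size 256, fixed input length 26. The
#' CNN-LSTM variant inserts a convolution (36 filters, width 9, stride 1,
#' ReLU) between embedding and LSTM. The Siamese PPI model uses four shared
#' convolution modules (conv -> ReLU -> batch norm -> average pooling; the
#' fourth uses global average pooling) and an MLP head ending in one sigmoid
#' unit with binary cross-entropy loss; per-module filters/kernels default
#' to 32/64/128/256 and 9/7/5/5 (pool width 3), a documented stand-in.
#'
#' @param lstm_units LSTM width.
#' @param input_length fixed token length.
#' @param batch_size minibatch size.
#' @param epochs default training epochs.
#' @param learning_rate Adam step size.
#' @return A config list of the matching class.
#' @export
lstm_config <- function(lstm_units = 12L, input_length = 26L,
                        batch_size = 256L, epochs = 3000L,
                        learning_rate = 1e-3) {
  stopifnot(lstm_units > 0, input_length > 0, batch_size > 0, epochs > 0)
  structure(list(arch = "lstm", lstm_units = as.integer(lstm_units),
                 input_length = as.integer(input_length),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate),
            class = c("lstm_config", "model_config"))
}

#' @rdname lstm_config
#' @param conv_filters,kernel_size,stride convolution block parameters.
#' @export
cnn_lstm_config <- function(conv_filters = 36L, kernel_size = 9L, stride = 1L,
                            lstm_units = 12L, input_length = 26L,
                            batch_size = 256L, epochs = 3000L,
                            learning_rate = 1e-3) {
  if (kernel_size > input_length) {
    stop("kernel_size must not exceed input_length", call. = FALSE)
  }
  if (stride != 1L) stop("only stride 1 is supported", call. = FALSE)
  cfg <- lstm_config(lstm_units, input_length, batch_size, epochs,
                     learning_rate)
  cfg$arch <- "cnn_lstm"
  cfg$conv_filters <- as.integer(conv_filters)
  cfg$kernel_size <- as.integer(kernel_size)
  cfg$stride <- 1L
  class(cfg) <- c("cnn_lstm_config", "model_config")
  cfg
}

#' @rdname lstm_config
#' @param filters,kernels per-module convolution filters and kernel widths
#'   (length 4).
#' @param pool_width average-pooling width (modules 1-3).
#' @param hidden_units width of the MLP head's hidden layer.
#' @param combiner `"concat"` joins the two branch vectors by concatenation;
#'   `"symmetric"` uses element-wise product plus absolute difference, which
#'   makes predictions invariant to input order.
#' @export
siamese_config <- function(filters = c(32L, 64L, 128L, 256L),
                           kernels = c(9L, 7L, 5L, 5L), pool_width = 3L,
                           hidden_units = 128L,
                           combiner = c("concat", "symmetric"),
                           input_length = 1000L, batch_size = 1024L,
                           epochs = 50L, learning_rate = 1e-3) {
  combiner <- match.arg(combiner)
  stopifnot(length(filters) == 4L, length(kernels) == 4L, pool_width >= 1)
  structure(list(arch = "siamese_cnn", filters = as.integer(filters),
                 kernels = as.integer(kernels),
                 pool_width = as.integer(pool_width),
                 hidden_units = as.integer(hidden_units), combiner = combiner,
                 input_length = as.integer(input_length),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate),
            class = c("siamese_config", "model_config"))
}

.new_model <- function(task, arch, config, spec, weights) {
  structure(list(task = task, arch = arch, config = config, spec = spec,
                 weights = weights, trained = FALSE),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("<aa_model> task=%s arch=%s scheme=%s dim=%d trained=%s\n",
              x$task, x$arch, x$spec$scheme, x$spec$dim, x$trained))
  invisible(x)
}

#' Build the three reference models
#'
#' Each constructor seeds all non-embedding parameters from `seed` (Glorot
#' uniform; LSTM forget-gate bias 1) so that two builds with identical seeds
#' have identical initial parameters. The embedding layer is populated from
#' `spec` and is update-eligible only in learned mode.
#'
#' @param spec an [embedding_spec()].
#' @param config matching config from [lstm_config()], [cnn_lstm_config()]
#'   or [siamese_config()].
#' @param seed integer seed for non-embedding parameter initialization.
#' @return An `aa_model`.
#' @export
build_lstm_model <- function(spec, config = lstm_config(), seed = 1L) {
  stopifnot(inherits(spec, "embedding_spec"), inherits(config, "lstm_config"))
  w <- cpp_hla_init(spec$encoding$values, FALSE, 0L, 0L, config$lstm_units,
                    as.integer(seed))
  .new_model("hla", "lstm", config, spec, w)
}

#' @rdname build_lstm_model
#' @export
build_cnn_lstm_model <- function(spec, config = cnn_lstm_config(), seed = 1L) {
  stopifnot(inherits(spec, "embedding_spec"),
            inherits(config, "cnn_lstm_config"))
  w <- cpp_hla_init(spec$encoding$values, TRUE, config$conv_filters,
                    config$kernel_size, config$lstm_units, as.integer(seed))
  .new_model("hla", "cnn_lstm", config, spec, w)
}

#' @rdname build_lstm_model
#' @export
build_siamese_ppi_model <- function(spec, config = siamese_config(),
                                    seed = 1L) {
  stopifnot(inherits(spec, "embedding_spec"),
            inherits(config, "siamese_config"))
  w <- cpp_siamese_init(spec$encoding$values, config$filters, config$kernels,
                        config$pool_width, config$hidden_units,
                        config$combiner == "symmetric", as.integer(seed))
  .new_model("ppi", "siamese_cnn", config, spec, w)
}

.check_inputs <- function(model, inputs) {
  L <- model$config$input_length
  if (model$task == "hla") {
    if (!is.matrix(inputs) || ncol(inputs) != L) {
      stop("expected an n x ", L, " token matrix", call. = FALSE)
    }
  } else {
    if (!is.list(inputs) || length(inputs) != 2L ||
        ncol(inputs[[1]]) != L || ncol(inputs[[2]]) != L) {
      stop("expected a list of two n x ", L, " token matrices", call. = FALSE)
    }
  }
}

#' Predict with a built or trained model
#'
#' @param model an `aa_model`.
#' @param inputs a token matrix (affinity task) or list of two token
#'   matrices (pair task), or a [prepared_dataset()].
#' @return Numeric predictions, strictly inside `(0, 1)`.
#' @export
predict_model <- function(model, inputs) {
  stopifnot(inherits(model, "aa_model"))
  if (inherits(inputs, "prepared_dataset")) inputs <- inputs$inputs
  .check_inputs(model, inputs)
  if (model$task == "hla") {
    as.numeric(cpp_hla_predict(model$weights, inputs))
  } else {
    as.numeric(cpp_siamese_predict(model$weights, inputs[[1]], inputs[[2]]))
  }
}

#' Train a model and record its history
#'
#' Runs the architecture's stated optimizer, loss and batch size for
#' `epochs` epochs, recording training loss and validation loss each epoch
#' plus the task metric (validation AUC of the binarized affinities for the
#' peptide task at the 0.426 threshold; validation accuracy at 0.5 for the
#' pair task). With a frozen embedding spec the embedding matrix is
#' byte-identical before and after training. Fully seeded: identical
#' `(data, config, seed)` reproduce the history bitwise on one platform.
#'
#' @param model an `aa_model`.
#' @param train_data,val_data [prepared_dataset()]s (or lists with
#'   `inputs`/`targets`).
#' @param epochs number of epochs; defaults to the model config.
#' @param seed integer seed for batch shuffling.
#' @return List with the trained `model` and a `training_history`
#'   (tidy `data.frame`: `epoch`, `split`, `metric`, `value`).
#' @export
train_model <- function(model, train_data, val_data, epochs = NULL,
                        seed = 1L) {
  stopifnot(inherits(model, "aa_model"))
  if (is.null(epochs)) epochs <- model$config$epochs
  stopifnot(epochs >= 1)
  .check_inputs(model, train_data$inputs)
  .check_inputs(model, val_data$inputs)
  cfg <- model$config
  if (model$task == "hla") {
    fit <- cpp_hla_train(model$weights, train_data$inputs,
                         as.numeric(train_data$targets), val_data$inputs,
                         as.numeric(val_data$targets), as.integer(epochs),
                         cfg$batch_size, cfg$learning_rate,
                         model$spec$encoding$trainable, as.integer(seed))
    vlab <- binarize_affinity(as.numeric(val_data$targets))
    metric <- "val_auc"
    mvals <- apply(fit$val_pred, 1, function(p) {
      if (length(unique(vlab)) < 2L) NA_real_ else compute_auc(p, vlab)
    })
  } else {
    fit <- cpp_siamese_train(model$weights, train_data$inputs[[1]],
                             train_data$inputs[[2]],
                             as.numeric(train_data$targets),
                             val_data$inputs[[1]], val_data$inputs[[2]],
                             as.numeric(val_data$targets), as.integer(epochs),
                             cfg$batch_size, cfg$learning_rate,
                             model$spec$encoding$trainable, as.integer(seed))
    metric <- "val_accuracy"
    mvals <- apply(fit$val_pred, 1, compute_accuracy,
                   binary_labels = as.integer(val_data$targets))
  }
  model$weights <- fit$weights
  model$trained <- TRUE
  ep <- seq_len(epochs)
  history <- rbind(
    data.frame(epoch = ep, split = "train", metric = "loss",
               value = as.numeric(fit$train_loss)),
    data.frame(epoch = ep, split = "validation", metric = "loss",
               value = as.numeric(fit$val_loss)),
    data.frame(epoch = ep, split = "validation", metric = metric,
               value = as.numeric(mvals)))
  attr(history, "config") <- cfg
  attr(history, "seed") <- seed
  attr(history, "scheme") <- model$spec$scheme
  class(history) <- c("training_history", "data.frame")
  list(model = model, history = history,
       val_pred = fit$val_pred)
}

#' Extract the current embedding matrix from a model
#'
#' For a frozen model this equals the construction-time matrix; for a
#' learned model it is the matrix after whatever training has happened
#' (the seeded initialization if untrained).
#'
#' @param model an `aa_model`.
#' @return An `aa_encoding` tagged with the spec's scheme and mode.
#' @export
extract_embedding <- function(model) {
  stopifnot(inherits(model, "aa_model"))
  if (is.null(model$weights$E)) stop("model has no embedding layer",
                                     call. = FALSE)
  enc <- new_aa_encoding(model$weights$E, model$spec$scheme,
                         trainable = model$spec$encoding$trainable,
                         seed = model$spec$encoding$seed)
  enc
}

#' Serialize a training history
#'
#' Tidy CSV (`epoch,split,metric,value`) plus a JSON sidecar with the config
#' snapshot and seed.
#'
#' @param history a `training_history`.
#' @param path CSV path; the sidecar gets extension `.json`.
#' @export
write_history <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  manifest <- list(config = attr(history, "config"),
                   seed = attr(history, "seed"),
                   scheme = attr(history, "scheme"))
  jsonlite::write_json(manifest, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  invisible(path)
}
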