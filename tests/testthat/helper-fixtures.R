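# Shared fixtures. Expensive artifacts (trained models for the acceptance
# criteria) are computed once per test session and cached here. All training
# in the test suite runs a desk-scale profile: n = 2000 peptides, 60 epochs
# (scaled down from the reference 3000-epoch runs), seeds 1:3.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# the canonical synthetic affinity dataset of the acceptance profile
acceptance_hla_data <- function(noise_sd = 0.05) {
  key <- paste0("hla_data_", noise_sd)
  fixture(key, {
    cfg <- hla_synthetic_config(n = 2000L, noise_sd = noise_sd,
                                data_seed = 2024L)
    aabench:::.hla_data(cfg)
  })
}

# one desk-scale LSTM run; returns best validation AUC, the trained model
# and its history
hla_run <- function(scheme, dim = NULL, seed, epochs = 60L,
                    noise_sd = 0.05) {
  key <- paste("run", scheme, dim, seed, epochs, noise_sd, sep = "_")
  fixture(key, {
    data <- acceptance_hla_data(noise_sd)
    spec <- switch(scheme,
      learned = embedding_spec("learned", dim = dim, seed = seed * 10L),
      random_frozen = embedding_spec("frozen", "random_frozen", dim = dim,
                                     seed = seed * 10L),
      embedding_spec("frozen", scheme))
    model <- build_lstm_model(spec, lstm_config(epochs = epochs), seed = seed)
    emb_before <- model$weights$E
    fit <- train_model(model, data$train, data$val, epochs = epochs,
                       seed = seed)
    h <- as.data.frame(fit$history)
    list(best_auc = max(h$value[h$metric == "val_auc"]),
         model = fit$model, history = h, emb_before = emb_before)
  })
}

# tiny PPI world shared by the model/benchmark tests
tiny_ppi_config <- function(seed = 5L) {
  ppi_synthetic_config(n_proteins = 80L, length_range = c(100L, 180L),
                       n_positive = 300L, input_length = 200L,
                       data_seed = seed)
}

tiny_siamese_config <- function(epochs = 3L, combiner = "concat") {
  siamese_config(filters = c(8L, 8L, 16L, 16L), kernels = c(9L, 7L, 5L, 5L),
                 input_length = 200L, batch_size = 32L, epochs = epochs,
                 hidden_units = 16L, combiner = combiner)
}

random_tokens <- function(n, L) {
  matrix(sample(0:20, n * L, replace = TRUE), n, L)
}
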