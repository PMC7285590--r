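test_that("embedding layer loads frozen matrices verbatim, learned in range", {
  spec <- embedding_spec("frozen", "one_hot")
  model <- build_lstm_model(spec, lstm_config(epochs = 1), seed = 1)
  expect_identical(model$weights$E, unname(build_one_hot()$values))
  lspec <- embedding_spec("learned", dim = 4, seed = 2)
  lmodel <- build_lstm_model(lspec, lstm_config(epochs = 1), seed = 1)
  expect_identical(dim(lmodel$weights$E), c(21L, 4L))
  expect_true(all(lmodel$weights$E >= -0.05 & lmodel$weights$E <= 0.05))
  expect_error(embedding_spec("frozen"), "matrix or scheme")
  expect_error(embedding_spec("learned"), "dim")
})

test_that("model builds are seeded and predictions live in (0,1)", {
  spec <- embedding_spec("learned", dim = 4, seed = 3)
  m1 <- build_lstm_model(spec, lstm_config(epochs = 1), seed = 5)
  m2 <- build_lstm_model(spec, lstm_config(epochs = 1), seed = 5)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_lstm_model(spec, lstm_config(epochs = 1), seed = 6)
  expect_false(identical(m1$weights$Wx, m3$weights$Wx))
  X <- random_tokens(17, 26)
  p <- predict_model(m1, X)
  expect_length(p, 17L)
  expect_true(all(p > 0 & p < 1))
  # LSTM width contract
  expect_identical(dim(m1$weights$Wh), c(12L, 48L))
  expect_error(predict_model(m1, random_tokens(3, 20)), "26")
})

test_that("CNN-LSTM inserts the stated convolution block", {
  spec <- embedding_spec("frozen", "vhse8")
  cfg <- cnn_lstm_config(epochs = 1)
  model <- build_cnn_lstm_model(spec, cfg, seed = 1)
  # 36 filters of width 9 over an 8-dim embedding; LSTM consumes 36 channels
  expect_identical(dim(model$weights$Wc), c(72L, 36L))
  expect_identical(dim(model$weights$Wx), c(36L, 48L))
  p <- predict_model(model, random_tokens(5, 26))
  expect_true(all(p > 0 & p < 1))
  expect_error(cnn_lstm_config(kernel_size = 30), "input_length")
})

test_that("analytic gradients match finite differences (regression guard)", {
  set.seed(1)
  emb <- init_learned(5, seed = 3)$values
  X <- random_tokens(6, 12)
  y <- runif(6)
  for (use_conv in c(FALSE, TRUE)) {
    w <- aabench:::cpp_hla_init(emb, use_conv, 3L, 4L, 4L, 7L)
    g <- aabench:::cpp_hla_grad(w, X, y)
    for (nm in c("E", "Wx", "Wh", "b", "wo")) {
      idx <- sample(length(w[[nm]]), min(4, length(w[[nm]])))
      for (i in idx) {
        eps <- 1e-6
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
        fd <- (aabench:::cpp_hla_loss(wp, X, y) -
                 aabench:::cpp_hla_loss(wm, X, y)) / (2 * eps)
        an <- g[[paste0("d", nm)]][i]
        expect_lt(abs(fd - an) / (abs(fd) + abs(an) + 1e-8), 1e-3)
      }
    }
  }
  # Siamese: check one parameter per layer family (training-mode loss)
  embS <- init_learned(4, seed = 5)$values
  ws <- aabench:::cpp_siamese_init(embS, c(3L, 4L, 5L, 6L), c(5L, 3L, 3L, 3L),
                                   2L, 8L, FALSE, 11L)
  Xa <- random_tokens(6, 60); Xb <- random_tokens(6, 60)
  yy <- sample(0:1, 6, replace = TRUE)
  gs <- aabench:::cpp_siamese_grad(ws, Xa, Xb, yy)
  probe <- list(list("E", gs$dE), list("W1", gs$dW1), list("w2", gs$dw2))
  for (m in 1:4) probe <- c(probe, list(list(c("Wc", m), gs$dWc[[m]]),
                                        list(c("bn_gamma", m), gs$dgamma[[m]])))
  for (pr in probe) {
    path <- pr[[1]]; an_all <- pr[[2]]
    v <- if (length(path) == 2) ws[[path[1]]][[as.integer(path[2])]] else
      ws[[path[1]]]
    i <- sample(length(v), 1)
    bump <- function(w, d) {
      if (length(path) == 2) {
        w[[path[1]]][[as.integer(path[2])]][i] <-
          w[[path[1]]][[as.integer(path[2])]][i] + d
      } else {
        w[[path[1]]][i] <- w[[path[1]]][i] + d
      }
      w
    }
    eps <- 1e-5
    fd <- (aabench:::cpp_siamese_loss(bump(ws, eps), Xa, Xb, yy, TRUE) -
             aabench:::cpp_siamese_loss(bump(ws, -eps), Xa, Xb, yy, TRUE)) /
      (2 * eps)
    expect_lt(abs(fd - an_all[i]) / (abs(fd) + abs(an_all[i]) + 1e-8), 1e-3)
  }
})

test_that("training histories are complete, seeded and reproducible", {
  data <- acceptance_hla_data()
  small_tr <- prepared_dataset(data$train$inputs[1:300, ],
                               data$train$targets[1:300])
  spec <- embedding_spec("learned", dim = 4, seed = 1)
  model <- build_lstm_model(spec, lstm_config(epochs = 5), seed = 1)
  fit1 <- train_model(model, small_tr, data$val, epochs = 5, seed = 9)
  fit2 <- train_model(model, small_tr, data$val, epochs = 5, seed = 9)
  h <- as.data.frame(fit1$history)
  expect_identical(nrow(h), 15L)  # 3 series x 5 epochs
  expect_true(all(is.finite(h$value)))
  expect_identical(fit1$history$value, fit2$history$value)
  expect_identical(fit1$model$weights, fit2$model$weights)
  # learned mode must move the embedding
  expect_false(identical(fit1$model$weights$E, model$weights$E))
  # shape mismatch caught before training
  expect_error(train_model(model, prepared_dataset(random_tokens(4, 20),
                                                   runif(4)), data$val),
               "26")
})

test_that("frozen embeddings are byte-identical through training", {
  data <- acceptance_hla_data()
  small_tr <- prepared_dataset(data$train$inputs[1:300, ],
                               data$train$targets[1:300])
  for (scheme in c("one_hot", "blosum62", "vhse8")) {
    spec <- embedding_spec("frozen", scheme)
    model <- build_lstm_model(spec, lstm_config(epochs = 3), seed = 2)
    before <- model$weights$E
    fit <- train_model(model, small_tr, data$val, epochs = 3, seed = 2)
    expect_identical(fit$model$weights$E, before)
    # but the rest of the network did train
    expect_false(identical(fit$model$weights$Wx, model$weights$Wx))
  }
})

test_that("extract_embedding reflects mode and round-trips", {
  spec <- embedding_spec("learned", dim = 6, seed = 4)
  model <- build_lstm_model(spec, lstm_config(epochs = 1), seed = 1)
  enc <- extract_embedding(model)
  expect_identical(unname(enc$values), model$weights$E)
  expect_identical(unname(enc$values), unname(init_learned(6, 4)$values))
  data <- acceptance_hla_data()
  small_tr <- prepared_dataset(data$train$inputs[1:200, ],
                               data$train$targets[1:200])
  vmodel <- build_lstm_model(embedding_spec("frozen", "vhse8"),
                             lstm_config(epochs = 2), seed = 1)
  vfit <- train_model(vmodel, small_tr, data$val, epochs = 2, seed = 1)
  expect_identical(unname(extract_embedding(vfit$model)$values),
                   unname(build_vhse8()$values))
  tmp <- tempfile(fileext = ".tsv")
  save_matrix(enc, tmp)
  expect_lt(max(abs(load_matrix(tmp)$values - enc$values)), 1e-12)
})

test_that("the Siamese model shares branch weights and respects order symmetry", {
  cfg <- tiny_ppi_config()
  data <- aabench:::.ppi_data(cfg)
  spec <- embedding_spec("learned", dim = 6, seed = 3)
  model <- build_siamese_ppi_model(spec, tiny_siamese_config(combiner = "symmetric"),
                                   seed = 3)
  a <- data$train$inputs$a[1:8, , drop = FALSE]
  b <- data$train$inputs$b[1:8, , drop = FALSE]
  # one shared encoder: the same protein gives the same vector wherever fed
  ea <- aabench:::cpp_siamese_encode(model$weights, a)
  ea2 <- aabench:::cpp_siamese_encode(model$weights, a)
  expect_identical(ea, ea2)
  # symmetric combiner: swapping the inputs leaves predictions unchanged
  p_ab <- predict_model(model, list(a, b))
  p_ba <- predict_model(model, list(b, a))
  expect_identical(p_ab, p_ba)
  expect_true(all(p_ab > 0 & p_ab < 1))
  # four convolution modules are present
  expect_length(model$weights$Wc, 4L)
})

test_that("Siamese training learns the motif rule on a tiny world", {
  cfg <- tiny_ppi_config()
  data <- aabench:::.ppi_data(cfg)
  spec <- embedding_spec("learned", dim = 8, seed = 2)
  model <- build_siamese_ppi_model(spec, tiny_siamese_config(epochs = 4),
                                   seed = 2)
  before <- model$weights$E
  fit <- train_model(model, data$train, data$train, epochs = 4, seed = 2)
  h <- as.data.frame(fit$history)
  tl <- h$value[h$split == "train" & h$metric == "loss"]
  expect_lt(tl[4], tl[1])  # loss decreases
  expect_false(identical(fit$model$weights$E, before))
  # frozen variant leaves the embedding untouched
  fspec <- embedding_spec("frozen", "random_frozen", dim = 8, seed = 21)
  fmodel <- build_siamese_ppi_model(fspec, tiny_siamese_config(epochs = 2),
                                    seed = 2)
  fbefore <- fmodel$weights$E
  ffit <- train_model(fmodel, data$train, data$train, epochs = 2, seed = 2)
  expect_identical(ffit$model$weights$E, fbefore)
})

test_that("adequate capacity reaches AUC > 0.9 on noiseless peptides", {
  # generator learnability contract: 3-seed majority, desk-scale epochs
  wins <- 0L
  for (s in 1:3) {
    run <- hla_run("one_hot", seed = s, epochs = 60L, noise_sd = 0)
    if (run$best_auc > 0.9) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
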