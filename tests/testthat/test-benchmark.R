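test_that("per-cell seeds are stable, positive and coordinate-sensitive", {
  s1 <- derive_seed(1, "hla", "lstm", "one_hot", 20, 1, 1)
  expect_identical(s1, derive_seed(1, "hla", "lstm", "one_hot", 20, 1, 1))
  expect_false(s1 == derive_seed(1, "hla", "lstm", "one_hot", 20, 1, 2))
  expect_false(s1 == derive_seed(2, "hla", "lstm", "one_hot", 20, 1, 1))
  expect_true(s1 >= 1 && s1 < 2^31)
})

test_that("grid configs validate axes and collapse dims for classical schemes", {
  expect_error(grid_config("hla", "siamese_cnn"), "not valid")
  expect_error(grid_config("ppi", "lstm"), "not valid")
  sd <- aabench:::.scheme_dim_grid(c("one_hot", "vhse8", "learned"),
                                   c(2L, 4L))
  labels <- vapply(sd, function(x) paste(x$scheme, x$dim), character(1))
  expect_setequal(labels, c("one_hot 20", "vhse8 8", "learned 2", "learned 4"))
})

test_that("run_grid executes every cell, deterministically and resumably", {
  data_cfg <- hla_synthetic_config(n = 250L, data_seed = 99L)
  grid <- grid_config("hla", "lstm", schemes = c("one_hot", "learned"),
                      dims = 2L, fractions = c(0.5, 1.0), repetitions = 2L,
                      epochs = 2L, base_seed = 7L, data = data_cfg)
  out <- run_grid(grid)
  # 2 scheme-cells x 2 fractions x 2 reps = 8 runs, 3 series x 2 epochs each
  expect_identical(nrow(out), 8L * 6L)
  expect_true(all(is.na(out$error)))
  expect_true(all(is.finite(out$value)))
  expect_setequal(unique(out$metric),
                  c("train_loss", "validation_loss", "validation_val_auc"))
  out2 <- run_grid(grid)
  expect_identical(out$value, out2$value)

  # resumability: interrupt after the first half of the cells
  d1 <- tempfile(); d2 <- tempfile()
  full <- run_grid(grid, out_dir = d1)
  cells <- unique(full$cell)
  dir.create(d2)
  file.copy(file.path(d1, "results.csv"), file.path(d2, "results.csv"))
  writeLines(cells[1:4],  file.path(d2, "manifest.txt"))
  # truncate results to the first 4 cells, as if the run had been killed
  part <- full[full$cell %in% cells[1:4], ]
  utils::write.table(part, file.path(d2, "results.csv"), sep = ",",
                     row.names = FALSE)
  resumed <- run_grid(grid, out_dir = d2, resume = TRUE)
  expect_identical(resumed$value, full$value)
  expect_identical(resumed$cell, full$cell)
})

test_that("learned-vs-classical comparison emits one curve per scheme", {
  cfg <- hla_synthetic_config(n = 250L, data_seed = 42L)
  r <- experiment_fig1(cfg, dims = 2L, epochs = 2L, seed = 1,
                       schemes = c("one_hot", "vhse8", "learned"))
  curves <- r$curves
  key <- unique(paste(curves$scheme, curves$dim))
  expect_setequal(key, c("one_hot 20", "vhse8 8", "learned 2"))
  expect_true(all(curves$value >= 0 & curves$value <= 1))
  expect_identical(nrow(r$best), 3L)
})

test_that("random-frozen dimension sweep produces a curve per dimension", {
  cfg <- hla_synthetic_config(n = 250L, data_seed = 43L)
  r <- experiment_fig4(cfg, dims = c(1L, 4L), epochs = 2L, seeds = 1:2)
  expect_setequal(unique(r$curves$dim), c(1L, 4L))
  expect_identical(nrow(r$summary), 2L)
  expect_identical(r$summary$n, c(2L, 2L))
  expect_true(all(r$curves$value >= 0 & r$curves$value <= 1))
})

test_that("fraction sweep summarizes mean and sd from exactly n repetitions", {
  cfg <- tiny_ppi_config()
  r <- experiment_fig2(cfg, schemes = "learned", dims = 4L,
                       fractions = c(0.5, 1.0), repetitions = 2L,
                       epochs = 2L, seed = 3)
  expect_identical(nrow(r$summary), 2L)
  expect_identical(r$summary$n, c(2L, 2L))
  expect_true(all(!is.na(r$summary$sd_accuracy)))
  expect_true(all(r$summary$mean_accuracy >= 0 &
                    r$summary$mean_accuracy <= 1))
})

test_that("embedding analysis chains distances, clustering and cohesion", {
  a <- analyze_embedding(build_vhse8(), n_permutations = 199, seed = 1)
  expect_gt(a$cohesion$statistic, 0)
  expect_identical(rownames(a$distance), aa_alphabet())
  oh <- analyze_embedding(build_one_hot(), n_permutations = 199, seed = 1)
  expect_equal(oh$cohesion$statistic, 0)  # equidistant rows
  off <- unclass(oh$distance)[-1, -1][upper.tri(diag(20))]
  expect_true(all(abs(off - sqrt(2)) < 1e-12))
  # full report written with all 21 tokens, pad included
  outd <- tempfile()
  m <- analyze_embedding(build_vhse8(), n_permutations = 99, seed = 1,
                         out_dir = outd)
  rep <- jsonlite::read_json(file.path(outd, "cohesion.json"))
  expect_length(rep$tokens, 21L)
  expect_true(file.exists(file.path(outd, "distance.tsv")))
  expect_true(file.exists(file.path(outd, "dendrogram.nwk")))
  # a matrix file path is a valid analysis input
  tmp <- tempfile(fileext = ".tsv")
  save_matrix(build_vhse8(), tmp)
  a2 <- analyze_embedding(tmp, n_permutations = 199, seed = 1)
  expect_equal(a2$cohesion$statistic, a$cohesion$statistic)
})

test_that("the CLI runs its simulate and analyze subcommands", {
  outd <- tempfile()
  suppressMessages(
    bench_cli(c("simulate-hla", "--n", "30", "--seed", "4",
                "--out-dir", outd)))
  f <- file.path(outd, "peptides.tsv")
  expect_true(file.exists(f))
  expect_identical(nrow(read_peptide_dataset(f)), 30L)
  tmp <- tempfile(fileext = ".tsv")
  save_matrix(build_vhse8(), tmp)
  outd2 <- tempfile()
  suppressMessages(
    bench_cli(c("analyze-embedding", "--input", tmp, "--out-dir", outd2)))
  expect_true(file.exists(file.path(outd2, "cohesion.json")))
  expect_error(suppressMessages(bench_cli("frobnicate")), "unknown subcommand")
})
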