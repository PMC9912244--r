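test_that("model topology matches the published architecture and scales sanely", {
  m <- build_crnn(model_config(seed = 1), L = 30L)
  arch <- model_architecture(m)
  expect_equal(sum(arch$layer == "conv" & arch$branch == "seq"), 2L)
  expect_equal(sum(arch$layer == "conv" & arch$branch == "struct"), 2L)
  g <- glance(m)
  expect_equal(g$conv_layers_per_branch, 2L)
  expect_equal(g$n_branches, 2L)
  expect_false(g$trained)
  expect_lt(g$n_parameters, 1e6)

  bigger <- build_crnn(model_config(dense_units = 128L, seed = 1), L = 30L)
  expect_gt(n_parameters(bigger), n_parameters(m))

  expect_error(build_crnn(model_config(conv_kernel = 20L), L = 30L), "too large")
})

test_that("scores are bounded, batch-order invariant and only available after training", {
  tc <- trained_crnn()
  m <- tc$model
  expect_error(predict_deep_score(build_crnn(model_config(), 30L), tc$enc), "untrained")

  p <- predict_deep_score(m, tc$enc)
  expect_true(all(p >= 0 & p <= 1))

  set.seed(3)
  perm <- sample(length(p))
  pp <- predict_deep_score(m, cas13design:::slice_inputs(tc$enc, perm))
  expect_equal(pp, p[perm], tolerance = 1e-6)
  # single-guide prediction equals batched prediction
  one <- predict_deep_score(m, cas13design:::slice_inputs(tc$enc, 5L))
  expect_equal(one, p[5], tolerance = 1e-6)
})

test_that("training reduces loss on planted signal and is exactly reproducible", {
  tc <- trained_crnn()
  h <- tidy(tc$model)
  expect_equal(nrow(h), 15L)
  expect_lt(h$mse[nrow(h)], h$mse[1])

  # same seed, same data: identical predictions
  cfg <- model_config(conv_filters = 8L, recurrent_units = 8L, dense_units = 8L,
                      seed = 33L, batch_size = 32L)
  sub <- cas13design:::slice_inputs(tc$enc, 1:120)
  y <- tc$y[1:120]
  m1 <- fit_crnn(build_crnn(cfg, 30L), sub, y, epochs = 3L)
  m2 <- fit_crnn(build_crnn(cfg, 30L), sub, y, epochs = 3L)
  expect_equal(predict_deep_score(m1, sub), predict_deep_score(m2, sub),
               tolerance = 1e-3)
  expect_identical(m1$history, m2$history)
})

test_that("a small network memorises a tiny dataset", {
  tc <- trained_crnn()
  sub <- cas13design:::slice_inputs(tc$enc, 1:20)
  y <- tc$y[1:20]
  cfg <- model_config(conv_filters = 16L, recurrent_units = 16L, dense_units = 16L,
                      dropout_conv = 0, dropout_lstm = 0, seed = 9L,
                      batch_size = 20L, learning_rate = 3e-3)
  m <- suppressWarnings(fit_crnn(build_crnn(cfg, 30L), sub, y, epochs = 500L))
  expect_lt(m$history$mse[500], 0.01)
})

test_that("trained scores separate efficient from inefficient planted guides", {
  tc <- trained_crnn()
  pg <- planted_guides()
  p <- predict_deep_score(tc$model, tc$enc)
  qs <- quantile(pg$efficiency, c(0.1, 0.9))
  expect_gt(mean(p[pg$efficiency >= qs[2]]), mean(p[pg$efficiency <= qs[1]]))
})

test_that("the structure branch adds signal when the planted driver is structural", {
  cfg <- sim_config(n_genes = 20L, guides_per_gene = 30L, frac_essential = 0.95,
                    n_nontargeting = 0L, seed = 88L)
  guides <- simulate_guides(cfg)
  guides <- guides[guides$essential, ]
  folds <- fold_guides(guides$spacer, engine = "maxpair")
  eff <- planted_efficiency(guides$spacer, folds, weights = c(0, 8, 0))  # structure only
  set.seed(4)
  lfc <- -3 * eff + rnorm(nrow(guides), 0, 0.3)
  y <- lfc_to_target(lfc)
  enc <- encode_guide_set(guides$spacer, L = 30L, folds = folds)
  n <- nrow(guides)
  set.seed(10); test_idx <- sample(n, 150L); train_idx <- setdiff(seq_len(n), test_idx)
  pos <- lfc[test_idx] <= -0.5

  train_eval <- function(use_structure) {
    cfgm <- model_config(conv_filters = 16L, recurrent_units = 32L, dense_units = 32L,
                         seed = 11L, use_structure = use_structure)
    m <- build_crnn(cfgm, 30L)
    m <- fit_crnn(m, cas13design:::slice_inputs(enc, train_idx), y[train_idx],
                  epochs = 10L)
    auc_score(predict_deep_score(m, cas13design:::slice_inputs(enc, test_idx)), pos)
  }
  expect_gt(train_eval(TRUE), train_eval(FALSE))
})

test_that("grid search covers the cartesian product and is reproducible", {
  tc <- trained_crnn()
  sub <- cas13design:::slice_inputs(tc$enc, 1:150)
  y <- tc$y[1:150]
  grid <- list(dense_units = c(8L, 16L), dropout_conv = c(0, 0.5),
               optimizer = "adam", learning_rate = 1e-3)
  base <- model_config(conv_filters = 8L, recurrent_units = 8L, batch_size = 32L)
  tg <- tune_grid(grid, sub, y, seed = 2L, epochs = 2L, base_config = base)
  expect_equal(nrow(tg$results), 4L)
  tg2 <- tune_grid(grid, sub, y, seed = 2L, epochs = 2L, base_config = base)
  expect_identical(tg$best_config, tg2$best_config)
  expect_error(tune_grid(list(dense_units = integer(0), dropout_conv = 0,
                              optimizer = "adam", learning_rate = 1e-3),
                         sub, y), "non-empty")

  # a degenerate learning rate ranks below a sane one
  sub2 <- cas13design:::slice_inputs(tc$enc, 1:300)
  grid2 <- list(dense_units = 16L, dropout_conv = 0.5, optimizer = "adam",
                learning_rate = c(1e-3, 10))
  tg3 <- tune_grid(grid2, sub2, tc$y[1:300], seed = 3L, epochs = 8L,
                   base_config = base)
  expect_equal(tg3$best_config$learning_rate, 1e-3)
})

test_that("non-finite loss aborts with diagnostics", {
  tc <- trained_crnn()
  sub <- cas13design:::slice_inputs(tc$enc, 1:150)
  y_bad <- tc$y[1:150]
  y_bad[3] <- NaN
  cfg <- model_config(conv_filters = 8L, recurrent_units = 8L, dense_units = 8L,
                      batch_size = 150L, seed = 5L)
  expect_error(fit_crnn(build_crnn(cfg, 30L), sub, y_bad, epochs = 2L),
               "NaN/Inf loss")
})
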