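test_that("a zero path gives exactly zero attributions", {
  tc <- trained_crnn()
  g <- encode_guide(tc$guides$spacer[1],
                    list(dot_bracket = nussinov_fallback(tc$guides$spacer[1])$dot_bracket),
                    L = 30L)
  m <- integrated_gradients(tc$model, g, baseline = g, steps = 8L)
  expect_true(all(m$seq == 0))
  expect_true(all(m$struct == 0))
  expect_equal(m$completeness_residual, 0, tolerance = 1e-12)
})

test_that("IG on a linear model equals weight times input difference for any steps", {
  set.seed(2)
  W <- matrix(rnorm(30 * 4), 30, 4)
  model <- linear_surrogate(W, b = 0.7)
  s <- random_rna(1, 22, seed = 3)
  g <- encode_guide(s, nussinov_fallback(s), L = 30L)
  closed_form <- W * g$seq_onehot
  for (steps in c(2L, 5L, 64L)) {
    m <- integrated_gradients(model, g, steps = steps)
    expect_equal(m$seq, closed_form, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(m$completeness_residual, 0, tolerance = 1e-9)
  }
  expect_error(integrated_gradients(model, g, steps = 1L), "at least 2")
})

test_that("completeness residual vanishes with the step count on the trained model", {
  tc <- trained_crnn()
  # use the top-scoring guide so |F(x) - F(baseline)| is comfortably non-zero
  p <- predict_deep_score(tc$model, tc$enc)
  s <- tc$guides$spacer[which.max(p)]
  g <- encode_guide(s, nussinov_fallback(s), L = 30L)

  maps <- lapply(c(8L, 32L, 256L), function(st) integrated_gradients(tc$model, g, steps = st))
  res <- vapply(maps, function(m) m$completeness_residual, numeric(1))
  gap <- abs(maps[[3]]$input_score - maps[[3]]$baseline_score)
  expect_lt(res[3], res[1] + 1e-12)          # halving-step convergence trend
  expect_lte(res[3], 0.01 * gap)             # 1% completeness at 256 steps
})

test_that("attributions at padded positions are exactly zero", {
  tc <- trained_crnn()
  s <- tc$guides$spacer[2]
  g <- encode_guide(s, nussinov_fallback(s), L = 30L)
  m <- integrated_gradients(tc$model, g, steps = 16L)
  pad <- which(g$mask == 0)
  expect_true(all(m$seq[pad, ] == 0))
  expect_true(all(m$struct[pad, ] == 0))
})

test_that("position importance summarises observed-channel attributions", {
  tc <- trained_crnn()
  s <- tc$guides$spacer[3]
  g <- encode_guide(s, nussinov_fallback(s), L = 30L)
  m <- integrated_gradients(tc$model, g, steps = 16L)

  one <- position_importance(list(m))
  obs <- g$seq_onehot == 1
  expect_equal(one[obs], m$seq[obs], ignore_attr = TRUE)
  expect_true(all(one[!obs] == 0))

  norm <- position_importance(list(m, m), normalize = TRUE)
  expect_equal(sum(abs(norm)), 1, tolerance = 1e-9)
  expect_error(position_importance(list()), "no attribution maps")
})

test_that("the model attributes the planted C/G 15-23 preference", {
  tc <- trained_crnn()
  idx <- seq_len(120)
  maps <- lapply(idx, function(i) {
    s <- tc$guides$spacer[i]
    g <- encode_guide(s, nussinov_fallback(s), L = 30L)
    integrated_gradients(tc$model, g, steps = 24L)
  })
  imp <- position_importance(maps)
  win <- 15:22  # planted window clipped to the 22-nt spacers
  cg <- mean(imp[win, c("C", "G")])
  au <- mean(imp[win, c("A", "U")])
  expect_gt(cg, au)
})

test_that("tidy attribution summaries are well-formed", {
  tc <- trained_crnn()
  s <- tc$guides$spacer[4]
  g <- encode_guide(s, nussinov_fallback(s), L = 30L)
  m <- integrated_gradients(tc$model, g, steps = 8L)
  td <- tidy(position_importance(list(m)))
  expect_equal(nrow(td), 120L)
  expect_setequal(unique(td$nucleotide), c("A", "C", "G", "U"))
})
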