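test_that("strong-depletion labels take the exact lowest quantile with stable ties", {
  g <- tibble::tibble(guide_id = sprintf("g%03d", 1:100), lfc = seq(-2, 2, length.out = 100))
  lab <- make_depletion_labels(g, 0.25)
  expect_equal(sum(lab$strong), 25L)
  expect_true(all(lab$lfc[lab$strong] < lab$lfc[!lab$strong][1]))

  g8 <- tibble::tibble(guide_id = letters[1:8], lfc = c(-3, -2, -1, 0, 1, 2, 3, 4))
  expect_equal(sum(make_depletion_labels(g8, 0.25)$strong), 2L)

  tied <- tibble::tibble(guide_id = c("b", "a", "c", "d", "e", "f", "g", "h"),
                         lfc = c(-1, -1, 0, 0, 1, 1, 2, 2))
  lab2 <- make_depletion_labels(tied, 0.25)
  expect_setequal(lab2$guide_id[lab2$strong], c("a", "b"))  # (lfc, guide_id) order

  flat <- tibble::tibble(guide_id = letters[1:10], lfc = rep(1, 10))
  expect_error(make_depletion_labels(flat), "degenerate")
  expect_error(make_depletion_labels(g[1:5, ]), "at least 8")
})

test_that("off-target labels refuse essential-gene contamination", {
  g <- tibble::tibble(guide_id = sprintf("g%03d", 1:20),
                      gene = rep(c("NE1", "ESS1"), each = 10),
                      lfc = rnorm(20))
  expect_error(make_offtarget_labels(g, essential_genes = "ESS1"), "essential")
  ok <- make_offtarget_labels(g[g$gene == "NE1", ], essential_genes = "ESS1")
  expect_equal(sum(ok$strong), 2L)
})

test_that("random-forest importances are normalised and recover a planted driver", {
  scr <- default_screen()
  keep <- which(!scr$guides$essential & scr$guides$target_type == "mRNA")[1:400]
  g <- scr$guides[keep, ]
  fm <- extract_feature_matrix(g, dr = synthetic_dr(), engine = "maxpair",
                               folds = scr$folds[keep, ])
  X <- as.matrix(fm[-1])
  # labels driven solely by the spacer folding energy
  energy <- X[, "energy"]
  labels <- energy <= quantile(energy, 0.25)
  fit <- fit_offtarget_rf(X, labels, seed = 3)
  expect_equal(sum(fit$importance), 1, tolerance = 1e-9)
  expect_identical(names(fit$importance), canonical_feature_names())
  # energy (or its exact per-nt rescaling, collinear at fixed guide length)
  # must dominate every other feature
  top2 <- names(sort(fit$importance, decreasing = TRUE))[1:2]
  expect_true("energy" %in% top2 || "energy_per_nt" %in% top2)
  others <- setdiff(canonical_feature_names(),
                    c("energy", "energy_per_nt", "paired_frac", "max_stem_len",
                      "n_hairpins", "paired_pos01"))
  expect_gt(fit$importance["energy"] + fit$importance["energy_per_nt"],
            max(fit$importance[others]))
})

test_that("pure-noise labels spread importance thinly", {
  scr <- default_screen()
  keep <- which(!scr$guides$essential & scr$guides$target_type == "mRNA")[1:120]
  fm <- extract_feature_matrix(scr$guides[keep, ], dr = synthetic_dr(),
                               engine = "maxpair", folds = scr$folds[keep, ])
  X <- as.matrix(fm[-1])
  # ~45 of the 185 features are (near-)constant indicators with zero
  # importance, so even under the null the max sits around 4-6x the grand
  # mean (null simulation); a planted driver concentrates >30x. The bound
  # below separates the regimes.
  ok <- vapply(1:20, function(s) {
    set.seed(5000 + s)
    labels <- sample(rep(c(TRUE, FALSE), c(30, 90)))
    fit <- fit_offtarget_rf(X, labels, seed = s, ntree = 200)
    imp <- fit$importance
    max(imp) < 10 * mean(imp)
  }, logical(1))
  expect_gte(sum(ok), 16)
})

test_that("importance correlation handles identity, reversal and degeneracy", {
  v <- setNames(c(0.5, 0.3, 0.2), c("f1", "f2", "f3"))
  expect_equal(importance_correlation(v, v), 1)
  rev_v <- setNames(rev(unname(v)), names(v))
  expect_lt(importance_correlation(v, rev_v), 0)
  z <- setNames(rep(1 / 3, 3), names(v))
  expect_warning(out <- importance_correlation(v, z), "zero-variance")
  expect_true(is.na(out))
  expect_error(importance_correlation(v, setNames(unname(v), c("a", "b", "c"))),
               "canonical")
})

test_that("feature weights are consistent across independent screens", {
  fit_one <- function(seed) {
    cfg <- sim_config(n_genes = 40L, guides_per_gene = 30L, frac_essential = 0.1,
                      offtarget_coupling = 0.8, n_nontargeting = 0L, seed = seed)
    scr <- simulate_full_screen(cfg)
    keep <- !scr$guides$essential
    g <- scr$guides[keep, ]
    g$lfc <- scr$truth$realized_lfc[keep]
    lab <- make_offtarget_labels(g, essential_genes = unique(scr$guides$gene[scr$guides$essential]))
    fm <- extract_feature_matrix(g, dr = synthetic_dr(), engine = "maxpair",
                                 folds = scr$folds[keep, ])
    fit_offtarget_rf(as.matrix(fm[-1]), lab$strong, seed = seed)
  }
  f1 <- fit_one(71)
  f2 <- fit_one(72)
  expect_gt(importance_correlation(f1, f2), 0.5)
})
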