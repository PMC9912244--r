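test_that("fold assignment is a balanced partition, optionally gene-grouped", {
  f <- kfold_assign(103, k = 5, seed = 1)
  expect_setequal(as.integer(names(table(f))), 1:5)
  expect_setequal(as.integer(table(f)), c(21, 21, 21, 20, 20))

  genes <- rep(paste0("g", 1:20), each = 5)
  fg <- kfold_assign(100, k = 5, genes = genes, seed = 2)
  per_gene <- tapply(fg, genes, function(x) length(unique(x)))
  expect_true(all(per_gene == 1))
  expect_error(kfold_assign(3, k = 5), "must not exceed")
})

test_that("kfold predictions cover every guide exactly once out of fold", {
  d <- tibble::tibble(x = rnorm(50), lfc = rnorm(50))
  out <- kfold_predictions(
    d,
    fit_fun = function(tr) lm(lfc ~ x, data = tr),
    predict_fun = function(m, te) predict(m, te),
    k = 5, seed = 3
  )
  expect_false(anyNA(out$prediction))
  expect_equal(sort(unique(out$fold)), 1:5)
})

test_that("rank AUC agrees with trapezoidal ROC integration and pROC", {
  set.seed(8)
  score <- rnorm(200)
  pos <- rbinom(200, 1, plogis(score)) == 1
  # independent oracle 1: explicit trapezoidal ROC integration
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(score[pos] >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(score[!pos] >= t), numeric(1)))
  trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(auc_score(score, pos), trap, tolerance = 1e-9)
  # independent oracle 2: pROC
  expect_equal(auc_score(score, pos),
               as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("AUPR behaves at the extremes and matches prevalence for random scores", {
  pos <- c(rep(TRUE, 20), rep(FALSE, 80))
  perfect <- as.numeric(pos)
  expect_equal(aupr_score(perfect, pos), 1)
  expect_gte(aupr_score(perfect, pos), mean(pos) - 1e-9)
  set.seed(4)
  vals <- vapply(1:50, function(i) aupr_score(rnorm(100), pos), numeric(1))
  expect_lt(abs(mean(vals) - 0.2), 0.05)
})

test_that("metrics capture perfect anti-correlation and degenerate predictors", {
  lfc <- seq(-2, 1, length.out = 40)
  m <- compute_metrics(-lfc, lfc)
  expect_equal(m$pcc, -1)
  expect_equal(m$auc, 1)
  expect_equal(m$positives, sum(lfc <= -0.5))

  mc <- compute_metrics(rep(0.5, 40), lfc)
  expect_lte(mc$r2, 0)
  expect_equal(mc$auc, 0.5)   # midrank tie convention
  expect_true(is.na(mc$pcc))
})

test_that("random scores against random labels give chance AUC", {
  set.seed(12)
  aucs <- vapply(1:50, function(i) {
    auc_score(rnorm(2000), rbinom(2000, 1, 0.3) == 1)
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("top-fraction gene evaluation filters genes and recovers buried signal", {
  set.seed(21)
  n_genes <- 100; gpg <- 10
  gene <- rep(sprintf("g%03d", 1:n_genes), each = gpg)
  responsive <- gene %in% sprintf("g%03d", 1:10)
  eff <- runif(n_genes * gpg)
  lfc <- ifelse(responsive, -2 * eff, 0) + rnorm(n_genes * gpg, 0, 0.3)
  rank_table <- tibble::tibble(gene = sprintf("g%03d", 1:n_genes), rank = 1:n_genes)

  all_eval <- topfrac_gene_eval(eff, lfc, gene, rank_table, fraction = 1)
  expect_equal(all_eval$genes_kept, 100L)
  global <- compute_metrics(eff, lfc)
  expect_equal(all_eval$aupr, global$aupr)

  top10 <- topfrac_gene_eval(eff, lfc, gene, rank_table, fraction = 0.1)
  expect_equal(top10$genes_kept, 10L)
  expect_gt(top10$aupr, all_eval$aupr)

  topn <- topfrac_gene_eval(eff, lfc, gene, rank_table, top_n = 25)
  expect_equal(topn$genes_kept, 25L)
  expect_error(topfrac_gene_eval(eff, lfc, gene, rank_table, fraction = 0.001),
               "zero genes")
})

test_that("top/bottom filtering keeps each gene's extremes, deduplicated", {
  d <- tibble::tibble(gene = rep(c("a", "b"), c(30, 6)),
                      lfc = c(rnorm(30), rnorm(6)))
  out <- top_bottom_filter(d, 4)
  expect_equal(sum(out$gene == "a"), 8L)
  expect_equal(sum(out$gene == "b"), 6L)
  a <- d$lfc[d$gene == "a"]
  expect_setequal(out$lfc[out$gene == "a"], c(sort(a)[1:4], sort(a, TRUE)[1:4]))
})

test_that("dataset transfer generalises planted signal across synthetic sources", {
  build_source <- function(seed, n = 250) {
    cfg <- sim_config(n_genes = 5L, guides_per_gene = 50L, frac_essential = 0.8,
                      n_nontargeting = 0L, seed = seed)
    scr <- simulate_full_screen(cfg)
    keep <- scr$guides$essential
    g <- scr$guides[keep, ]
    g$lfc <- scr$truth$realized_lfc[keep]
    fm <- extract_feature_matrix(g, dr = synthetic_dr(), engine = "maxpair",
                                 folds = scr$folds[keep, ])
    g$source <- paste0("s", seed)
    g$gene <- paste0(g$gene, "_s", seed)   # sources are distinct gene spaces
    dplyr::bind_cols(g, fm[-1])
  }
  data <- dplyr::bind_rows(build_source(61), build_source(62))
  feat_cols <- canonical_feature_names()
  fit_fun <- function(tr) suppressWarnings(
    train_baseline("RF", as.matrix(tr[feat_cols]), lfc_to_target(tr$lfc), seed = 5))
  predict_fun <- function(m, te) predict(m, as.matrix(te[feat_cols]))

  expect_error(
    dataset_transfer(data[data$source == "s61", ], fit_fun, predict_fun,
                     mode = "leave_one_dataset_out"),
    "at least two")

  res <- dataset_transfer(data, fit_fun, predict_fun, mode = "leave_one_dataset_out",
                          top_bottom = NULL)
  expect_equal(nrow(res$metrics), 2L)
  expect_true(all(res$metrics$auc > 0.7))

  # per-gene extreme filtering before evaluation
  filtered <- dataset_transfer(data, fit_fun, predict_fun, mode = "mixed_cv",
                               top_bottom = 4L, k = 3, seed = 2)
  expect_equal(nrow(filtered$predictions), 64L)  # 2 sources x 4 genes x 8 extremes
})
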