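toy_screen <- function(counts, genes = NULL, annot = NULL) {
  n <- nrow(counts)
  rownames(counts) <- sprintf("g%03d", seq_len(n))
  colnames(counts) <- c("t0_r1", "t1_r1")
  roles <- c(t0_r1 = "t0", t1_r1 = "t1")
  if (is.null(annot)) annot <- setNames(rep("other", n), rownames(counts))
  guides <- tibble::tibble(guide_id = rownames(counts),
                           gene = genes %||% rownames(counts))
  screen_matrix(counts, roles, annot, guides)
}

test_that("median-ratio size factors respond to scale and control subsetting", {
  set.seed(1)
  base <- rpois(200, 500) + 1L
  scr <- toy_screen(cbind(base, base))
  nm <- normalize_counts(scr, "none")
  expect_equal(unname(nm$size_factors), c(1, 1))

  scr2 <- toy_screen(cbind(base, 2L * base))
  nm2 <- normalize_counts(scr2, "none")
  expect_equal(unname(nm2$size_factors[2] / nm2$size_factors[1]), 2)

  # scale equivariance of the factor ratio: scaling one sample by c
  # scales its factor relative to the others by c (the geometric-mean
  # reference absorbs an overall c^(1/m))
  scr3 <- toy_screen(cbind(base, 3L * base))
  f3 <- normalize_counts(scr3, "none")$size_factors
  expect_equal(unname(f3[2] / f3[1]), 3 * unname(nm$size_factors[2] / nm$size_factors[1]))

  # factors depend only on the control subset
  annot <- setNames(rep(c("non_essential_target", "other"), each = 100),
                    sprintf("g%03d", 1:200))
  scr4 <- toy_screen(cbind(base, base + 0L), annot = annot)
  f1 <- normalize_counts(scr4, "non_essential")$size_factors
  perturbed <- cbind(base, base + 0L)
  perturbed[101:200, 2] <- perturbed[101:200, 2] * 7L
  scr5 <- toy_screen(perturbed, annot = annot)
  f2 <- normalize_counts(scr5, "non_essential")$size_factors
  expect_equal(f1, f2)

  expect_error(normalize_counts(scr, "non_targeting"), "no guides annotated")
})

test_that("median-ratio factors agree with the DESeq estimator", {
  set.seed(2)
  counts <- matrix(rnbinom(400 * 4, mu = 300, size = 10) + 1L, 400, 4)
  rownames(counts) <- sprintf("g%03d", 1:400)
  colnames(counts) <- c("t0_r1", "t0_r2", "t1_r1", "t1_r2")
  scr <- screen_matrix(counts, c(t0_r1 = "t0", t0_r2 = "t0", t1_r1 = "t1", t1_r2 = "t1"),
                       setNames(rep("other", 400), rownames(counts)))
  ours <- normalize_counts(scr, "none")$size_factors
  deseq <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(deseq), tolerance = 1e-4)
})

test_that("guide LFC is the pseudocounted log-ratio of time-point means", {
  m <- matrix(c(100, 100, 0, 400, 100, 0), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("t0_r1", "t1_r1")))
  lfc <- guide_lfc(m, c(t0_r1 = "t0", t1_r1 = "t1"), pseudocount = 1)
  expect_equal(unname(lfc[2]), 0)
  expect_equal(unname(lfc[1]), log2(401 / 101))
  expect_true(is.finite(lfc[3]) && lfc[3] == 0)

  m2 <- matrix(c(1000, 0), 1, dimnames = list("a", c("t0_r1", "t1_r1")))
  lfc2 <- guide_lfc(m2, c(t0_r1 = "t0", t1_r1 = "t1"))
  expect_true(is.finite(lfc2) && lfc2 < -9)
})

test_that("extreme genes reach the minimum attainable permutation p-value", {
  set.seed(5)
  lfc <- rnorm(500)
  gene <- rep(NA_character_, 500)
  gene[order(lfc)[1:5]] <- "worst"
  fillers <- setdiff(seq_len(500), order(lfc)[1:5])[1:45]
  gene[fillers] <- rep(sprintf("null%02d", 1:9), each = 5)
  d <- tibble::tibble(gene = gene, lfc = lfc)
  res <- gene_negative_selection(d, n_perm = 1000, seed = 1)
  expect_equal(res$p[res$gene == "worst"], 1 / 1001)
  expect_error(gene_negative_selection(d, n_perm = 50), "at least 100")
})

test_that("duplicated guide sets give identical scores and compatible p-values", {
  set.seed(6)
  lfc <- rnorm(300)
  gene <- c(rep("a", 5), rep("b", 5), rep(NA, 290))
  lfc[6:10] <- lfc[1:5]                      # gene b duplicates gene a's LFCs
  d <- tibble::tibble(gene = gene, lfc = lfc)
  res <- gene_negative_selection(d, n_perm = 2000, seed = 2)
  expect_equal(res$score[res$gene == "a"], res$score[res$gene == "b"])
  expect_equal(res$p[res$gene == "a"], res$p[res$gene == "b"], tolerance = 0.05)
})

test_that("permutation p-values are calibrated under the exchangeable null", {
  ks_ok <- vapply(1:20, function(s) {
    set.seed(s)
    n_genes <- 200; gpg <- 5
    d <- tibble::tibble(gene = rep(sprintf("g%03d", 1:n_genes), each = gpg),
                        lfc = rnorm(n_genes * gpg))
    res <- gene_negative_selection(d, n_perm = 2000, seed = 1000 + s)
    suppressWarnings(ks.test(res$p, "punif")$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(ks_ok), 18)

  # validity at conventional levels: P(p <= alpha) <= alpha + MC tolerance
  set.seed(99)
  d <- tibble::tibble(gene = rep(sprintf("g%03d", 1:400), each = 5),
                      lfc = rnorm(2000))
  res <- gene_negative_selection(d, n_perm = 2000, seed = 7)
  for (alpha in c(0.05, 0.1)) {
    expect_lte(mean(res$p <= alpha), alpha + 0.035)
  }
})

test_that("the control benchmark orders control choices as the collateral model predicts", {
  scr <- default_screen()
  ess <- unique(scr$guides$gene[scr$guides$essential])
  ness <- unique(scr$guides$gene[scr$guides$target_type == "mRNA" & !scr$guides$essential])
  cb <- control_benchmark(scr, ess, ness, n_perm = 2000, seed = 5,
                          fdr_grid = c(0, 0.05, 0.1, 0.25))
  at <- function(ctrl, cut, what) cb[[what]][cb$control == ctrl & cb$fdr_cutoff == cut]

  # zero cutoff finds nothing
  for (ctrl in c("none", "non_targeting", "non_essential")) {
    expect_equal(at(ctrl, 0, "tpr"), 0)
    expect_equal(at(ctrl, 0, "fpr"), 0)
  }
  # non-targeting controls miss the collateral depletion shared by all
  # targeting guides and call non-essential genes as hits
  expect_gt(at("non_targeting", 0.1, "fpr"), at("non_essential", 0.1, "fpr"))
  # non-essential controls clean the null and improve sensitivity over no controls
  expect_gt(at("non_essential", 0.1, "tpr"), at("none", 0.1, "tpr"))
  # monotone in the cutoff
  for (ctrl in c("none", "non_targeting", "non_essential")) {
    expect_true(all(diff(cb$tpr[cb$control == ctrl]) >= 0))
    expect_true(all(diff(cb$fpr[cb$control == ctrl]) >= 0))
  }

  expect_error(control_benchmark(scr, ess, c(ness, ess[1])), "overlap")
})
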