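# Cross-validation and metrics. AUC uses the rank (Mann-Whitney) statistic
# with midrank tie handling; AUPR is the step-wise integral of the
# precision-recall curve (average-precision convention).

#' Area under the ROC curve (rank statistic, midrank ties)
#' @param score Numeric ranking scores (higher = predicted positive).
#' @param positive Logical labels.
#' @return AUC in \[0, 1\]; `NA` with a warning if only one class present.
#' @export
auc_score <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    warn("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#' @inheritParams auc_score
#' @return AUPR in \[0, 1\]; `NA` with a warning if no positives.
#' @export
aupr_score <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n_pos <- sum(positive)
  if (n_pos == 0L || all(positive)) {
    warn("AUPR undefined: only one class present")
    return(NA_real_)
  }
  ord <- order(score, decreasing = TRUE)
  y <- positive[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  # average precision: sum precision at each positive, over n_pos
  sum(precision[y]) / n_pos
}

#' Assign k-fold cross-validation folds
#'
#' Seeded shuffled assignment at guide level (fold sizes differ by at most
#' one) or grouped by gene so that no gene straddles folds.
#'
#' @param n Number of guides (guide grouping) — ignored when `genes` given.
#' @param k Number of folds.
#' @param genes Optional gene label per guide; when supplied, genes (not
#'   guides) are partitioned.
#' @param seed Seed.
#' @return Integer fold id (1..k) per guide.
#' @export
kfold_assign <- function(n, k = 5L, genes = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(genes)) {
    if (k > n) abort("k must not exceed the number of guides")
    sample(rep_len(seq_len(k), n))
  } else {
    u <- unique(genes)
    if (k > length(u)) abort("k must not exceed the number of genes")
    gf <- setNames(sample(rep_len(seq_len(k), length(u))), u)
    unname(gf[genes])
  }
}

#' Out-of-fold predictions by k-fold cross-validation
#'
#' Model-agnostic engine: every guide is predicted exactly once, by a model
#' whose training fold excluded it.
#'
#' @param data A data frame of guides (one row per guide).
#' @param fit_fun `function(train_data) -> model`.
#' @param predict_fun `function(model, test_data) -> numeric`.
#' @param k Number of folds.
#' @param grouping `"guide"` (balanced shuffle) or `"gene"` (genes never
#'   straddle folds; requires a `gene` column).
#' @param seed Seed for fold assignment.
#' @return `data` with columns `fold` and `prediction` appended.
#' @export
kfold_predictions <- function(data, fit_fun, predict_fun, k = 5L,
                              grouping = c("guide", "gene"), seed = 1L) {
  grouping <- match.arg(grouping)
  n <- nrow(data)
  folds <- if (grouping == "gene") {
    kfold_assign(n, k, genes = data$gene, seed = seed)
  } else {
    kfold_assign(n, k, seed = seed)
  }
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- fit_fun(data[!test, , drop = FALSE])
    pred[test] <- predict_fun(model, data[test, , drop = FALSE])
  }
  data$fold <- folds
  data$prediction <- pred
  data
}

#' Performance metrics of efficiency predictions against measured LFCs
#'
#' Computes R squared (of the prediction against the sigmoid-normalised
#' LFC target), the Pearson correlation between prediction and raw LFC
#' (expected negative: high scores should mean depletion), and AUC / AUPR
#' with guides at `lfc <= threshold` as positives.
#'
#' @param predictions Numeric scores (higher = predicted more effective).
#' @param lfcs Measured log2 fold changes.
#' @param threshold Positive-label LFC threshold (default -0.5).
#' @param params Sigmoid calibration for the R-squared target.
#' @return A one-row tibble: `r2`, `pcc`, `auc`, `aupr`, `n`, `positives`.
#' @export
compute_metrics <- function(predictions, lfcs, threshold = -0.5,
                            params = solve_sigmoid_params()) {
  stopifnot(length(predictions) == length(lfcs))
  keep <- !is.na(predictions) & !is.na(lfcs)
  predictions <- predictions[keep]; lfcs <- lfcs[keep]
  target <- lfc_to_target(lfcs, params)
  ss_res <- sum((predictions - target)^2)
  ss_tot <- sum((target - mean(target))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  pcc <- if (sd(predictions) == 0 || sd(lfcs) == 0) NA_real_ else cor(predictions, lfcs)
  pos <- label_positive(lfcs, threshold)
  tibble(
    r2 = r2, pcc = pcc,
    auc = suppressWarnings(auc_score(predictions, pos)),
    aupr = suppressWarnings(aupr_score(predictions, pos)),
    n = length(lfcs), positives = sum(pos)
  )
}

#' AUPR restricted to guides of top-fraction negatively selected genes
#'
#' Mirrors the screening-evaluation protocol for largely non-functional
#' target sets (e.g. circRNA libraries): most genes carry no signal, so
#' global AUPR understates performance; restricting to the most negatively
#' selected genes isolates guides whose targets actually respond.
#'
#' @param predictions,lfcs Per-guide scores and measured LFCs.
#' @param genes Gene per guide.
#' @param gene_rank_table Tibble with columns `gene` and `rank` (1 = most
#'   negatively selected), e.g. from [gene_negative_selection()].
#' @param fraction Fraction of top-ranked genes to keep (used if `top_n`
#'   is `NULL`).
#' @param top_n Alternatively, keep exactly the `top_n` best-ranked genes.
#' @param threshold Positive-label LFC threshold.
#' @return One-row tibble as [compute_metrics()], plus `genes_kept`.
#' @export
topfrac_gene_eval <- function(predictions, lfcs, genes, gene_rank_table,
                              fraction = 0.1, top_n = NULL, threshold = -0.5) {
  stopifnot(all(c("gene", "rank") %in% names(gene_rank_table)))
  ranked <- dplyr::arrange(gene_rank_table, .data$rank)
  n_keep <- if (!is.null(top_n)) min(top_n, nrow(ranked)) else floor(fraction * nrow(ranked))
  if (n_keep < 1L) abort("fraction/top_n selects zero genes")
  keep_genes <- ranked$gene[seq_len(n_keep)]
  sel <- genes %in% keep_genes
  res <- compute_metrics(predictions[sel], lfcs[sel], threshold = threshold)
  res$genes_kept <- n_keep
  res
}

#' Keep only each gene's most extreme guides by LFC rank
#'
#' Per gene, retains the `n_extreme` most depleted (lowest-LFC) and the
#' `n_extreme` least depleted guides; overlapping selections in small
#' genes are deduplicated, so a gene with fewer than `2 * n_extreme`
#' guides keeps all of them.
#'
#' @param data Guide tibble with `gene` and `lfc` columns.
#' @param n_extreme Guides to keep at each end (default 4).
#' @return Filtered tibble.
#' @export
top_bottom_filter <- function(data, n_extreme = 4L) {
  data |>
    dplyr::group_by(.data$gene) |>
    dplyr::filter({
      r <- rank(.data$lfc, ties.method = "first")
      r <= n_extreme | r > dplyr::n() - n_extreme
    }) |>
    dplyr::ungroup()
}

#' Cross-dataset evaluation protocols
#'
#' `mixed_cv` pools all sources and cross-validates; for
#' `leave_one_dataset_out` each source in turn is held out entirely and a
#' model trained on the remaining sources predicts it. Optionally each
#' gene is first reduced to its most extreme guides by LFC
#' ([top_bottom_filter()]), the evaluation protocol used when comparing
#' predictors on proliferation screens.
#'
#' @param data Guide tibble with columns `gene`, `lfc` and `source`.
#' @param fit_fun,predict_fun As in [kfold_predictions()].
#' @param mode `"mixed_cv"` or `"leave_one_dataset_out"`.
#' @param top_bottom Per-gene extreme-guide filter applied before
#'   evaluation (`NULL` to disable).
#' @param k Folds for `mixed_cv`.
#' @param seed Seed.
#' @param threshold Positive-label LFC threshold.
#' @return List with `metrics` (one row per evaluation unit) and
#'   `predictions`.
#' @export
dataset_transfer <- function(data, fit_fun, predict_fun,
                             mode = c("mixed_cv", "leave_one_dataset_out"),
                             top_bottom = 4L, k = 5L, seed = 1L, threshold = -0.5) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "lfc", "source") %in% names(data)))
  if (!is.null(top_bottom)) data <- top_bottom_filter(data, top_bottom)
  if (mode == "mixed_cv") {
    out <- kfold_predictions(data, fit_fun, predict_fun, k = k, seed = seed)
    metrics <- compute_metrics(out$prediction, out$lfc, threshold = threshold)
    metrics$unit <- "pooled"
  } else {
    sources <- unique(data$source)
    if (length(sources) < 2L) {
      abort("leave_one_dataset_out needs at least two dataset sources")
    }
    out <- purrr::map_dfr(sources, function(s) {
      test <- data$source == s
      model <- fit_fun(data[!test, , drop = FALSE])
      d <- data[test, , drop = FALSE]
      d$prediction <- predict_fun(model, d)
      d
    })
    metrics <- out |>
      dplyr::group_by(unit = .data$source) |>
      dplyr::group_modify(~ compute_metrics(.x$prediction, .x$lfc, threshold = threshold)) |>
      dplyr::ungroup()
  }
  list(metrics = metrics, predictions = out)
}
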