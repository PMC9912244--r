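# The off-target viability model: guides targeting non-essential genes
# should not deplete through their target, so their strongest dropouts
# isolate guide-intrinsic (collateral) viability effects. Guides in the
# lowest LFC quartile are labelled "strong depletion" and a random forest
# separates them from the rest over the curated features; the normalised
# feature importances are then compared across datasets and against the
# analogous on-target model trained on essential-gene guides.

#' Strong-depletion labels from guide LFCs
#'
#' Labels the `quantile` fraction of guides with the lowest LFC as strong
#' depletion, breaking ties deterministically by (LFC, guide_id). Exactly
#' `floor(quantile * n)` guides are labelled.
#'
#' @param guides Guide tibble with `guide_id` and non-missing `lfc`.
#' @param quantile Labelled fraction (default 0.25).
#' @return The tibble with a logical `strong` column appended.
#' @export
make_depletion_labels <- function(guides, quantile = 0.25) {
  stopifnot(all(c("guide_id", "lfc") %in% names(guides)))
  if (anyNA(guides$lfc)) abort("all guides must have an LFC")
  n <- nrow(guides)
  if (n < 8L) abort("need at least 8 guides to label")
  if (sd(guides$lfc) == 0) abort("degenerate LFC distribution: all values equal")
  n_pos <- floor(quantile * n)
  ord <- order(guides$lfc, guides$guide_id)
  strong <- logical(n)
  strong[ord[seq_len(n_pos)]] <- TRUE
  guides$strong <- strong
  guides
}

#' Off-target labels from non-essential-targeting guides
#'
#' [make_depletion_labels()] with a contamination guard: every guide must
#' target a non-essential gene, since depletion of essential-gene guides
#' is an on-target effect.
#'
#' @inheritParams make_depletion_labels
#' @param essential_genes Character vector of known essential genes; any
#'   guide targeting one is an error. If `guides` has an `essential`
#'   column it is checked too.
#' @return Tibble with `strong` labels.
#' @export
make_offtarget_labels <- function(guides, quantile = 0.25,
                                  essential_genes = character(0)) {
  contaminated <- guides$gene %in% essential_genes
  if ("essential" %in% names(guides)) contaminated <- contaminated | guides$essential
  if (any(contaminated)) {
    abort(sprintf(
      "%d guide(s) target essential genes; off-target labels must come from non-essential targets only",
      sum(contaminated)))
  }
  make_depletion_labels(guides, quantile)
}

#' Random forest of strong vs rest depletion, with feature importances
#'
#' @param features Numeric matrix or tibble of the 185 curated features
#'   (a `guide_id` column, if present, is dropped).
#' @param labels Logical strong-depletion labels.
#' @param seed Seed.
#' @param ntree Number of trees (default 500, the library default).
#' @return A `depletion_rf`: the fitted forest plus `importance`, the
#'   mean-decrease-in-impurity weights normalised to sum 1 in canonical
#'   feature order.
#' @export
fit_offtarget_rf <- function(features, labels, seed = 1L, ntree = 500L) {
  if (is.data.frame(features)) {
    features <- features[setdiff(names(features), "guide_id")]
    features <- as.matrix(features)
  }
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) abort("labels contain a single class")
  if (nrow(features) < 50L) warn("fewer than 50 guides: importances will be noisy")
  set.seed(seed)
  fit <- randomForest::randomForest(x = features, y = factor(labels, c(FALSE, TRUE)),
                                    ntree = ntree, importance = FALSE)
  imp <- randomForest::importance(fit)[, 1]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(list(fit = fit, importance = imp, n = nrow(features),
                 positives = sum(labels), seed = seed),
            class = "depletion_rf")
}

#' Pearson correlation between two feature-importance vectors
#'
#' @param v1,v2 Named importance vectors in the same canonical order
#'   (`depletion_rf$importance`).
#' @return Pearson correlation; `NA` with a warning when either vector has
#'   zero variance (undefined).
#' @export
importance_correlation <- function(v1, v2) {
  if (inherits(v1, "depletion_rf")) v1 <- v1$importance
  if (inherits(v2, "depletion_rf")) v2 <- v2$importance
  stopifnot(length(v1) == length(v2))
  if (!is.null(names(v1)) && !is.null(names(v2)) && !identical(names(v1), names(v2))) {
    abort("importance vectors are not in the same canonical feature order")
  }
  if (sd(v1) == 0 || sd(v2) == 0) {
    warn("importance correlation undefined: zero-variance vector")
    return(NA_real_)
  }
  cor(v1, v2)
}

#' @export
tidy.depletion_rf <- function(x, ...) {
  tibble(feature = names(x$importance), importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
glance.depletion_rf <- function(x, ...) {
  tibble(n = x$n, positives = x$positives, ntree = x$fit$ntree,
         oob_error = x$fit$err.rate[x$fit$ntree, "OOB"])
}
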