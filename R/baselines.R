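# Classical regression baselines over the curated features: random forest,
# XGBoost and an RBF support-vector machine from their packages; AdaBoost.R2
# and least-squares gradient boosting built on rpart trees (no AdaBoost or
# classic-GBM package ships with this stack, and both algorithms are a few
# dozen lines). All run with library defaults and a fixed seed.

BASELINE_KINDS <- c("RF", "XGB", "SVM", "ADA", "GBM")

fit_adaboost_r2 <- function(X, y, n_rounds = 50L, maxdepth = 3L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list(); betas <- numeric(0)
  df <- data.frame(X, .y = y, check.names = FALSE)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                        control = rpart::rpart.control(maxdepth = maxdepth, cp = 0.001))
    pred <- predict(fit, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) { learners[[m]] <- fit; betas[m] <- 1e-10; break }
    loss <- err / emax
    lbar <- sum(w * loss)
    if (lbar >= 0.5) break
    beta <- lbar / (1 - lbar)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
    learners[[m]] <- fit
    betas[m] <- beta
  }
  if (length(learners) == 0L) abort("AdaBoost.R2 failed to fit any learner")
  list(learners = learners, log_inv_beta = log(1 / betas))
}

predict_adaboost_r2 <- function(fit, X) {
  df <- data.frame(X, check.names = FALSE)
  preds <- vapply(fit$learners, function(l) predict(l, df), numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  wts <- fit$log_inv_beta
  # weighted median across learners
  apply(preds, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= sum(wts) / 2)[1]]
  })
}

fit_ls_gbm <- function(X, y, n_rounds = 100L, shrinkage = 0.1, maxdepth = 3L) {
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", n_rounds)
  df <- data.frame(X, check.names = FALSE)
  for (m in seq_len(n_rounds)) {
    df$.r <- resid
    tr <- rpart::rpart(.r ~ ., data = df[, c(colnames(X), ".r")],
                       control = rpart::rpart.control(maxdepth = maxdepth, cp = 0.001))
    resid <- resid - shrinkage * predict(tr, df)
    trees[[m]] <- tr
  }
  list(f0 = f0, trees = trees, shrinkage = shrinkage)
}

predict_ls_gbm <- function(fit, X) {
  df <- data.frame(X, check.names = FALSE)
  out <- rep(fit$f0, nrow(df))
  for (tr in fit$trees) out <- out + fit$shrinkage * predict(tr, df)
  out
}

#' Train a classical baseline on curated features
#'
#' @param kind One of `"RF"`, `"XGB"`, `"SVM"`, `"ADA"`, `"GBM"`.
#' @param X Numeric feature matrix (rows = guides).
#' @param y Numeric targets (e.g. sigmoid-normalised LFC scores).
#' @param seed Seed; refitting with the same seed reproduces predictions.
#' @return A `baseline_model`; use `predict()` for real-valued scores.
#' @export
train_baseline <- function(kind = BASELINE_KINDS, X, y, seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 20L) abort("need at least 20 training rows")
  if (sd(y) == 0) abort("constant targets: nothing to learn")
  set.seed(seed)
  fit <- switch(kind,
    RF = randomForest::randomForest(x = X, y = y),
    XGB = xgboost::xgb.train(
      params = list(objective = "reg:squarederror", nthread = 1, seed = seed,
                    max_depth = 6, eta = 0.3),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100
    ),
    SVM = e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial"),
    ADA = fit_adaboost_r2(X, y),
    GBM = fit_ls_gbm(X, y)
  )
  structure(list(kind = kind, fit = fit, feature_names = colnames(X), n = nrow(X)),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) colnames(X) <- object$feature_names
  X <- X[, object$feature_names, drop = FALSE]
  switch(object$kind,
    RF = unname(predict(object$fit, X)),
    XGB = predict(object$fit, xgboost::xgb.DMatrix(X)),
    SVM = unname(predict(object$fit, X)),
    ADA = predict_adaboost_r2(object$fit, X),
    GBM = predict_ls_gbm(object$fit, X)
  )
}

#' @export
glance.baseline_model <- function(x, ...) {
  tibble(kind = x$kind, n = x$n, n_features = length(x$feature_names))
}
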