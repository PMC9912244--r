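# The on-target efficiency model: two parallel convolutional-recurrent
# branches, one over the one-hot guide sequence (L x 4) and one over the
# one-hot dot-bracket structure (L x 3). Each branch is
# conv -> batch-norm -> ReLU, twice, then dropout (50%), max pooling, an
# LSTM, dropout (30%) and a dense layer; the branch outputs are
# concatenated and a final dense layer with a sigmoid produces a "deep
# score" in [0, 1]. Trained with mean squared error against
# sigmoid-normalised LFC targets.

#' Model configuration for the CRNN efficiency model
#'
#' Defaults match the published topology (two convolution layers per
#' branch, 50% dropout after the convolution stack, 30% after the LSTM);
#' layer sizes are configurable because only the topology, not the sizes,
#' is fixed by the design.
#'
#' @param conv_filters Filters in each convolution layer.
#' @param conv_kernel Positional width of the convolution kernels (full
#'   channel depth).
#' @param dense_units Units in the per-branch dense layer.
#' @param dropout_conv Dropout rate after the convolution stack (default 0.5).
#' @param dropout_lstm Dropout rate after the LSTM (default 0.3).
#' @param recurrent_units LSTM hidden units.
#' @param optimizer One of `"adam"`, `"rmsprop"`, `"sgd"`.
#' @param learning_rate Learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @param use_structure Keep the structure branch (set `FALSE` for the
#'   sequence-only ablation).
#' @return A `model_config` list.
#' @export
model_config <- function(conv_filters = 32L, conv_kernel = 4L, dense_units = 64L,
                         dropout_conv = 0.5, dropout_lstm = 0.3,
                         recurrent_units = 64L, optimizer = c("adam", "rmsprop", "sgd"),
                         learning_rate = 1e-3, epochs = 100L, batch_size = 64L,
                         seed = 1L, use_structure = TRUE) {
  optimizer <- match.arg(optimizer)
  stopifnot(conv_filters >= 1L, conv_kernel >= 2L, dense_units >= 1L,
            dropout_conv >= 0, dropout_conv < 1, dropout_lstm >= 0, dropout_lstm < 1,
            recurrent_units >= 1L, learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(
    conv_filters = as.integer(conv_filters), conv_kernel = as.integer(conv_kernel),
    dense_units = as.integer(dense_units), dropout_conv = dropout_conv,
    dropout_lstm = dropout_lstm, recurrent_units = as.integer(recurrent_units),
    optimizer = optimizer, learning_rate = learning_rate,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed), use_structure = isTRUE(use_structure)
  ), class = "model_config")
}

crnn_branches <- function(config) {
  if (config$use_structure) c(seq = 4L, struct = 3L) else c(seq = 4L)
}

#' Build an untrained CRNN efficiency model
#'
#' @param config A [model_config()].
#' @param L Model input length (padded guide length).
#' @return A `crnn_model` with seeded initial weights.
#' @export
build_crnn <- function(config = model_config(), L = 30L) {
  stopifnot(inherits(config, "model_config"))
  k <- config$conv_kernel
  t2 <- L - 2L * (k - 1L)
  if (t2 < 2L) abort(sprintf("conv kernel %d too large for input length %d", k, L))
  set.seed(config$seed)
  F_ <- config$conv_filters; H <- config$recurrent_units; D <- config$dense_units
  params <- list()
  bn_state <- list()
  for (br in names(crnn_branches(config))) {
    cin <- crnn_branches(config)[[br]]
    params[[paste0(br, "_conv1_W")]] <- glorot(k * cin, F_)
    params[[paste0(br, "_conv1_b")]] <- rep(0, F_)
    params[[paste0(br, "_conv2_W")]] <- glorot(k * F_, F_)
    params[[paste0(br, "_conv2_b")]] <- rep(0, F_)
    for (bn in c("_bn1", "_bn2")) {
      params[[paste0(br, bn, "_gamma")]] <- rep(1, F_)
      params[[paste0(br, bn, "_beta")]] <- rep(0, F_)
      bn_state[[paste0(br, bn)]] <- list(mean = rep(0, F_), var = rep(1, F_))
    }
    l <- lstm_init(F_, H)
    params[[paste0(br, "_lstm_Wx")]] <- l$Wx
    params[[paste0(br, "_lstm_Wh")]] <- l$Wh
    params[[paste0(br, "_lstm_b")]] <- l$b
    params[[paste0(br, "_dense_W")]] <- glorot(H, D)
    params[[paste0(br, "_dense_b")]] <- rep(0, D)
  }
  nin <- D * length(crnn_branches(config))
  params[["head_W"]] <- glorot(nin, 1L)
  params[["head_b"]] <- 0
  structure(list(params = params, bn_state = bn_state, config = config,
                 L = as.integer(L), trained = FALSE, history = NULL),
            class = "crnn_model")
}

#' Number of trainable parameters
#' @param model A `crnn_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

branch_forward <- function(model, br, X, mask, training) {
  p <- model$params; cfg <- model$config; k <- cfg$conv_kernel
  pf <- function(s) paste0(br, "_", s)
  cache <- list()
  c1 <- conv1d_forward(X, p[[pf("conv1_W")]], p[[pf("conv1_b")]], k); cache$c1 <- c1$cache
  b1 <- bn_forward(c1$out, p[[pf("bn1_gamma")]], p[[pf("bn1_beta")]],
                   model$bn_state[[pf("bn1")]], training); cache$b1 <- b1$cache
  model$bn_state[[pf("bn1")]] <- b1$state
  r1 <- relu_forward(b1$out); cache$r1 <- r1$cache
  c2 <- conv1d_forward(r1$out, p[[pf("conv2_W")]], p[[pf("conv2_b")]], k); cache$c2 <- c2$cache
  b2 <- bn_forward(c2$out, p[[pf("bn2_gamma")]], p[[pf("bn2_beta")]],
                   model$bn_state[[pf("bn2")]], training); cache$b2 <- b2$cache
  model$bn_state[[pf("bn2")]] <- b2$state
  r2 <- relu_forward(b2$out); cache$r2 <- r2$cache
  t2 <- dim(r2$out)[2]
  m2 <- mask[, seq_len(t2), drop = FALSE]        # exclude padded positions
  a <- r2$out * c(m2); cache$m2 <- m2
  d1 <- dropout_forward(a, cfg$dropout_conv, training); cache$d1 <- d1$cache
  mp <- maxpool2_forward(d1$out); cache$mp <- mp$cache
  ls <- lstm_forward(mp$out, list(Wx = p[[pf("lstm_Wx")]], Wh = p[[pf("lstm_Wh")]],
                                  b = p[[pf("lstm_b")]])); cache$ls <- ls$cache
  d2 <- dropout_forward(ls$out, cfg$dropout_lstm, training); cache$d2 <- d2$cache
  de <- dense_forward(d2$out, p[[pf("dense_W")]], p[[pf("dense_b")]]); cache$de <- de$cache
  r3 <- relu_forward(de$out); cache$r3 <- r3$cache
  list(out = r3$out, cache = cache, model = model)
}

branch_backward <- function(model, br, dH, cache) {
  p <- model$params; k <- model$config$conv_kernel
  pf <- function(s) paste0(br, "_", s)
  g <- list()
  dH <- relu_backward(dH, cache$r3)
  de <- dense_backward(dH, cache$de)
  g[[pf("dense_W")]] <- de$dW; g[[pf("dense_b")]] <- de$db
  dh <- dropout_backward(de$dX, cache$d2)
  lb <- lstm_backward(dh, list(Wx = p[[pf("lstm_Wx")]], Wh = p[[pf("lstm_Wh")]],
                               b = p[[pf("lstm_b")]]), cache$ls)
  g[[pf("lstm_Wx")]] <- lb$dWx; g[[pf("lstm_Wh")]] <- lb$dWh; g[[pf("lstm_b")]] <- lb$db
  dmp <- maxpool2_backward(lb$dX, cache$mp)
  dd1 <- dropout_backward(dmp, cache$d1)
  dd1 <- dd1 * c(cache$m2)
  dr2 <- relu_backward(dd1, cache$r2)
  b2 <- bn_backward(dr2, cache$b2)
  g[[pf("bn2_gamma")]] <- b2$dgamma; g[[pf("bn2_beta")]] <- b2$dbeta
  c2 <- conv1d_backward(b2$dX, cache$c2)
  g[[pf("conv2_W")]] <- c2$dW; g[[pf("conv2_b")]] <- c2$db
  dr1 <- relu_backward(c2$dX, cache$r1)
  b1 <- bn_backward(dr1, cache$b1)
  g[[pf("bn1_gamma")]] <- b1$dgamma; g[[pf("bn1_beta")]] <- b1$dbeta
  c1 <- conv1d_backward(b1$dX, cache$c1)
  g[[pf("conv1_W")]] <- c1$dW; g[[pf("conv1_b")]] <- c1$db
  list(grads = g, dX = c1$dX)
}

crnn_forward <- function(model, inputs, training = FALSE) {
  brs <- names(crnn_branches(model$config))
  hs <- list(); caches <- list()
  for (br in brs) {
    X <- if (br == "seq") inputs$seq else inputs$struct
    bf <- branch_forward(model, br, X, inputs$mask, training)
    model <- bf$model
    hs[[br]] <- bf$out; caches[[br]] <- bf$cache
  }
  Hcat <- do.call(cbind, hs)
  hd <- dense_forward(Hcat, model$params$head_W, model$params$head_b)
  logit <- hd$out[, 1]
  out <- nn_sigmoid(logit)
  list(out = out, logit = logit, model = model,
       cache = list(branches = caches, head = hd$cache, out = out,
                    widths = vapply(hs, ncol, integer(1))))
}

# dout: gradient of the objective w.r.t. the sigmoid output (length B);
# on_logit = TRUE backpropagates from the pre-sigmoid logit instead
crnn_backward <- function(model, cache, dout, on_logit = FALSE) {
  dlogit <- if (on_logit) dout else dout * cache$out * (1 - cache$out)
  hd <- dense_backward(matrix(dlogit, ncol = 1L), cache$head)
  g <- list(head_W = hd$dW, head_b = hd$db)
  dXs <- list()
  offset <- 0L
  for (br in names(cache$branches)) {
    w <- cache$widths[[br]]
    dH <- hd$dX[, (offset + 1L):(offset + w), drop = FALSE]
    offset <- offset + w
    bb <- branch_backward(model, br, dH, cache$branches[[br]])
    g <- c(g, bb$grads)
    dXs[[br]] <- bb$dX
  }
  list(grads = g, dinputs = dXs)
}

slice_inputs <- function(inputs, idx) {
  out <- list(seq = inputs$seq[idx, , , drop = FALSE],
              mask = inputs$mask[idx, , drop = FALSE])
  if (!is.null(inputs$struct)) out$struct <- inputs$struct[idx, , , drop = FALSE]
  out
}

#' Train the CRNN efficiency model
#'
#' Minimises mean squared error between the sigmoid-bounded model output
#' and the (sigmoid-normalised) targets, tracking the per-epoch training
#' MSE. Fully seeded: two runs with the same configuration and data give
#' identical weights.
#'
#' @param model An untrained (or warm) `crnn_model`.
#' @param inputs Encoded guides from [encode_guide_set()].
#' @param targets Numeric targets in (0, 1) (see [lfc_to_target()]).
#' @param epochs Overrides `config$epochs` when given.
#' @param validation Optional `list(inputs =, targets =)` evaluated per epoch.
#' @param verbose Print per-epoch loss.
#' @return The trained model; `model$history` is a tibble with columns
#'   `epoch`, `mse` and (if validation given) `val_mse`.
#' @export
fit_crnn <- function(model, inputs, targets, epochs = NULL, validation = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(model, "crnn_model"))
  n <- dim(inputs$seq)[1]
  stopifnot(length(targets) == n)
  if (n < 100) warn("fewer than 100 training guides: fit may be unstable")
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  set.seed(cfg$seed + 1L)
  opt <- optimizer_init(model$params, cfg$optimizer)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    losses <- c(); sizes <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      b <- idx[start:min(start + cfg$batch_size - 1L, n)]
      xb <- slice_inputs(inputs, b)
      fw <- crnn_forward(model, xb, training = TRUE)
      model <- fw$model
      err <- fw$out - targets[b]
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        abort(sprintf(
          "NaN/Inf loss at epoch %d (lr = %g, optimizer = %s); lower the learning rate",
          ep, cfg$learning_rate, cfg$optimizer))
      }
      bw <- crnn_backward(model, fw$cache, 2 * err / length(b))
      stp <- optimizer_step(opt, model$params, bw$grads, cfg$learning_rate)
      opt <- stp$opt; model$params <- stp$params
      losses <- c(losses, loss); sizes <- c(sizes, length(b))
    }
    row <- tibble(epoch = ep, mse = sum(losses * sizes) / sum(sizes))
    if (!is.null(validation)) {
      vp <- crnn_predict(model, validation$inputs)
      row$val_mse <- mean((vp - validation$targets)^2)
    }
    history[[ep]] <- row
    if (verbose) message(sprintf("epoch %d: mse %.5f", ep, row$mse))
  }
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(history)
  model
}

#' Predict deep scores
#'
#' @param model A trained `crnn_model`.
#' @param inputs Encoded guides from [encode_guide_set()].
#' @param chunk Prediction batch size (results are per-guide identical
#'   whatever the batching).
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_deep_score <- function(model, inputs, chunk = 512L) {
  stopifnot(inherits(model, "crnn_model"))
  if (!isTRUE(model$trained)) abort("model is untrained; call fit_crnn() first")
  crnn_predict(model, inputs, chunk = chunk)
}

crnn_predict <- function(model, inputs, chunk = 512L) {
  n <- dim(inputs$seq)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    b <- start:min(start + chunk - 1L, n)
    out[b] <- crnn_forward(model, slice_inputs(inputs, b), training = FALSE)$out
  }
  out
}

#' @export
predict.crnn_model <- function(object, newdata, ...) {
  predict_deep_score(object, newdata)
}

# gradient of the scalar model output w.r.t. both input tensors, eval mode
crnn_input_gradient <- function(model, inputs, on_logit = FALSE) {
  fw <- crnn_forward(model, inputs, training = FALSE)
  n <- length(fw$out)
  bw <- crnn_backward(model, fw$cache, rep(1, n), on_logit = on_logit)
  c(bw$dinputs, list(out = fw$out, logit = fw$logit))
}

#' Cross-validated deep scores for a guide table
#'
#' Encodes the guides (folding each spacer once), then runs k-fold
#' cross-validation of the CRNN: every guide's deep score comes from a
#' model whose training fold excluded it.
#'
#' @param guides Tibble with columns `spacer` and `lfc` (and `gene` when
#'   `grouping = "gene"`).
#' @param k Number of folds.
#' @param config A [model_config()].
#' @param L Model input length.
#' @param engine Folding engine.
#' @param epochs Training epochs per fold (default `config$epochs`).
#' @param grouping Fold assignment unit, `"guide"` or `"gene"`.
#' @param seed Seed for fold assignment.
#' @param params Sigmoid calibration for the training targets.
#' @param folds_precomputed Optional [fold_guides()] tibble.
#' @return `guides` with `fold`, `deep_score` and `target` appended.
#' @export
cv_deep_score <- function(guides, k = 5L, config = model_config(), L = 30L,
                          engine = default_fold_engine(), epochs = NULL,
                          grouping = c("guide", "gene"), seed = 1L,
                          params = solve_sigmoid_params(),
                          folds_precomputed = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(all(c("spacer", "lfc") %in% names(guides)), !anyNA(guides$lfc))
  enc <- encode_guide_set(guides$spacer, L = L, engine = engine,
                          folds = folds_precomputed)
  target <- lfc_to_target(guides$lfc, params)
  n <- nrow(guides)
  fold <- if (grouping == "gene") kfold_assign(n, k, genes = guides$gene, seed = seed)
          else kfold_assign(n, k, seed = seed)
  pred <- rep(NA_real_, n)
  for (f in sort(unique(fold))) {
    test <- fold == f
    m <- build_crnn(config, L = L)
    m <- fit_crnn(m, slice_inputs(enc, which(!test)), target[!test], epochs = epochs)
    pred[test] <- predict_deep_score(m, slice_inputs(enc, which(test)))
  }
  guides$fold <- fold
  guides$deep_score <- pred
  guides$target <- target
  guides
}

#' Grid search over training hyperparameters
#'
#' Trains one model per combination of the four tuned hyperparameters
#' (dense units, convolution-stage dropout rate, optimizer, learning rate)
#' and selects the combination with the lowest held-out MSE.
#'
#' @param grid Named list with non-empty axes `dense_units`,
#'   `dropout_conv`, `optimizer`, `learning_rate`.
#' @param inputs,targets Training data as for [fit_crnn()].
#' @param seed Seed for the train/validation split and model seeds.
#' @param val_fraction Held-out fraction (default 0.2).
#' @param epochs Training epochs per combination.
#' @param base_config Template [model_config()] supplying the untuned
#'   fields.
#' @param L Model input length.
#' @return List with `best_config` (a `model_config`) and `results`, a
#'   tibble with one row per combination and its validation MSE.
#' @export
tune_grid <- function(grid, inputs, targets, seed = 1L, val_fraction = 0.2,
                      epochs = 10L, base_config = model_config(), L = 30L) {
  axes <- c("dense_units", "dropout_conv", "optimizer", "learning_rate")
  if (!all(axes %in% names(grid)) || any(vapply(grid[axes], length, integer(1)) == 0L)) {
    abort("grid must provide non-empty axes dense_units, dropout_conv, optimizer, learning_rate")
  }
  combos <- expand.grid(grid[axes], stringsAsFactors = FALSE)
  n <- dim(inputs$seq)[1]
  set.seed(seed)
  val_idx <- sample.int(n, max(1L, round(val_fraction * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  tr <- slice_inputs(inputs, tr_idx); va <- slice_inputs(inputs, val_idx)
  results <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    cfg <- base_config
    cfg$dense_units <- as.integer(combos$dense_units[i])
    cfg$dropout_conv <- combos$dropout_conv[i]
    cfg$optimizer <- combos$optimizer[i]
    cfg$learning_rate <- combos$learning_rate[i]
    cfg$seed <- as.integer(seed)
    m <- build_crnn(cfg, L = L)
    m <- tryCatch(fit_crnn(m, tr, targets[tr_idx], epochs = epochs),
                  error = function(e) NULL)
    val_mse <- if (is.null(m)) Inf else mean((crnn_predict(m, va) - targets[val_idx])^2)
    tibble(dense_units = combos$dense_units[i], dropout_conv = combos$dropout_conv[i],
           optimizer = combos$optimizer[i], learning_rate = combos$learning_rate[i],
           val_mse = val_mse)
  })
  best <- results[which.min(results$val_mse), ]
  cfg <- base_config
  cfg$dense_units <- as.integer(best$dense_units)
  cfg$dropout_conv <- best$dropout_conv
  cfg$optimizer <- best$optimizer
  cfg$learning_rate <- best$learning_rate
  cfg$seed <- as.integer(seed)
  list(best_config = cfg, results = results)
}
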