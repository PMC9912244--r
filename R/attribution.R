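# Integrated Gradients: path-integral attribution of the model score over
# input positions and channels, with the completeness residual
# |sum(IG) - (F(x) - F(baseline))| reported for every map.

#' Forward scores of an attribution-capable model
#' @param model Model object.
#' @param inputs Batched input tensors.
#' @param ... Method arguments.
#' @return Numeric scores.
#' @export
model_forward_scores <- function(model, inputs, ...) UseMethod("model_forward_scores")

#' Input-space gradients of an attribution-capable model
#' @inheritParams model_forward_scores
#' @return List of gradient tensors (same shapes as the inputs) plus `out`.
#' @export
model_input_gradient <- function(model, inputs, ...) UseMethod("model_input_gradient")

#' @export
model_forward_scores.crnn_model <- function(model, inputs, on_logit = FALSE, ...) {
  fw <- crnn_forward(model, inputs, training = FALSE)
  if (on_logit) fw$logit else fw$out
}

#' @export
model_input_gradient.crnn_model <- function(model, inputs, on_logit = FALSE, ...) {
  crnn_input_gradient(model, inputs, on_logit = on_logit)
}

#' A single-linear-layer surrogate model
#'
#' `F(x) = sum(W * x_seq) + b`: its Integrated Gradients have the closed
#' form `W * (x - baseline)` for any number of steps, which pins the IG
#' implementation in tests.
#'
#' @param W Weight matrix (L x 4).
#' @param b Scalar bias.
#' @return A `linear_surrogate` model.
#' @export
linear_surrogate <- function(W, b = 0) {
  structure(list(W = W, b = b), class = "linear_surrogate")
}

#' @export
model_forward_scores.linear_surrogate <- function(model, inputs, ...) {
  B <- dim(inputs$seq)[1]
  vapply(seq_len(B), function(i) sum(model$W * inputs$seq[i, , ]) + model$b, numeric(1))
}

#' @export
model_input_gradient.linear_surrogate <- function(model, inputs, ...) {
  B <- dim(inputs$seq)[1]
  g <- array(0, dim(inputs$seq))
  for (i in seq_len(B)) g[i, , ] <- model$W
  list(seq = g, out = model_forward_scores(model, inputs))
}

zero_baseline <- function(enc) {
  list(seq_onehot = enc$seq_onehot * 0, struct_onehot = enc$struct_onehot * 0,
       mask = enc$mask, L = enc$L)
}

#' Integrated Gradients for one encoded guide
#'
#' Approximates `IG_i = (x_i - x'_i) * mean over alpha in {1/m, ..., 1} of
#' dF(x' + alpha (x - x')) / dx_i` (right-Riemann path integral from the
#' baseline `x'` to the input). The default baseline is the all-zero
#' encoding (no sequence present).
#'
#' @param model A trained model implementing [model_input_gradient()].
#' @param guide An [encode_guide()] result.
#' @param baseline A same-shape `encoded_guide`; default all-zero.
#' @param steps Number of Riemann steps (default 64; must be >= 2).
#' @param on_logit Attribute the pre-sigmoid logit instead of the bounded
#'   score (CRNN models only).
#' @return An `attribution_map`: `seq` (L x 4), `struct` (L x 3, zero for
#'   models without a structure input), `baseline_score`, `input_score`,
#'   `steps`, `completeness_residual`, and the encoded `input`.
#' @export
integrated_gradients <- function(model, guide, baseline = NULL, steps = 64L,
                                 on_logit = FALSE) {
  stopifnot(inherits(guide, "encoded_guide"))
  if (steps < 2L) abort("steps must be at least 2")
  baseline <- baseline %||% zero_baseline(guide)
  stopifnot(all(dim(baseline$seq_onehot) == dim(guide$seq_onehot)))
  L <- guide$L
  alphas <- seq_len(steps) / steps
  dseq <- guide$seq_onehot - baseline$seq_onehot
  dstruct <- guide$struct_onehot - baseline$struct_onehot
  seq_b <- array(0, c(steps, L, 4L))
  struct_b <- array(0, c(steps, L, 3L))
  for (s in seq_len(steps)) {
    seq_b[s, , ] <- baseline$seq_onehot + alphas[s] * dseq
    struct_b[s, , ] <- baseline$struct_onehot + alphas[s] * dstruct
  }
  inputs <- list(seq = seq_b, struct = struct_b,
                 mask = matrix(rep(guide$mask, each = steps), steps, L))
  grads <- model_input_gradient(model, inputs, on_logit = on_logit)
  avg_seq <- apply(grads$seq, c(2, 3), mean)
  ig_seq <- dseq * avg_seq
  ig_struct <- if (!is.null(grads$struct)) dstruct * apply(grads$struct, c(2, 3), mean)
               else guide$struct_onehot * 0
  one <- function(enc) {
    i <- list(seq = array(enc$seq_onehot, c(1, L, 4L)),
              struct = array(enc$struct_onehot, c(1, L, 3L)),
              mask = matrix(enc$mask, 1, L))
    model_forward_scores(model, i, on_logit = on_logit)
  }
  f_x <- one(guide); f_b <- one(baseline)
  residual <- abs(sum(ig_seq) + sum(ig_struct) - (f_x - f_b))
  structure(list(seq = ig_seq, struct = ig_struct,
                 baseline_score = f_b, input_score = f_x,
                 steps = as.integer(steps), completeness_residual = residual,
                 input = guide),
            class = "attribution_map")
}

#' Position-by-nucleotide attribution summary
#'
#' For each position and nucleotide channel, the mean attribution across
#' the maps in which that nucleotide was the one observed at that
#' position; never-observed cells are 0. Optionally normalised so the
#' total absolute mass is 1.
#'
#' @param maps List of [integrated_gradients()] results over the same `L`.
#' @param normalize Rescale so `sum(abs(summary)) == 1`.
#' @return An `attribution_summary` matrix (L x 4, columns A, C, G, U).
#' @export
position_importance <- function(maps, normalize = FALSE) {
  if (length(maps) == 0L) abort("no attribution maps supplied")
  L <- nrow(maps[[1]]$seq)
  total <- matrix(0, L, 4L, dimnames = list(NULL, SEQ_CHANNELS))
  count <- matrix(0, L, 4L)
  for (m in maps) {
    stopifnot(nrow(m$seq) == L)
    obs <- m$input$seq_onehot == 1
    total[obs] <- total[obs] + m$seq[obs]
    count <- count + obs
  }
  out <- ifelse(count > 0, total / pmax(count, 1), 0)
  if (normalize) {
    mass <- sum(abs(out))
    if (mass > 0) out <- out / mass
  }
  structure(out, class = c("attribution_summary", "matrix", "array"))
}

#' Export an attribution summary as a tidy tibble
#' @param x An `attribution_summary`.
#' @param ... Unused.
#' @return Tibble with `position`, `nucleotide`, `attribution`.
#' @export
tidy.attribution_summary <- function(x, ...) {
  tibble(
    position = rep(seq_len(nrow(x)), times = 4L),
    nucleotide = rep(SEQ_CHANNELS, each = nrow(x)),
    attribution = as.vector(unclass(x))
  )
}
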