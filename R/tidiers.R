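# broom-style accessors for the package's fitted objects.

#' Per-epoch training history of a CRNN fit
#' @param x A trained `crnn_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `mse` (and `val_mse` if tracked).
#' @export
tidy.crnn_model <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history; fit it first")
  x$history
}

#' One-row summary of a CRNN model
#' @param x A `crnn_model`.
#' @param ... Unused.
#' @return Tibble with parameter count, topology counts and final loss.
#' @export
glance.crnn_model <- function(x, ...) {
  arch <- model_architecture(x)
  tibble(
    n_parameters = n_parameters(x),
    n_branches = length(crnn_branches(x$config)),
    conv_layers_per_branch = sum(arch$layer[arch$branch == "seq"] == "conv"),
    trained = isTRUE(x$trained),
    epochs_trained = if (is.null(x$history)) 0L else max(x$history$epoch),
    final_mse = if (is.null(x$history)) NA_real_ else x$history$mse[nrow(x$history)]
  )
}

#' Layer-by-layer architecture listing
#'
#' @param model A `crnn_model`.
#' @return Tibble with one row per layer per branch (`branch`, `layer`,
#'   `detail`), plus the shared head.
#' @export
model_architecture <- function(model) {
  cfg <- model$config
  per_branch <- function(br) {
    tibble(
      branch = br,
      layer = c("conv", "batchnorm", "relu", "conv", "batchnorm", "relu",
                "dropout", "maxpool", "lstm", "dropout", "dense"),
      detail = c(
        sprintf("%d filters, kernel %d", cfg$conv_filters, cfg$conv_kernel), "", "",
        sprintf("%d filters, kernel %d", cfg$conv_filters, cfg$conv_kernel), "", "",
        sprintf("rate %.2f", cfg$dropout_conv), "width 2",
        sprintf("%d units", cfg$recurrent_units),
        sprintf("rate %.2f", cfg$dropout_lstm),
        sprintf("%d units", cfg$dense_units)
      )
    )
  }
  dplyr::bind_rows(
    purrr::map_dfr(names(crnn_branches(cfg)), per_branch),
    tibble(branch = "head", layer = c("concat", "dense", "sigmoid"),
           detail = c("", "1 unit", ""))
  )
}

#' @export
tidy.sigmoid_params <- function(x, ...) tibble(n = x$n, b = x$b)

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("sigmoid LFC normalisation: S(x) = 1/(1 + exp(-n*x + b)), n = %.5f, b = %.5f\n",
              x$n, x$b))
  invisible(x)
}

#' @export
print.crnn_model <- function(x, ...) {
  cat(sprintf("CRNN efficiency model: %d branches, %d parameters, %s\n",
              length(crnn_branches(x$config)), n_parameters(x),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen matrix: %d guides x %d samples (%d t0, %d t1); controls: %s\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$sample_roles == "t0"), sum(x$sample_roles == "t1"),
              paste(names(table(x$control_annotation)), table(x$control_annotation),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
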