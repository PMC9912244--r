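# LFC normalisation: a customised sigmoid maps guide log-fold-changes onto
# (0, 1) so that strong depletion scores near 1. The two parameters (n, b)
# of S(x) = 1 / (1 + exp(-n*x + b)) are pinned by two calibration
# constraints, by default S(0) = 0.3 and S(-0.3) = 0.7.

#' Solve the sigmoid normalisation parameters
#'
#' Finds `(n, b)` such that `S(x) = 1 / (1 + exp(-n*x + b))` passes through
#' two calibration points. Closed form: with logit `L(S) = log((1-S)/S)`,
#' the constraints `b - n*x1 = L(S1)` and `b - n*x2 = L(S2)` form a linear
#' 2x2 system. With the defaults, `b = log(7/3)` and
#' `n = -2*log(7/3)/0.3`.
#'
#' @param constraints A list of two `c(x, S)` pairs; default
#'   `list(c(0, 0.3), c(-0.3, 0.7))`.
#' @return A `sigmoid_params` list with elements `n` and `b`. If the two
#'   constraints imply `n = 0` the (non-monotone, degenerate) solution is
#'   returned with a warning.
#' @export
#' @examples
#' solve_sigmoid_params()
solve_sigmoid_params <- function(constraints = list(c(0, 0.3), c(-0.3, 0.7))) {
  stopifnot(length(constraints) == 2L)
  x <- vapply(constraints, `[`, numeric(1), 1L)
  s <- vapply(constraints, `[`, numeric(1), 2L)
  if (any(s <= 0 | s >= 1)) abort("constraint S values must lie strictly in (0, 1)")
  if (x[1] == x[2]) abort("degenerate constraints: the two x values must differ")
  L <- log((1 - s) / s)
  n <- (L[1] - L[2]) / (x[2] - x[1])
  b <- L[1] + n * x[1]
  if (n == 0) warn("constraints give n = 0: the sigmoid is constant (non-monotone)")
  # verify to the advertised tolerance
  check <- 1 / (1 + exp(-n * x + b))
  stopifnot(all(abs(check - s) <= 1e-10))
  structure(list(n = n, b = b), class = "sigmoid_params")
}

#' Map an LFC to its sigmoid-normalised target score
#'
#' `S(x) = 1 / (1 + exp(-n*x + b))`: strictly decreasing in the LFC for the
#' default calibration, so strongly depleted guides (very negative LFC)
#' score near 1.
#'
#' @param x Numeric vector of log2 fold changes.
#' @param params A [solve_sigmoid_params()] result.
#' @return Numeric vector of scores in (0, 1).
#' @export
lfc_to_target <- function(x, params = solve_sigmoid_params()) {
  stopifnot(inherits(params, "sigmoid_params"))
  1 / (1 + exp(-params$n * x + params$b))
}

#' Label guides as positive (effective) by LFC threshold
#'
#' A guide is an effective (positive) example when its LFC is at or below
#' the threshold; the boundary is inclusive.
#'
#' @param lfc Numeric vector of log2 fold changes; must not contain `NA`
#'   (filter missing LFCs first).
#' @param threshold Positive-label threshold (default -0.5).
#' @return Logical vector.
#' @export
label_positive <- function(lfc, threshold = -0.5) {
  if (anyNA(lfc)) abort("lfc contains missing values; filter them before labelling")
  lfc <= threshold
}
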