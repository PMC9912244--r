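# One-hot encoding of guides for the neural model: an L x 4 sequence matrix
# (channels A, C, G, U), an L x 3 structure matrix (channels '.', '(', ')')
# and a length-L validity mask. Guides shorter than L are right-padded with
# all-zero rows.

SEQ_CHANNELS <- c("A", "C", "G", "U")
STRUCT_CHANNELS <- c(".", "(", ")")

#' Encode one guide into model tensors
#'
#' @param spacer RNA spacer.
#' @param fold A [fold_mfe()] result (or any list with `dot_bracket`
#'   computed on the spacer).
#' @param L Model input length; spacers longer than `L` are an error
#'   (raise `L`), shorter ones are right-padded.
#' @return An `encoded_guide` list: `seq_onehot` (L x 4), `struct_onehot`
#'   (L x 3), `mask` (length L, 1 = real position) and `L`.
#' @export
encode_guide <- function(spacer, fold, L = 30L) {
  spacer <- assert_rna(spacer, "spacer")
  ch <- seq_chars(spacer)
  n <- length(ch)
  if (n > L) {
    abort(sprintf("spacer length %d exceeds model input length L = %d; raise L", n, L))
  }
  db <- seq_chars(fold$dot_bracket)
  if (length(db) != n) abort("fold$dot_bracket length must equal spacer length")
  seq_onehot <- matrix(0, L, 4L, dimnames = list(NULL, SEQ_CHANNELS))
  struct_onehot <- matrix(0, L, 3L, dimnames = list(NULL, STRUCT_CHANNELS))
  seq_onehot[cbind(seq_len(n), match(ch, SEQ_CHANNELS))] <- 1
  struct_onehot[cbind(seq_len(n), match(db, STRUCT_CHANNELS))] <- 1
  mask <- c(rep(1, n), rep(0, L - n))
  structure(list(seq_onehot = seq_onehot, struct_onehot = struct_onehot,
                 mask = mask, L = as.integer(L)),
            class = "encoded_guide")
}

#' Decode an encoded guide back to its spacer and structure
#'
#' Exact inverse of [encode_guide()] on its image.
#'
#' @param enc An `encoded_guide`.
#' @return List with `spacer` and `dot_bracket`.
#' @export
decode_guide <- function(enc) {
  stopifnot(inherits(enc, "encoded_guide"))
  real <- which(enc$mask == 1)
  spacer <- paste(SEQ_CHANNELS[max.col(enc$seq_onehot[real, , drop = FALSE])],
                  collapse = "")
  db <- paste(STRUCT_CHANNELS[max.col(enc$struct_onehot[real, , drop = FALSE])],
              collapse = "")
  list(spacer = spacer, dot_bracket = db)
}

#' Encode a set of guides into batched arrays
#'
#' Folds every spacer (once, batched) and stacks encodings into arrays
#' shaped `n x L x channels`, the input format of the neural model.
#'
#' @param spacers Character vector of RNA spacers.
#' @param L Model input length.
#' @param engine Folding engine passed to [fold_guides()].
#' @param folds Optional precomputed tibble from [fold_guides()] (column
#'   `dot_bracket`, one row per spacer); skips folding when given.
#' @return List with arrays `seq` (n x L x 4), `struct` (n x L x 3) and
#'   matrix `mask` (n x L).
#' @export
encode_guide_set <- function(spacers, L = 30L, engine = default_fold_engine(),
                             folds = NULL) {
  spacers <- assert_rna(spacers, "spacer")
  if (is.null(folds)) folds <- fold_guides(spacers, engine = engine)
  stopifnot(nrow(folds) == length(spacers))
  n <- length(spacers)
  seq_arr <- array(0, c(n, L, 4L))
  struct_arr <- array(0, c(n, L, 3L))
  mask <- matrix(0, n, L)
  for (i in seq_len(n)) {
    e <- encode_guide(spacers[i], list(dot_bracket = folds$dot_bracket[i]), L = L)
    seq_arr[i, , ] <- e$seq_onehot
    struct_arr[i, , ] <- e$struct_onehot
    mask[i, ] <- e$mask
  }
  list(seq = seq_arr, struct = struct_arr, mask = mask, L = as.integer(L))
}
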