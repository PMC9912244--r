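# RNA secondary structure: a thermodynamic engine (RNAfold wrapper) and a
# deterministic internal maximum-pairing fallback used where external
# binaries are unwanted.

#' Default folding engine
#'
#' `"thermo"` (the RNAfold binary) when available on the PATH, otherwise the
#' internal `"maxpair"` fallback.
#' @return `"thermo"` or `"maxpair"`.
#' @export
default_fold_engine <- function() {
  if (nzchar(Sys.which("RNAfold"))) "thermo" else "maxpair"
}

WC_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

can_pair <- function(a, b) paste0(a, b) %in% WC_PAIRS

#' Maximum-pairing fallback folder
#'
#' Dynamic-programming maximisation of the number of Watson-Crick plus G-U
#' wobble pairs subject to a minimum hairpin-loop size, with deterministic
#' traceback (the 5'-most position pairs first, with its 3'-most compatible
#' partner). Serves as a dependency-free, exactly reproducible stand-in for
#' a thermodynamic folder; its energy proxy is minus the pair count.
#'
#' @param seq RNA string (DNA accepted, converted).
#' @param min_hairpin Minimum number of unpaired bases closed by a pair
#'   (default 3, the standard steric constraint).
#' @return List with `dot_bracket` and `pair_count`.
#' @export
nussinov_fallback <- function(seq, min_hairpin = 3L) {
  s <- assert_rna(seq, "sequence")
  ch <- seq_chars(s)
  n <- length(ch)
  if (n == 0L) abort("sequence must be non-empty")
  pairable <- outer(ch, ch, function(a, b) paste0(a, b) %in% WC_PAIRS)
  # dp padded so dp[a, b] = 0 whenever a > b
  dp <- matrix(0L, n + 1L, n + 1L)
  min_span <- min_hairpin + 1L
  if (n > min_span) {
    for (span in seq(min_span, n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- dp[i + 1L, j]
        ks <- seq(i + min_span, j)
        ks <- ks[pairable[i, ks]]
        if (length(ks) > 0L) {
          vals <- dp[i + 1L, ks - 1L] + dp[cbind(ks + 1L, j)] + 1L
          best <- max(best, vals)
        }
        dp[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || dp[i, j] == 0L) next
    ks <- if (i + min_span <= j) seq(i + min_span, j) else integer(0)
    ks <- ks[pairable[i, ks]]
    paired <- FALSE
    if (length(ks) > 0L) {
      vals <- dp[i + 1L, ks - 1L] + dp[cbind(ks + 1L, j)] + 1L
      hit <- ks[vals == dp[i, j]]
      if (length(hit) > 0L) {
        k <- max(hit)   # 3'-most partner for the 5'-most base
        db[i] <- "("; db[k] <- ")"
        stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        paired <- TRUE
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  list(dot_bracket = paste(db, collapse = ""), pair_count = sum(db == "("))
}

rnafold_batch <- function(seqs) {
  if (!nzchar(Sys.which("RNAfold"))) {
    abort(paste(
      "the 'thermo' folding engine needs the RNAfold binary on the PATH;",
      "use engine = 'maxpair' for the internal fallback folder"
    ))
  }
  out <- system2("RNAfold", args = c("--noPS"), stdout = TRUE,
                 input = paste(seqs, collapse = "\n"))
  stopifnot(length(out) >= 2L * length(seqs))
  struct_lines <- out[seq(2L, by = 2L, length.out = length(seqs))]
  db <- sub("^([.()]+).*$", "\\1", struct_lines)
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", struct_lines))
  list(dot_bracket = db, mfe = mfe)
}

#' Fold a single RNA sequence
#'
#' Predicts the minimum-free-energy secondary structure of an RNA sequence.
#' The `"thermo"` engine wraps the RNAfold binary; `"maxpair"` is the
#' internal deterministic fallback ([nussinov_fallback()]) whose energy
#' proxy is minus the pair count.
#'
#' @param seq RNA string (case-insensitive; T accepted as U).
#' @param engine `"thermo"` or `"maxpair"`.
#' @param min_hairpin Hairpin constraint for the fallback engine.
#' @return A `fold_result` list with `dot_bracket`, `mfe` (kcal/mol for
#'   thermo; pair-count proxy for maxpair) and `engine`.
#' @export
fold_mfe <- function(seq, engine = default_fold_engine(), min_hairpin = 3L) {
  res <- fold_guides(seq, engine = engine, min_hairpin = min_hairpin)
  structure(list(dot_bracket = res$dot_bracket[1], mfe = res$mfe[1],
                 engine = engine),
            class = "fold_result")
}

#' Fold many sequences at once
#'
#' Vectorised folding; the thermo engine is called once for the whole batch.
#'
#' @param seqs Character vector of RNA sequences.
#' @inheritParams fold_mfe
#' @return A tibble with columns `seq`, `dot_bracket`, `mfe`.
#' @export
fold_guides <- function(seqs, engine = default_fold_engine(), min_hairpin = 3L) {
  engine <- match.arg(engine, c("thermo", "maxpair"))
  seqs <- assert_rna(seqs, "sequence")
  if (any(nchar(seqs) == 0L)) abort("sequences must be non-empty")
  if (engine == "thermo") {
    r <- rnafold_batch(seqs)
    tibble(seq = seqs, dot_bracket = r$dot_bracket, mfe = r$mfe)
  } else {
    res <- purrr::map(seqs, nussinov_fallback, min_hairpin = min_hairpin)
    tibble(
      seq = seqs,
      dot_bracket = purrr::map_chr(res, "dot_bracket"),
      mfe = -1.0 * purrr::map_dbl(res, "pair_count")
    )
  }
}

#' Folding energy of the full crRNA (direct repeat + spacer)
#'
#' The Cas13d crRNA is the constant direct-repeat (DR) scaffold followed by
#' the spacer; its folding energy is a known determinant of guide activity.
#' The DR sequence must be supplied explicitly: no default is baked in.
#'
#' @param spacer RNA spacer (vectorised).
#' @param dr The direct-repeat sequence, 5' of the spacer.
#' @inheritParams fold_mfe
#' @return Numeric vector of folding energies of `dr + spacer`.
#' @export
crrna_energy <- function(spacer, dr, engine = default_fold_engine(),
                         min_hairpin = 3L) {
  if (missing(dr) || is.null(dr) || !nzchar(dr)) {
    abort("a direct-repeat (DR) sequence must be configured for crRNA energy")
  }
  dr <- assert_rna(dr, "direct repeat")
  spacer <- assert_rna(spacer, "spacer")
  fold_guides(paste0(dr, spacer), engine = engine, min_hairpin = min_hairpin)$mfe
}

#' Parse a dot-bracket string into a pair map
#'
#' @param db Dot-bracket string over `.`, `(`, `)`.
#' @return Integer vector; `pairs[i]` is the partner of position i, or
#'   `NA` if unpaired. Errors on unbalanced or crossing brackets.
#' @export
dotbracket_pairs <- function(db) {
  ch <- seq_chars(db)
  bad <- setdiff(unique(ch), c(".", "(", ")"))
  if (length(bad) > 0L) abort("dot-bracket contains invalid characters")
  pairs <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) abort(sprintf("unbalanced ')' at position %d", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  if (length(stack) > 0L) abort("unbalanced '(' in dot-bracket")
  pairs
}
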