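# The canonical 185-feature set used by the classical baselines and the
# off-target viability model: positional nucleotide and pairing-state
# indicators, mono- and dinucleotide composition, GC content (overall and
# in the 15-23 window), folding energies of the spacer ("energy") and of
# the DR+spacer crRNA ("crrna_energy"), structural summaries, target-region
# indicators and simple sequence fractions. The name order is fixed and
# versioned; downstream importance vectors align on it.

FEATURE_POSITIONS <- 30L

#' Canonical feature names (fixed order, 185 entries)
#' @return Character vector of length 185.
#' @export
canonical_feature_names <- function() {
  pos <- seq_len(FEATURE_POSITIONS)
  c(
    as.vector(t(outer(pos, SEQ_CHANNELS, function(p, n) sprintf("pos%02d_%s", p, n)))),
    sprintf("paired_pos%02d", pos),
    paste0("frac_", SEQ_CHANNELS),
    as.vector(t(outer(SEQ_CHANNELS, SEQ_CHANNELS, function(a, b) paste0("di_", a, b)))),
    "gc_content", "gc_15_23",
    "energy", "crrna_energy", "energy_per_nt",
    "paired_frac", "n_hairpins", "max_stem_len",
    paste0("region_", REGIONS),
    "spacer_length", "purine_frac", "au_frac"
  )
}

#' Extract the curated feature vector for one guide
#'
#' A pure function of (spacer, fold, crRNA energy, region): calling it
#' twice with the same inputs gives identical vectors. Positions beyond
#' the spacer length have all indicators 0; an unknown region sets all
#' region indicators to 0 with a warning.
#'
#' @param spacer RNA spacer.
#' @param fold A [fold_mfe()] result on the spacer.
#' @param crrna_fold_energy Folding energy of the DR+spacer crRNA
#'   ([crrna_energy()]).
#' @param region Target region: one of CDS, UTR5, UTR3, noncoding, or `NA`.
#' @return Named numeric vector of length 185 in canonical order.
#' @export
extract_features <- function(spacer, fold, crrna_fold_energy, region = NA_character_) {
  spacer <- assert_rna(spacer, "spacer")
  ch <- seq_chars(spacer)
  n <- length(ch)
  db <- seq_chars(fold$dot_bracket)
  stopifnot(length(db) == n)
  v <- setNames(numeric(185L), canonical_feature_names())

  pidx <- seq_len(min(n, FEATURE_POSITIONS))
  v[sprintf("pos%02d_%s", pidx, ch[pidx])] <- 1
  v[sprintf("paired_pos%02d", pidx)] <- as.numeric(db[pidx] != ".")

  v[paste0("frac_", SEQ_CHANNELS)] <- vapply(SEQ_CHANNELS, function(x) mean(ch == x), numeric(1))
  if (n >= 2L) {
    di <- paste0(ch[-n], ch[-1])
    tab <- table(factor(di, levels = as.vector(t(outer(SEQ_CHANNELS, SEQ_CHANNELS, paste0)))))
    v[paste0("di_", names(tab))] <- as.numeric(tab) / (n - 1L)
  }
  v["gc_content"] <- mean(ch %in% c("C", "G"))
  win <- intersect(15:23, seq_len(n))
  v["gc_15_23"] <- if (length(win) > 0) mean(ch[win] %in% c("C", "G")) else 0
  v["energy"] <- fold$mfe
  v["crrna_energy"] <- crrna_fold_energy
  v["energy_per_nt"] <- fold$mfe / n
  v["paired_frac"] <- mean(db != ".")
  v["n_hairpins"] <- length(gregexpr("\\(\\.*\\)", fold$dot_bracket)[[1]] [
    gregexpr("\\(\\.*\\)", fold$dot_bracket)[[1]] > 0])
  runs <- rle(db)
  v["max_stem_len"] <- max(c(0L, runs$lengths[runs$values == "("]))
  if (!is.na(region) && region %in% REGIONS) {
    v[paste0("region_", region)] <- 1
  } else if (!is.na(region)) {
    warn(sprintf("unknown region '%s': region indicators set to 0", region))
  }
  v["spacer_length"] <- n
  v["purine_frac"] <- mean(ch %in% c("A", "G"))
  v["au_frac"] <- mean(ch %in% c("A", "U"))
  v
}

#' Feature matrix for a guide table
#'
#' Folds every spacer (batched), computes crRNA energies against the
#' supplied direct repeat and stacks [extract_features()] rows.
#'
#' @param guides Guide tibble with `spacer` (and optionally `region`).
#' @param dr Direct-repeat sequence for the crRNA energy feature.
#' @param engine Folding engine.
#' @param folds Optional precomputed [fold_guides()] tibble.
#' @param crrna_energies Optional precomputed crRNA energies.
#' @return Tibble: `guide_id` plus the 185 canonical feature columns.
#' @export
extract_feature_matrix <- function(guides, dr, engine = default_fold_engine(),
                                   folds = NULL, crrna_energies = NULL) {
  stopifnot("spacer" %in% names(guides))
  if (is.null(folds)) folds <- fold_guides(guides$spacer, engine = engine)
  if (is.null(crrna_energies)) {
    crrna_energies <- crrna_energy(guides$spacer, dr, engine = engine)
  }
  region <- if ("region" %in% names(guides)) guides$region else rep(NA_character_, nrow(guides))
  rows <- lapply(seq_len(nrow(guides)), function(i) {
    extract_features(guides$spacer[i],
                     list(dot_bracket = folds$dot_bracket[i], mfe = folds$mfe[i]),
                     crrna_energies[i], region[i])
  })
  m <- do.call(rbind, rows)
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(guide_id = guides$guide_id %||% as.character(seq_len(nrow(guides)))), out)
  out
}
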