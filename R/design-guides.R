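#' Guide design rules
#'
#' Parameters for tiling guide design: guide length, forbidden cloning
#' motifs (BsmBI sites by default, screened on both strands of the DNA
#' rendering because the enzyme cuts double-stranded cloning oligos),
#' the mismatch allowance of the uniqueness filter, and how many guides to
#' keep per gene.
#'
#' @param guide_length Spacer length in nt (default 22).
#' @param forbidden_motifs Character vector of uppercase DNA motifs; any
#'   candidate whose DNA rendering (either strand) contains one is rejected.
#' @param max_mismatch_for_uniqueness Maximum Hamming mismatches at which a
#'   match inside another gene's transcripts disqualifies a candidate.
#' @param guides_per_gene Maximum number of guides retained per gene.
#' @return A `design_rules` list.
#' @export
design_rules <- function(guide_length = 22L,
                         forbidden_motifs = c("CGTCTC", "GAGACG"),
                         max_mismatch_for_uniqueness = 1L,
                         guides_per_gene = 15L) {
  guide_length <- as.integer(guide_length)
  if (guide_length < 15L) abort("guide_length must be at least 15 nt")
  forbidden_motifs <- toupper(forbidden_motifs)
  if (any(grepl("[^ACGT]", forbidden_motifs))) abort("forbidden_motifs must be uppercase DNA")
  structure(
    list(
      guide_length = guide_length,
      forbidden_motifs = forbidden_motifs,
      max_mismatch_for_uniqueness = as.integer(max_mismatch_for_uniqueness),
      guides_per_gene = as.integer(guides_per_gene)
    ),
    class = "design_rules"
  )
}

# all guide_length windows of a transcript (DNA rendering), 1-based starts
candidate_windows <- function(seq_dna, k) {
  n <- nchar(seq_dna)
  if (n < k) return(tibble(start = integer(0), window = character(0)))
  starts <- seq_len(n - k + 1L)
  tibble(start = starts, window = substring(seq_dna, starts, starts + k - 1L))
}

contains_forbidden_motif <- function(window_dna, motifs) {
  rc <- revcomp_dna(window_dna)
  vapply(seq_along(window_dna), function(i) {
    any(vapply(motifs, function(m) {
      grepl(m, window_dna[i], fixed = TRUE) || grepl(m, rc[i], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
}

# TRUE where the window (or its reverse complement) matches within
# max_mismatch inside any sequence of `subjects` (a DNAStringSet)
hits_other_genes <- function(windows_dna, subjects, max_mismatch) {
  if (length(subjects) == 0L) return(rep(FALSE, length(windows_dna)))
  vapply(windows_dna, function(w) {
    for (pat in c(w, revcomp_dna(w))) {
      p <- Biostrings::DNAString(pat)
      n <- sum(Biostrings::vcountPattern(p, subjects, max.mismatch = max_mismatch))
      if (n > 0L) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' Design tiling guides for each gene
#'
#' Enumerates all windows of `guide_length` along every transcript, removes
#' candidates that carry a forbidden cloning motif on either strand or that
#' match (within the configured mismatch allowance, either strand) inside a
#' different gene's transcripts, then selects up to `guides_per_gene` guides
#' per gene, preferring candidates shared by the most of the gene's
#' transcripts ("common" guides) and breaking ties with a seeded RNG.
#'
#' The spacer reported is the reverse complement of the transcript window in
#' the RNA alphabet (Cas13d spacers are antisense to their target RNA).
#' Uniqueness is screened against the supplied transcript set only, not a
#' whole genome.
#'
#' @param transcripts Named character vector of transcript sequences (DNA or
#'   RNA; names are transcript ids).
#' @param rules A [design_rules()] object.
#' @param seed Integer seed for the tie-breaking RNG.
#' @param genes Optional named character vector mapping transcript id to
#'   gene; defaults to one gene per transcript (gene = transcript id).
#' @return A tibble with columns `guide_id`, `spacer` (RNA), `gene`,
#'   `target_type`, `region`, `lfc`, `transcript_hits`, `transcript_id`,
#'   `start`, `end` (1-based inclusive coordinates on the representative
#'   transcript).
#' @export
design_guides <- function(transcripts, rules = design_rules(), seed = 1L,
                          genes = NULL) {
  stopifnot(length(transcripts) > 0L, !is.null(names(transcripts)))
  if (is.null(genes)) genes <- setNames(names(transcripts), names(transcripts))
  missing_map <- setdiff(names(transcripts), names(genes))
  if (length(missing_map) > 0L) {
    abort(sprintf("no gene assignment for transcript(s): %s",
                  paste(missing_map, collapse = ", ")))
  }
  tx_dna <- toupper(chartr("U", "T", transcripts))
  gene_of <- genes[names(tx_dna)]
  all_subjects <- Biostrings::DNAStringSet(tx_dna)

  set.seed(as.integer(seed))
  out <- list()
  for (g in unique(gene_of)) {
    tx_ids <- names(tx_dna)[gene_of == g]
    usable <- tx_ids[nchar(tx_dna[tx_ids]) >= rules$guide_length]
    if (length(usable) == 0L) {
      warn(sprintf("gene '%s': all transcripts shorter than guide_length (%d); skipped",
                   g, rules$guide_length))
      next
    }
    cand <- purrr::map_dfr(usable, function(id) {
      dplyr::mutate(candidate_windows(tx_dna[[id]], rules$guide_length),
                    transcript_id = id)
    })
    # transcript-hit count per unique window within this gene
    per_window <- cand |>
      dplyr::group_by(.data$window) |>
      dplyr::summarise(
        transcript_hits = dplyr::n_distinct(.data$transcript_id),
        transcript_id = dplyr::first(.data$transcript_id),
        start = dplyr::first(.data$start),
        .groups = "drop"
      )
    keep <- !contains_forbidden_motif(per_window$window, rules$forbidden_motifs)
    per_window <- per_window[keep, , drop = FALSE]
    if (nrow(per_window) > 0L) {
      other <- all_subjects[gene_of[names(tx_dna)] != g]
      cross <- hits_other_genes(per_window$window, other,
                                rules$max_mismatch_for_uniqueness)
      per_window <- per_window[!cross, , drop = FALSE]
    }
    if (nrow(per_window) == 0L) next
    # seeded selection: highest transcript-hit count first, random within ties
    ord <- order(-per_window$transcript_hits, runif(nrow(per_window)))
    sel <- per_window[head(ord, rules$guides_per_gene), , drop = FALSE]
    sel <- sel |>
      dplyr::mutate(
        gene = g,
        spacer = as_rna(revcomp_dna(.data$window)),
        end = .data$start + rules$guide_length - 1L
      )
    out[[g]] <- sel
  }
  if (length(out) == 0L) {
    return(tibble(
      guide_id = character(0), spacer = character(0), gene = character(0),
      target_type = character(0), region = character(0), lfc = numeric(0),
      transcript_hits = integer(0), transcript_id = character(0),
      start = integer(0), end = integer(0)
    ))
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(guide_id = sprintf("%s_g%03d", .data$gene, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(target_type = "mRNA", region = NA_character_, lfc = NA_real_) |>
    dplyr::select("guide_id", "spacer", "gene", "target_type", "region", "lfc",
                  "transcript_hits", "transcript_id", "start", "end")
  validate_guides(res)
  res
}
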