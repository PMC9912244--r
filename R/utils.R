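# Internal helpers shared across modules.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Upper-cases and converts T to U. Spacers are stored RNA-alphabet
#' internally; DNA is accepted on input.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector over A/C/G/U.
#' @export
as_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Render an RNA spacer as its DNA sense strand
#' @param x Character vector of RNA strings.
#' @return Character vector over A/C/G/T.
#' @export
as_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

# reverse complement of a DNA string (base R; kept dependency-free for
# per-window loops where DNAString construction would dominate)
revcomp_dna <- function(x) {
  comp <- chartr("ACGT", "TGCA", toupper(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}

assert_rna <- function(seq, what = "sequence") {
  seq <- as_rna(seq)
  bad <- grepl(paste0("[^", paste(RNA_ALPHABET, collapse = ""), "]"), seq)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside the RNA alphabet A/C/G/U (first offender: '%s')",
      what, seq[which(bad)[1]]
    ))
  }
  seq
}

seq_chars <- function(seq) strsplit(seq, "")[[1]]

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
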