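#' Read transcript sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that validates headers,
#' upper-cases sequences (U/T preserved as read) and truncates record ids at
#' the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record, in file order.
#'   An empty file yields an empty vector with a warning.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 some description", "ACGTACGT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warn(sprintf("FASTA file '%s' is empty; returning no sequences", path))
    return(setNames(character(0), character(0)))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf("malformed FASTA header at line %d of '%s': expected '>'", first, path))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  setNames(unname(seqs), ids)
}

guide_table_dialects <- function() {
  list(
    canonical = list(
      cols = c(
        guide_id = "guide_id", spacer = "spacer", gene = "gene",
        target_type = "target_type", region = "region", lfc = "lfc"
      ),
      delim = "\t"
    ),
    mageck = list(
      cols = c(guide_id = "sgrna", gene = "Gene", lfc = "LFC"),
      delim = "\t"
    )
  )
}

TARGET_TYPES <- c("mRNA", "lncRNA", "circRNA", "non_targeting")
REGIONS <- c("CDS", "UTR5", "UTR3", "noncoding")

#' Read a guide library table
#'
#' Reads a delimited guide table into a tibble of validated guide records.
#' Spacers are normalised to the RNA alphabet (T becomes U); rows whose LFC
#' cannot be parsed are kept, with `lfc` set to `NA` and `lfc_missing`
#' flagged, rather than dropped.
#'
#' @param path Path to a delimited file.
#' @param dialect `"canonical"` (columns guide_id, spacer, gene, target_type,
#'   region, lfc; tab-separated) or `"mageck"` (the sgRNA summary layout with
#'   columns sgrna, Gene, LFC).
#' @return A tibble with columns `guide_id`, `spacer`, `gene`, `target_type`,
#'   `region`, `lfc` and `lfc_missing`. Columns absent from the dialect are
#'   filled with `NA`.
#' @export
read_guide_table <- function(path, dialect = c("canonical", "mageck")) {
  dialect <- match.arg(dialect)
  spec <- guide_table_dialects()[[dialect]]
  raw <- readr::read_delim(path, delim = spec$delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(spec$cols), names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "guide table '%s' lacks mandatory column(s) %s; dialect '%s' expects: %s",
      path, paste(sQuote(missing_cols), collapse = ", "), dialect,
      paste(unname(spec$cols), collapse = ", ")
    ))
  }
  out <- tibble(
    guide_id = raw[[spec$cols[["guide_id"]]]],
    spacer = if ("spacer" %in% names(spec$cols)) raw[[spec$cols[["spacer"]]]] else NA_character_,
    gene = if ("gene" %in% names(spec$cols)) raw[[spec$cols[["gene"]]]] else NA_character_,
    target_type = if ("target_type" %in% names(spec$cols)) raw[[spec$cols[["target_type"]]]] else NA_character_,
    region = if ("region" %in% names(spec$cols)) raw[[spec$cols[["region"]]]] else NA_character_,
    lfc_raw = raw[[spec$cols[["lfc"]]]]
  )
  lfc <- suppressWarnings(as.numeric(out$lfc_raw))
  out <- out |>
    dplyr::mutate(
      spacer = ifelse(is.na(.data$spacer), NA_character_, as_rna(.data$spacer)),
      lfc = lfc,
      lfc_missing = is.na(lfc)
    ) |>
    dplyr::select(-"lfc_raw")
  validate_guides(out)
  out
}

#' Write a guide table in the canonical dialect
#'
#' @param guides A guide tibble as returned by [read_guide_table()] or
#'   [simulate_guides()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_guide_table <- function(guides, path) {
  cols <- c("guide_id", "spacer", "gene", "target_type", "region", "lfc")
  for (cc in setdiff(cols, names(guides))) guides[[cc]] <- NA
  readr::write_tsv(guides[cols], path, progress = FALSE)
  invisible(path)
}

validate_guides <- function(guides) {
  stopifnot(is.data.frame(guides), "guide_id" %in% names(guides))
  if (anyDuplicated(guides$guide_id)) {
    abort("guide_id values must be unique within a library")
  }
  sp <- guides$spacer[!is.na(guides$spacer)]
  if (length(sp) > 0L) {
    if (any(!nzchar(sp))) abort("empty spacer sequence")
    assert_rna(sp, "spacer")
  }
  invisible(guides)
}
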