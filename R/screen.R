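# Screen analysis: control-aware median-ratio normalisation, guide LFCs,
# a permutation-based gene negative-selection test whose null is drawn
# from the chosen negative-control guides (the mechanism by which the
# choice of controls changes a screen's hit list), and the TPR/FPR
# control benchmark.

#' Construct a screen matrix
#'
#' @param counts Non-negative integer matrix, guides x samples (rownames =
#'   guide ids, colnames = sample names).
#' @param sample_roles Named character vector mapping each sample to
#'   `"t0"` or `"t1"`; both roles must be present.
#' @param control_annotation Named per-guide vector over
#'   `non_targeting` / `non_essential_target` / `other`.
#' @param guides Optional guide tibble.
#' @return A `screen_matrix`.
#' @export
screen_matrix <- function(counts, sample_roles, control_annotation, guides = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  stopifnot(!is.null(colnames(counts)), !is.null(rownames(counts)))
  sample_roles <- sample_roles[colnames(counts)]
  if (!all(sample_roles %in% c("t0", "t1"))) abort("sample roles must be 't0' or 't1'")
  if (!all(c("t0", "t1") %in% sample_roles)) abort("need at least one t0 and one t1 sample")
  control_annotation <- control_annotation[rownames(counts)]
  stopifnot(all(control_annotation %in% c("non_targeting", "non_essential_target", "other")))
  structure(list(counts = counts, sample_roles = sample_roles,
                 control_annotation = control_annotation, guides = guides),
            class = "screen_matrix")
}

control_guide_index <- function(screen, control_set) {
  switch(control_set,
    none = seq_len(nrow(screen$counts)),
    non_targeting = which(screen$control_annotation == "non_targeting"),
    non_essential = which(screen$control_annotation == "non_essential_target")
  )
}

#' Median-ratio count normalisation on a chosen control set
#'
#' Size factors are the median, over the control guides, of each sample's
#' counts divided by the guide's geometric mean across samples (the
#' median-of-ratios estimator); `control_set = "none"` uses every guide.
#' Each sample is divided by its factor.
#'
#' @param screen A [screen_matrix()].
#' @param control_set `"none"`, `"non_targeting"` or `"non_essential"`.
#' @return List with `normalized` (numeric matrix) and `size_factors`.
#' @export
normalize_counts <- function(screen, control_set = c("none", "non_targeting", "non_essential")) {
  control_set <- match.arg(control_set)
  stopifnot(inherits(screen, "screen_matrix"))
  idx <- control_guide_index(screen, control_set)
  if (length(idx) == 0L) {
    abort(sprintf(
      "no guides annotated for control set '%s' (needs control_annotation '%s')",
      control_set,
      if (control_set == "non_targeting") "non_targeting" else "non_essential_target"))
  }
  sub <- screen$counts[idx, , drop = FALSE]
  log_gm <- rowMeans(log(sub))
  usable <- is.finite(log_gm)
  if (!any(usable)) abort("all control guides contain zero counts; cannot form reference")
  ref <- exp(log_gm[usable])
  sf <- apply(sub[usable, , drop = FALSE], 2, function(col) median(col / ref))
  if (any(sf <= 0)) abort("non-positive size factor; check input counts")
  list(normalized = sweep(screen$counts, 2, sf, "/"), size_factors = sf)
}

#' Per-guide log2 fold change between time points
#'
#' `log2((mean t1 + pc) / (mean t0 + pc))` on normalised counts.
#'
#' @param normalized Normalised count matrix.
#' @param sample_roles Named role vector as in [screen_matrix()].
#' @param pseudocount Pseudocount guarding zeros (default 1).
#' @return Named numeric vector of LFCs.
#' @export
guide_lfc <- function(normalized, sample_roles, pseudocount = 1.0) {
  sample_roles <- sample_roles[colnames(normalized)]
  m0 <- rowMeans(normalized[, sample_roles == "t0", drop = FALSE])
  m1 <- rowMeans(normalized[, sample_roles == "t1", drop = FALSE])
  log2((m1 + pseudocount) / (m0 + pseudocount))
}

#' Gene-level negative selection by mean-rank permutation test
#'
#' Each gene's score is the mean rank of its guides' LFCs (ascending, so
#' depleted genes score low) among all guides. The null distribution is
#' built by drawing same-sized guide sets from the control pool
#' (`control = NULL` uses all guides, the exchangeable null); the p-value
#' is the left-tail probability with the add-one correction, so
#' `p >= 1/(n_perm+1)`. FDR is Benjamini-Hochberg across genes.
#'
#' Anchoring the null on the chosen negative-control guides is what makes
#' the control choice matter: the rank statistic itself is invariant to
#' the global shift that renormalisation induces.
#'
#' @param data Tibble with columns `gene` and `lfc`, one row per guide;
#'   genes with `NA` gene are excluded from testing but kept in the
#'   ranking.
#' @param n_perm Number of permutation draws (>= 100).
#' @param seed Seed.
#' @param control Optional logical/integer index of the control guides
#'   forming the null pool.
#' @param test_genes Optional subset of genes to test (default: all genes
#'   with at least `min_guides` guides).
#' @param min_guides Minimum guides per tested gene (default 2).
#' @return A `gene_selection` tibble: `gene`, `n_guides`, `score`, `p`,
#'   `fdr`, sorted by p.
#' @export
gene_negative_selection <- function(data, n_perm = 10000L, seed = 1L,
                                    control = NULL, test_genes = NULL,
                                    min_guides = 2L) {
  stopifnot(all(c("gene", "lfc") %in% names(data)))
  if (n_perm < 100L) abort("n_perm must be at least 100")
  lfc <- data$lfc
  if (anyNA(lfc)) abort("LFCs must be non-missing")
  r <- rank(lfc)
  pool <- if (is.null(control)) r else r[control]
  if (length(pool) < 2L) abort("control pool too small to form a null")
  counts <- table(data$gene[!is.na(data$gene)])
  genes <- names(counts)[counts >= min_guides]
  if (!is.null(test_genes)) genes <- intersect(genes, test_genes)
  if (length(genes) == 0L) abort("no genes with enough guides to test")
  obs <- vapply(genes, function(g) mean(r[data$gene == g & !is.na(data$gene)]), numeric(1))
  sizes <- as.integer(counts[genes])
  set.seed(seed)
  p <- numeric(length(genes))
  for (s in unique(sizes)) {
    null_scores <- vapply(seq_len(n_perm), function(i) {
      mean(pool[sample.int(length(pool), s, replace = s > length(pool))])
    }, numeric(1))
    sel <- sizes == s
    ecdf_counts <- vapply(obs[sel], function(o) sum(null_scores <= o), numeric(1))
    p[sel] <- (1 + ecdf_counts) / (n_perm + 1)
  }
  out <- tibble(gene = genes, n_guides = sizes, score = unname(obs), p = p,
                fdr = p.adjust(p, method = "BH")) |>
    dplyr::arrange(.data$p)
  class(out) <- c("gene_selection", class(out))
  out
}

#' TPR/FPR benchmark across negative-control choices
#'
#' For each control choice (`none`, `non_targeting`, `non_essential`) the
#' screen is renormalised on that control set, guide LFCs recomputed, the
#' gene test run with the null drawn from the same control guides, and
#' the true-positive rate (fraction of known essential genes with
#' `fdr < cutoff`) and false-positive rate (same fraction among known
#' non-essential genes) evaluated on an FDR-cutoff grid.
#'
#' @param screen A [screen_matrix()].
#' @param essential_set,nonessential_set Disjoint, non-empty gene sets.
#' @param fdr_grid FDR cutoffs (default `c(0.01, 0.05, 0.1, 0.25)`).
#' @param controls Control choices to benchmark.
#' @param n_perm,seed Permutation-test settings.
#' @param pseudocount LFC pseudocount.
#' @return A `control_benchmark` tibble: `control`, `fdr_cutoff`, `tpr`,
#'   `fpr`, `n_essential`, `n_nonessential`.
#' @export
control_benchmark <- function(screen, essential_set, nonessential_set,
                              fdr_grid = c(0.01, 0.05, 0.1, 0.25),
                              controls = c("none", "non_targeting", "non_essential"),
                              n_perm = 2000L, seed = 1L, pseudocount = 1.0) {
  stopifnot(inherits(screen, "screen_matrix"))
  if (length(essential_set) == 0L || length(nonessential_set) == 0L) {
    abort("both truth sets must be non-empty")
  }
  if (length(intersect(essential_set, nonessential_set)) > 0L) {
    abort("essential and non-essential truth sets overlap")
  }
  genes <- screen$guides$gene %||% rownames(screen$counts)
  res <- purrr::map_dfr(controls, function(ctrl) {
    nm <- normalize_counts(screen, ctrl)
    lfc <- guide_lfc(nm$normalized, screen$sample_roles, pseudocount)
    dat <- tibble(gene = genes, lfc = unname(lfc))
    ctrl_idx <- control_guide_index(screen, ctrl)
    gs <- gene_negative_selection(dat, n_perm = n_perm, seed = seed,
                                  control = ctrl_idx,
                                  test_genes = c(essential_set, nonessential_set))
    purrr::map_dfr(fdr_grid, function(cut) {
      sig <- gs$gene[gs$fdr < cut]
      tibble(
        control = ctrl, fdr_cutoff = cut,
        tpr = mean(essential_set %in% sig),
        fpr = mean(nonessential_set %in% sig),
        n_essential = length(essential_set),
        n_nonessential = length(nonessential_set)
      )
    })
  })
  class(res) <- c("control_benchmark", class(res))
  res
}

#' Read a count matrix in the sgRNA-count table dialect
#'
#' Tab-separated with columns `sgRNA`, `Gene`, then one column per sample.
#'
#' @param path File path.
#' @param sample_roles Named role vector for the sample columns.
#' @param control_annotation Optional per-guide annotation (default
#'   `"other"`; guides with gene `"non_targeting"` are annotated as such).
#' @return A [screen_matrix()].
#' @export
read_count_table <- function(path, sample_roles, control_annotation = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sgRNA", "Gene") %in% names(raw))) {
    abort("count table must have columns sgRNA, Gene, then sample columns")
  }
  samples <- setdiff(names(raw), c("sgRNA", "Gene"))
  counts <- as.matrix(raw[samples])
  rownames(counts) <- raw$sgRNA
  if (is.null(control_annotation)) {
    control_annotation <- setNames(
      ifelse(raw$Gene == "non_targeting", "non_targeting", "other"), raw$sgRNA)
  }
  screen_matrix(counts, sample_roles, control_annotation,
                guides = tibble(guide_id = raw$sgRNA, gene = raw$Gene))
}

#' Write gene selection results
#' @param x A `gene_selection` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_selection <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
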