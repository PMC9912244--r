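# Synthetic Cas13d proliferation screens with planted, known ground truth.
# The generator emulates the study design this package models: 22-nt
# spacers tiled ~30 per gene, guide efficiency driven by C/G content at
# spacer positions 15-23 and by structural openness (folding energy),
# essential-gene depletion proportional to efficiency, an
# efficiency-coupled off-target depletion acting on every targeting guide,
# and negative-binomial sequencing counts.

#' Simulation configuration
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene Guides per gene (default 30, the tiling density
#'   of the screens this emulates).
#' @param guide_length Spacer length in nt (default 22).
#' @param frac_essential Fraction of genes that are essential.
#' @param essential_effect Log2 depletion of a fully efficient guide on a
#'   fully essential gene over the screen (default 3, a strong but
#'   realistic proliferation-screen effect).
#' @param essential_strength Beta shape parameters `c(a, b)` of the
#'   per-gene essentiality-strength multiplier (default `c(5, 1.2)`: most
#'   essential genes near full strength, a tail of marginal ones, as in
#'   real viability screens where many known essentials are only weakly
#'   depleted).
#' @param offtarget_coupling Efficiency-proportional log2 depletion applied
#'   to every targeting guide regardless of its target (default 0.3); this
#'   is the collateral-activity term.
#' @param nb_dispersion Negative-binomial dispersion of endpoint counts
#'   (variance = mu + dispersion * mu^2; default 0.1).
#' @param depth Sequencing reads per sample (default 1e6).
#' @param noise_sd SD of guide-level Gaussian LFC noise (default 0.4).
#' @param n_nontargeting Number of non-targeting control guides (default 150).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 100L, guides_per_gene = 30L, guide_length = 22L,
                       frac_essential = 0.5, essential_effect = 3,
                       essential_strength = c(5, 1.2),
                       offtarget_coupling = 0.3, nb_dispersion = 0.1,
                       depth = 1e6, noise_sd = 0.4, n_nontargeting = 150L,
                       seed = 1L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, guide_length >= 15,
            frac_essential > 0, frac_essential < 1, essential_effect > 0,
            length(essential_strength) == 2, all(essential_strength > 0),
            offtarget_coupling >= 0, nb_dispersion > 0, depth >= 1,
            noise_sd >= 0, n_nontargeting >= 0)
  structure(list(
    n_genes = as.integer(n_genes), guides_per_gene = as.integer(guides_per_gene),
    guide_length = as.integer(guide_length), frac_essential = frac_essential,
    essential_effect = essential_effect, essential_strength = essential_strength,
    offtarget_coupling = offtarget_coupling,
    nb_dispersion = nb_dispersion, depth = depth, noise_sd = noise_sd,
    n_nontargeting = as.integer(n_nontargeting), seed = as.integer(seed)
  ), class = "sim_config")
}

random_spacers <- function(n, len) {
  m <- matrix(sample(RNA_ALPHABET, n * len, replace = TRUE), n, len)
  apply(m, 1, paste, collapse = "")
}

#' Simulate a guide library
#'
#' Generates seeded i.i.d.-uniform spacers for `n_genes` genes (partitioned
#' essential / non-essential by `frac_essential`) plus non-targeting
#' control guides.
#'
#' @param cfg A [sim_config()].
#' @return A guide tibble with the usual columns plus `essential`.
#' @export
simulate_guides <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_ess <- max(1L, round(cfg$frac_essential * cfg$n_genes))
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  essential_genes <- genes[seq_len(n_ess)]
  strength <- ifelse(genes %in% essential_genes,
                     rbeta(cfg$n_genes, cfg$essential_strength[1], cfg$essential_strength[2]),
                     0)
  n_t <- cfg$n_genes * cfg$guides_per_gene
  targeting <- tibble(
    guide_id = sprintf("g%05d", seq_len(n_t)),
    spacer = random_spacers(n_t, cfg$guide_length),
    gene = rep(genes, each = cfg$guides_per_gene),
    target_type = "mRNA",
    region = "CDS",
    lfc = NA_real_,
    essential = rep(genes %in% essential_genes, each = cfg$guides_per_gene),
    gene_strength = rep(strength, each = cfg$guides_per_gene)
  )
  if (cfg$n_nontargeting > 0L) {
    nt <- tibble(
      guide_id = sprintf("nt%04d", seq_len(cfg$n_nontargeting)),
      spacer = random_spacers(cfg$n_nontargeting, cfg$guide_length),
      gene = "non_targeting",
      target_type = "non_targeting",
      region = NA_character_,
      lfc = NA_real_,
      essential = FALSE,
      gene_strength = 0
    )
    targeting <- dplyr::bind_rows(targeting, nt)
  }
  validate_guides(targeting)
  targeting
}

#' Planted guide efficiency
#'
#' The closed-form planted signal:
#' `efficiency = plogis(w_cg * (cg_15_23 - 0.5) + w_open * (openness - 0.5) + bias)`
#' where `cg_15_23` is the C/G fraction at spacer positions 15-23 (clipped
#' to the available length) and `openness = clamp(1 + mfe / 10, 0, 1)`
#' rescales the folding energy so that less-folded guides (energy nearer
#' zero) are more efficient. Both determinants mirror the empirical
#' drivers of Cas13d guide activity.
#'
#' @param spacers Character vector of RNA spacers.
#' @param folds Tibble from [fold_guides()] (column `mfe`), matched by row.
#' @param weights Numeric `c(w_cg, w_open, bias)`; defaults `c(6, 3, 0)`.
#' @return Numeric efficiencies in (0, 1).
#' @export
planted_efficiency <- function(spacers, folds, weights = c(w_cg = 6, w_open = 3, bias = 0)) {
  stopifnot(length(spacers) == nrow(folds))
  cg <- vapply(spacers, function(s) {
    ch <- seq_chars(s)
    win <- ch[seq(min(15L, length(ch)), min(23L, length(ch)))]
    mean(win %in% c("C", "G"))
  }, numeric(1), USE.NAMES = FALSE)
  open <- pmin(1, pmax(0, 1 + folds$mfe / 10))
  plogis(weights[[1]] * (cg - 0.5) + weights[[2]] * (open - 0.5) + weights[[3]])
}

#' Simulate a pooled proliferation screen
#'
#' Expected guide LFC is
#' `-essential_effect * gene_strength * efficiency - offtarget_coupling * efficiency`
#' for targeting guides (0 for non-targeting controls; `gene_strength` is 0
#' for non-essential genes), plus Gaussian noise. Start-point (t0) counts are multinomial at the configured depth
#' over mildly uneven library abundances; endpoint (t1) counts are
#' negative-binomial around the depleted expectation. Ground truth
#' (efficiency, expected and realized LFC, essentiality) is returned.
#'
#' @param guides Guide tibble from [simulate_guides()].
#' @param efficiencies One efficiency per guide ([planted_efficiency()]).
#' @param cfg The [sim_config()].
#' @param n_reps Replicates per time point (default 2).
#' @return A `screen_matrix`: list with `counts` (guides x samples),
#'   `sample_roles`, `control_annotation`, `guides` and `truth`.
#' @export
simulate_screen <- function(guides, efficiencies, cfg = sim_config(), n_reps = 2L) {
  n <- nrow(guides)
  stopifnot(length(efficiencies) == n)
  set.seed(cfg$seed + 7L)
  targeting <- guides$target_type != "non_targeting"
  strength <- guides$gene_strength %||% as.numeric(guides$essential)
  mu_lfc <- ifelse(targeting,
                   -cfg$essential_effect * strength * efficiencies -
                     cfg$offtarget_coupling * efficiencies,
                   0)
  lfc <- mu_lfc + rnorm(n, 0, cfg$noise_sd)
  base <- rgamma(n, shape = 10, rate = 10)  # mild library-abundance spread
  p0 <- base / sum(base)
  if (cfg$depth < 50 * n) warn("sequencing depth is small for this guide count")
  samples <- c(sprintf("t0_r%d", seq_len(n_reps)), sprintf("t1_r%d", seq_len(n_reps)))
  roles <- setNames(c(rep("t0", n_reps), rep("t1", n_reps)), samples)
  counts <- matrix(0L, n, length(samples), dimnames = list(guides$guide_id, samples))
  for (j in seq_len(n_reps)) {
    counts[, j] <- rmultinom(1, cfg$depth, p0)[, 1]
  }
  p1 <- base * 2^lfc
  p1 <- p1 / sum(p1)
  for (j in seq_len(n_reps)) {
    counts[, n_reps + j] <- rnbinom(n, size = 1 / cfg$nb_dispersion, mu = cfg$depth * p1)
  }
  annot <- dplyr::case_when(
    guides$target_type == "non_targeting" ~ "non_targeting",
    !guides$essential ~ "non_essential_target",
    TRUE ~ "other"
  )
  truth <- tibble(
    guide_id = guides$guide_id, gene = guides$gene, essential = guides$essential,
    gene_strength = strength, efficiency = efficiencies,
    expected_lfc = mu_lfc, realized_lfc = lfc
  )
  structure(list(
    counts = counts,
    sample_roles = roles,
    control_annotation = setNames(annot, guides$guide_id),
    guides = guides,
    truth = truth
  ), class = "screen_matrix")
}

#' Simulate a complete screen in one call
#'
#' Convenience wrapper: guides, folding, planted efficiencies, screen.
#'
#' @param cfg A [sim_config()].
#' @param engine Folding engine (default the deterministic internal
#'   fallback, so simulations need no external binary).
#' @param weights Planted-signal weights for [planted_efficiency()].
#' @param n_reps Replicates per time point.
#' @return The `screen_matrix`, with `folds` attached.
#' @export
simulate_full_screen <- function(cfg = sim_config(), engine = "maxpair",
                                 weights = c(w_cg = 6, w_open = 3, bias = 0),
                                 n_reps = 2L) {
  guides <- simulate_guides(cfg)
  folds <- fold_guides(guides$spacer, engine = engine)
  eff <- planted_efficiency(guides$spacer, folds, weights)
  scr <- simulate_screen(guides, eff, cfg, n_reps = n_reps)
  scr$folds <- folds
  scr
}

#' A synthetic direct-repeat sequence
#'
#' A fixed, clearly synthetic stand-in for the Cas13d direct repeat, for
#' examples and simulations; real analyses should supply the DR of the
#' system under study.
#'
#' @param length DR length (default 30).
#' @param seed Seed.
#' @return An RNA string.
#' @export
synthetic_dr <- function(length = 30L, seed = 99L) {
  set.seed(seed)
  paste(sample(RNA_ALPHABET, length, replace = TRUE), collapse = "")
}
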