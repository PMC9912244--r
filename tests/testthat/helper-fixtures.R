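# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# a mid-sized simulated screen with defaults (the study conditions)
default_screen <- function() {
  memo("default_screen", function() {
    simulate_full_screen(sim_config(seed = 21L))
  })
}

# a small planted-signal guide set with LFCs for quick model tests
planted_guides <- function() {
  memo("planted_guides", function() {
    cfg <- sim_config(n_genes = 20L, guides_per_gene = 30L, frac_essential = 0.95,
                      n_nontargeting = 0L, seed = 301L)
    scr <- simulate_full_screen(cfg)
    keep <- scr$guides$essential
    g <- scr$guides[keep, ]
    g$lfc <- scr$truth$realized_lfc[keep]
    list(guides = g, folds = scr$folds[keep, ],
         efficiency = scr$truth$efficiency[keep])
  })
}

# a small CRNN trained on the planted guides (used by deep-model and
# attribution tests)
trained_crnn <- function() {
  memo("trained_crnn", function() {
    pg <- planted_guides()
    enc <- encode_guide_set(pg$guides$spacer, L = 30L, folds = pg$folds)
    y <- lfc_to_target(pg$guides$lfc)
    cfg <- model_config(conv_filters = 16L, recurrent_units = 32L,
                        dense_units = 32L, seed = 7L)
    m <- build_crnn(cfg, L = 30L)
    m <- fit_crnn(m, enc, y, epochs = 15L)
    list(model = m, enc = enc, y = y, guides = pg$guides)
  })
}

# independent brute-force oracle: maximum pairing count by exhaustive
# recursion over all nested structures (no DP)
brute_force_max_pairs <- function(seq, min_hairpin = 3L) {
  ch <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L) return(0L)
    best <- rec(i + 1L, j)                      # i unpaired
    for (k in (i + min_hairpin + 1L):j) {
      if (ok(ch[i], ch[k])) {
        inner <- rec(i + 1L, k - 1L)
        right <- if (k + 1L <= j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + right)
      }
    }
    best
  }
  if (length(ch) < min_hairpin + 2L) return(0L)
  rec(1L, length(ch))
}

random_rna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}
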