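---
title: "Modelling Cas13d guide efficiency and screen controls: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Cas13d guide efficiency and screen controls: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `cas13design`, in the spirit of the long-form methods
sections that accompany differential-expression or ordination packages. It
states design rationale only; every empirical number the package claims is
computed by the test suite or by `scripts/acceptance.R`, not here.

## The prediction problem

A Cas13d guide is a 22–30-nt spacer antisense to a target transcript.
In pooled proliferation screens, guide abundance at the endpoint relative
to the start (log2 fold change, LFC) reports the fitness consequence of
expressing the guide: for essential targets, effective guides deplete.
The modelling task is to predict that effectiveness from the spacer
sequence and its predicted secondary structure alone.

### Target normalisation

Raw LFCs are unbounded and screen-scaled, so they are mapped to
(0, 1) through a calibrated logistic,

$$S(x) = \frac{1}{1 + e^{-nx + b}},$$

with $(n, b)$ solved from two anchor points, by default $S(0) = 0.3$ and
$S(-0.3) = 0.7$. In logit space both constraints are linear, so the
solution is closed-form (`solve_sigmoid_params()`): $b = \ln(7/3) \approx
0.84730$ and $n = -2\ln(7/3)/0.3 \approx -5.64865$, verified to
$10^{-10}$. The anchors deliberately place neutral guides ($x = 0$) well
below the midpoint, pushing the mass of effective guides (LFC below about
$-0.5$) towards 1. For classification metrics, positives are guides with
$\text{LFC} \le -0.5$; the boundary is inclusive, and both the threshold
and the anchors are configurable.

### Secondary structure

Structure is predicted per spacer. Two engines sit behind one interface:

* `"thermo"` shells out to RNAfold when it is on the PATH, parsing the
  dot-bracket and the minimum free energy (kcal/mol).
* `"maxpair"` is an internal dynamic-programming folder maximising
  Watson–Crick plus G·U pairs subject to a minimum hairpin loop of 3 nt
  (the standard steric floor). Its traceback is deterministic — the
  5'-most base pairs first, with its 3'-most compatible partner — and its
  energy proxy is $-1 \times$ the pair count, preserving the ordering
  "more paired = lower energy" that the features and the simulator rely
  on. It exists so that unit tests, simulations and offline use need no
  external binary, and it is pinned against exhaustive enumeration of all
  nested structures on short sequences.

For the network's structure channel the spacer alone is folded; folding
the direct repeat together with the spacer is exposed as an option
(`crrna_energy()`), because the DR+spacer energy is itself a known
activity determinant and one of the curated features. No DR sequence is
baked in — it must be supplied; `synthetic_dr()` provides a clearly
labelled synthetic stand-in for simulations.

### Encoding

Guides are one-hot encoded: an $L \times 4$ sequence matrix (A, C, G, U)
and an $L \times 3$ structure matrix over dot-bracket symbols, plus a
validity mask. $L$ defaults to 30 so that both 22-nt and 27-nt libraries
fit one model; shorter guides are right-padded with all-zero rows, and the
mask excludes padded positions from the convolutional activations. The
three-symbol structure encoding (rather than a binary paired/unpaired
state) preserves pairing directionality at no real cost. Encoding is
exactly invertible, which the tests assert for every length up to $L$.

## The efficiency network

Two parallel branches — sequence and structure — share a topology:
two blocks of 1-D convolution (valid padding, full channel depth) with
batch normalisation and ReLU, dropout at rate 0.5, width-2 max pooling, an
LSTM whose final hidden state summarises the pooled sequence, dropout at
rate 0.3, and a dense layer. The branch outputs are concatenated and a
single sigmoid unit produces the deep score in $[0, 1]$. Training
minimises mean squared error against the sigmoid-normalised LFC targets
with Adam; the per-epoch training MSE is recorded and `tidy()` returns it.

The dropout rates and the two-conv-per-branch topology are fixed by
design; layer sizes are not, so `model_config()` defaults (32 filters,
kernel width 4, 64 LSTM units, 64 dense units, batch 64, learning rate
$10^{-3}$, 100 epochs) are explicit, configurable choices. `tune_grid()`
searches the four that matter in practice — dense width, dropout,
optimizer, learning rate — over their cartesian product against a held-out
split.

The entire network, including backpropagation through the LSTM and the
batch-norm layers, is implemented in vectorised base R. This is a
deliberate choice, not a compromise: the model is small (well under a
million parameters), BLAS-backed matrix multiplies dominate the cost, and
owning the backward pass gives exact input-space gradients — the quantity
Integrated Gradients needs — without a second implementation. Gradient
correctness is established by central-difference checks during
development; reproducibility is exact, because initialisation, shuffling
and dropout all draw from one seeded RNG stream. Prediction runs in
evaluation mode (running batch-norm statistics, no dropout), so scores are
per-guide deterministic and invariant to batch composition.

Numerical conventions worth stating: batch-norm uses $\epsilon = 10^{-5}$
and momentum 0.9 on running statistics; the LSTM forget-gate bias starts
at 1; max-pool ties resolve to the earlier position; a non-finite training
loss aborts with diagnostics rather than continuing.

## Attribution

`integrated_gradients()` implements the right-Riemann path integral
$(x_i - x'_i)\,\frac{1}{m}\sum_{k=1}^m \partial F(x' + \tfrac{k}{m}(x -
x'))/\partial x_i$ against an all-zero baseline (the natural "no
sequence" reference; the paper-level choice is unstated, so the baseline
is an argument). The completeness residual
$|\sum \text{IG} - (F(x) - F(x'))|$ is attached to every map; it converges
as $1/m$ and the acceptance suite requires it below 1% of the score gap at
256 steps. Because the baseline shares the input's padding, attributions
at padded positions are identically zero. `position_importance()`
averages, per position and nucleotide, the attribution of the *observed*
channel across guides — the summary behind position-preference profiles —
with optional normalisation to unit absolute mass. Attribution on the
pre-sigmoid logit is available where saturation is a concern.

## Curated features and baselines

The classical-ML track uses a fixed, versioned vector of exactly 185
features: 120 positional nucleotide indicators (30 positions × 4), 30
positional pairing-state indicators, 4 mononucleotide and 16 dinucleotide
fractions, overall GC and GC in the 15–23 window, the spacer folding
energy, the DR+spacer (crRNA) energy, energy per nucleotide, paired
fraction, hairpin count, maximum stem run, 4 region indicators, spacer
length, and purine and A/U fractions. Positions past the spacer end are
all-zero (the imputation rule); unknown regions zero the region block with
a warning. The name order is part of the contract — importance vectors
align on it — and a checksum test pins it.

Baselines are trained with library defaults and a fixed seed: random
forest (`randomForest`), XGBoost, and an RBF support-vector regression
(`e1071`). AdaBoost.R2 and least-squares gradient boosting are implemented
in-package over `rpart` trees (fifty and one hundred rounds respectively,
shrinkage 0.1, depth-3 trees), as no dedicated package for either ships
with the declared dependencies; both are classical algorithms of a few
dozen lines and are tested for determinism and separation.

## Off-target viability model

Guides targeting confirmed non-essential genes cannot deplete through
their target, so their strongest dropouts isolate guide-intrinsic
(collateral) viability effects. `make_offtarget_labels()` marks the lowest
LFC quartile (exactly $\lfloor 0.25 n \rfloor$ guides, ties broken by
(LFC, guide id)) as "strong depletion", refusing datasets contaminated
with essential-gene guides. A random forest over the 185 features
separates strong from rest; importances (mean impurity decrease) are
normalised to sum one so they can be correlated across datasets (the
consistency check) and against the analogous on-target model trained on
essential-gene guides with the same quartile rule — the symmetric-quantile
choice is ours, as the strong/weak split for the on-target comparison is
not fully specified anywhere. Random-forest size is the library default
(500 trees).

## Screen analysis and the choice of negative controls

Counts are normalised by median-of-ratios size factors computed **on the
chosen control set** — all guides ("none"), non-targeting guides, or
guides targeting non-essential genes — and guide LFC is
$\log_2((\bar{t_1} + 1)/(\bar{t_0} + 1))$ on normalised means.

Gene-level negative selection is a mean-rank statistic: a gene's score is
the mean rank of its guides' LFCs among all guides, and its p-value is the
left tail of a permutation null built by drawing same-sized guide sets
**from the control pool**, with the add-one correction (so
$p \ge 1/(n_{\text{perm}}+1)$) and Benjamini–Hochberg FDR across genes.
Anchoring the null on the controls is the load-bearing decision: a rank
statistic is invariant to the global shift that renormalisation induces,
so normalisation alone cannot make the control choice matter; drawing the
null from the control guides is exactly how control-aware rank
aggregation behaves in established screen pipelines, and it reduces to
the ordinary exchangeable permutation when the pool is "all guides" —
which is the configuration under which the calibration tests (KS
uniformity of null p-values, validity at $\alpha = 0.05, 0.1$) run. This
mean-rank test is a deliberately lightweight stand-in for full robust
rank aggregation, which is out of scope; the control-choice comparison
only needs a calibrated negative-selection test.

`control_benchmark()` then reports, per control choice and FDR cutoff, the
fraction of known essential genes detected (TPR) and of known
non-essential genes falsely detected (FPR). Under collateral-coupled
simulation the expected ordering emerges: non-targeting controls sit
outside the collateral depletion shared by every targeting guide, so
non-essential genes look significant against them (high FPR), while
non-essential-target controls absorb that shared depletion (low FPR) and
give a cleaner null than "no controls" (higher TPR).

## The synthetic screen generator

The generator is the package's study design, not a tuning knob. Defaults:
100 genes × 30 guides of 22 nt (the tiling density of the screens this
emulates), half the genes essential, 150 non-targeting controls, two
replicates per time point at $10^6$ reads each.

Guide efficiency is planted as
$e = \text{logistic}(6\,(\text{CG}_{15\text{–}23} - 0.5) + 3\,(\text{open} - 0.5))$,
where $\text{CG}_{15\text{–}23}$ is the C/G fraction in the positional
window empirically associated with high activity and
$\text{open} = \text{clamp}(1 + \text{MFE}/10,\, 0,\, 1)$ rescales folding
energy so less-folded guides are more efficient — the two determinants the
interpretability stack (IG, importances) must recover as known truth. The
weights give sequence roughly twice the structural leverage, with
efficiencies spanning roughly 0.1–0.9 over random spacers.

Expected LFC is $-3\, m_g\, e$ for essential targets plus a collateral
term $-0.3\, e$ on every targeting guide, plus $N(0, 0.4^2)$ guide noise;
$m_g \sim \text{Beta}(5, 1.2)$ is a per-gene essentiality strength. The
Beta spread reflects how real viability screens behave — most library
"essentials" deplete strongly but a tail is only marginal (screens of this
kind typically confirm a minority of annotated essentials at FDR 10%) —
and it is what gives the control benchmark genes near the decision
boundary; a constant essentiality would saturate every test. The noise SD
(0.4) and the non-targeting count (150) are fields the simulation model
needs that the study description leaves implicit; both are fixed here at
values typical of well-powered screens. Start counts are multinomial at
depth over mildly uneven library abundances (Gamma(10, 10) weights);
endpoint counts are negative-binomial around the depleted expectation with
dispersion 0.1, the standard overdispersed count model for screens.

What the generator does *not* emulate: PCR amplification bias, positional
effects along the transcript, mechanistic collateral cleavage of specific
bystander transcripts, or cell-line-specific expression. Passing tests on
these simulations therefore demonstrates that the algorithms recover the
signal they are pointed at, under realistic counting noise — not that any
particular real screen will reach the same numbers.

## Problem sizes in the test and acceptance runs

The cross-validation property runs on 2,010 essential-gene guides (67
genes × 30) with 20 epochs per fold; the benchmark and importance
properties use the default 100-gene screen; permutation tests use 2,000
draws; IG convergence uses 256 steps. These sizes were chosen as the
smallest at which the planted effects are comfortably estimable.

## Known limitations

* The uniqueness filter in guide design scans only the supplied transcript
  set (both strands, Hamming distance) — genome-scale screening belongs to
  dedicated aligners and is deliberately out of scope.
* The `maxpair` energy proxy is a pair count, not a thermodynamic energy;
  analyses that interpret energies in kcal/mol should use the RNAfold
  engine.
* The mean-rank permutation test is not robust rank aggregation; with very
  few guides per gene its resolution is limited by $1/(n_{\text{perm}}+1)$.
* Published headline performance on real tiling and circRNA screens
  depends on external datasets; the package's evaluation protocols
  (top/bottom-4 filtering, leave-one-dataset-out, top-fraction gene
  subsetting) are implemented and tested on synthetic data, but the
  numbers from those papers are not reproduced here.
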