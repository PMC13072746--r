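---
title: "Validating protein folding rate models with FoldRateBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating protein folding rate models with FoldRateBench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FoldRateBench)
```

## The model and its assumptions

The folding rate of a protein is $k_f = 1/t$, with $t$ the folding time;
it is modelled on the natural-log scale. The package's baseline is the
two-parameter chain-length law

$$\ln(k_f) = a_0 + a_1 \ln(L),$$

with $L$ the number of residues. The fit is ordinary least squares in
closed form: the slope is the centered cross-moment of $\ln L$ and
$\ln(k_f)$ over the centered second moment of $\ln L$, and the intercept
follows from the means. Observations are unweighted, and duplicated
records (the same PDB code listed twice with different measured rates, as
real compilations do) are kept as independent observations. The model
assumes nothing about the residual distribution for fitting; the Gaussian
assumption enters only through the synthetic-data generator (below).

The fitted object carries a *minimal applicability domain* in the QSAR
sense: the inclusive training length range. `inDomain()` classifies a
query length as `inside`, `outside-low` or `outside-high`; predictions
outside the domain are still computed (the caller may want them) but
should be treated as extrapolation.

## Provenance-aware subsets

Different compilations disagree about the same proteins, so a shared
protein's *data provenance* must be explicit. `datasetOverlap(A, B)`
returns the records of `A` whose PDB code occurs in `B` — data from `A`,
order of `A` — and `datasetOverlap(B, A)` is the mirror subset with `B`'s
data. `datasetDifference(A, B)` keeps `A`'s unshared records. Every copy
of a duplicated code in the provenance set is kept, while membership in
the second set is tested against distinct codes only; consequently the
two overlaps of a pair can have different sizes while sharing the same
distinct codes, and for every pair the overlap and difference partition
the provenance set exactly (`partitionCheck()`).

In the benchmark workflow the overlaps are training sets and the
differences are external test sets: the most stringent and least used
check of a folding-rate model is its error on proteins it never saw.

## Validation statistics

`rmse()`, `pcc()` and `mae()` are computed between observed and predicted
$\ln(k_f)$. Three evaluation modes share one report type:

- **fit** — residuals of the training fit;
- **loo** — leave-one-out cross-validation by explicit refits: each
  record is predicted by a model fitted on the other $n-1$. Datasets here
  are small (≤ ~150), so refitting is cheap and transparent; the
  algebraically equivalent leverage identity (held-out residual = fit
  residual / (1 − leverage)) is used only as an independent oracle in the
  test suite, never as the implementation. For this model class the LOO
  error can never fall below the fit error.
- **external** — predictions on a set never used in training, from an
  already-fitted model or from an ingested third-party prediction table
  matched by PDB code (never refit). The optional `minLength` filter
  emulates prediction servers that only accept chains of at least, say,
  50 residues; the retained $n$ is reported.

An undefined Pearson correlation (constant vector, or fewer than two
points) is reported as `NA` with a classed warning — never coerced to
zero, which would silently corrupt comparisons. Display methods round to
2 decimals (3 for correlations), matching the conventions of published
comparison tables; `as.data.frame()` and JSON output keep full precision.

## Discrepancy analysis

`compareDatasets(A, B)` pairs two datasets over their distinct shared PDB
codes — one pair per code, first occurrence on each side, so duplicates
are not double-counted — and summarises sequence and rate disagreement.
Sequence identity is exact string equality after upper-casing; two rates
are non-identical when they differ by at least `rateTol` (default 0.01,
the precision of published tables). The comparison `|Δ| ≥ rateTol` is
applied with a 1e-9 absolute guard so that decimal inputs sitting exactly
at the threshold are classified by their printed value rather than by
their binary representation. Values are otherwise used as read, with no
re-rounding. `listDiscrepantPairs()` exposes the full pair list rather
than summarising it away, sorted by rate gap.

## The synthetic-data generator

`simulateDataset()` emulates the statistical regime of the real
compilations so that every stage is testable without any download:

- integer lengths drawn **log-uniformly** over 40–400 residues, so
  $\ln L$ has near-uniform leverage in the regression design (a uniform
  draw would concentrate leverage at the short end); the range brackets
  the ~50–150-residue bulk of real sets with margin;
- $\ln(k_f) = a_0 + a_1\ln L + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$, with defaults $a_0 = 30.4$,
  $a_1 = -6$, $\sigma = 2.6$ — the intercept, slope and residual-scatter
  regime of published chain-length fits. The residual distribution of
  real data about the length trend is not characterised anywhere we know
  of; Gaussian is an assumption, stated here;
- i.i.d. uniform sequences over the 20 standard residues — the analysis
  only ever reads length, so sequence composition realism is unnecessary;
- unique synthetic 4-character PDB-style identifiers, and the full ground
  truth (parameters and realised residuals) returned alongside for
  oracle tests.

`simulateVariant()` produces the paired-compilation scenario: same codes,
a random subset of sequences edited by up to `maxLenDelta` residues, and
rate shifts with **exponential magnitude** (mean 0.5 by default) and
random sign — a heavy-tailed scatter around a small mean, the shape seen
when real compilations are compared, without inventing a fitted
distribution. `simulateOverfitPredictor()` constructs a predictor that is
accurate on its training codes and noisy-plus-biased elsewhere, the
qualitative phenomenon (external RMSE several times the training RMSE)
that motivates external validation in the first place.

What passing tests on this generator do **not** show: that real
compilations have Gaussian residuals, independent errors, or
length-independent scatter; nor anything about sequence-composition or
structural-class effects, which the baseline deliberately ignores.

## Theory mapping

Exponentiating the baseline gives $k_f = c_0 L^{a_1}$ with
$c_0 = e^{a_0}$ s$^{-1}$, comparable to transition-state-theory folding
times $t = \tau\exp(\Delta G^{\#}/RT)$ ($R$ = 8.314 J mol$^{-1}$
K$^{-1}$; $\tau$ ~ 1–10 ns) and to the scaling law
$t \sim \tau_s L^{N}$ with $N$ the number of secondary-structure elements
to position, estimated as $L^{2/3}/3$ (≈ 7.2 at $L = 100$) or $L/15$
(≈ 6.7). `theoryConsistency()` collects, over a set of models, the
per-model $(-a_1, c_0)$, the mean intercept, the pre-exponential factor
implied by that mean, and the 1-decimal min/max of $-a_1$. The factor
reported for a set of models is $\exp(\overline{a_0})$ (the geometric
mean of the $c_0$), because intercepts — not rates — are what the models
average over; reports quote it at 2 significant figures and judge
agreement with the ~10$^{13}$ s$^{-1}$ per-residue attempt frequency at
order-of-magnitude level, since one rounding step in $a_0$ moves $c_0$
by more than its printed last digit.

## Numerical choices and degenerate inputs

- Coefficients come from centered moments, not matrix inversion; a
  normal-equations solver and `lm()` are the test oracles.
- Fewer than 3 records, or all lengths equal, is a hard error (the design
  is degenerate); LOO additionally requires $n \ge 4$ and a nondegenerate
  design after every removal, and names the offending record.
- PDB codes are matched case-insensitively and stored upper-cased; the
  whole token (including any chain suffix) is the key — no fuzzy or
  similarity matching.
- When a length column conflicts with the sequence, the sequence wins,
  with a warning: published tables themselves disagree internally, and
  one rule has to be fixed.
- Nonstandard residue codes (B, Z, X, U, O) are rejected by default; a
  `permissive` flag accepts them as length-contributing unknowns.
- Empty overlaps/differences warn and return `NULL` rather than an
  invalid zero-record object; `runBenchmark()` treats them as absent
  subsets and carries on, so one failing predictor or empty subset never
  aborts a whole comparison.

## Problem sizes

The test suite and examples run on simulated datasets of 10–110 proteins
with 500-replicate parameter-recovery and 100-replicate overfitting
studies — the same order as the real compilations, where a full benchmark
(four subsets, two baselines with LOO, several prediction tables) takes
well under a second.

## Known limitations

- Only strict PDB-code matching; no sequence-similarity analysis between
  datasets.
- The baseline is a single global model: no structural-class or
  kinetic-class submodels, and no multivariate descriptors — by design,
  since the point of the baseline is interpretability and stability.
- The applicability domain is length-range only.
- `renderReport()`'s markdown/TSV output is display-grade; downstream
  computation should use the JSON or the in-memory table.
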