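---
title: "Marker-coding translations in penalized epistatic regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-coding translations in penalized epistatic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiridge)
```

## The models

Let $M$ be the $n \times p$ matrix of allele dosages and $y$ the phenotype
vector.  `epifit()` fits polynomial regressions of total degree 1 or 2:

* **Additive** (degree 1): $y_i = \mu + M_{i\cdot}\beta + \varepsilon_i$.
* **First-order epistasis** (degree 2):
  $y_i = \mu + M_{i\cdot}\beta + \sum_{j<k} h_{jk} M_{ij} M_{ik} +
  \varepsilon_i$, optionally extended by squares $M_{ij}^2$ as a dominance
  device.

Three estimation principles share one design matrix $X$ (intercept column,
dosage columns, rowwise products):

* **OLS**: $\hat b = (X'X)^{-1}X'y$, defined only when the number of
  coefficients does not exceed $n$ and the normal equations are well
  conditioned.
* **Generalized ridge**: $\hat b = (X'X + D)^{-1}X'y$ with
  $D = \mathrm{diag}(\lambda_c)$.  The mixed-model interpretation sets
  $\lambda_c = 0$ for the intercept, $\lambda_1 =
  \sigma^2_\varepsilon/\sigma^2_\beta$ for additive terms and $\lambda_2 =
  \sigma^2_\varepsilon/\sigma^2_h$ for interactions.  The named variants
  are RRBLUP (degree 1), eRRBLUP-1 (both degrees penalized) and eRRBLUP-2
  ($\lambda_1 = 0$: additive effects fixed, only interactions penalized).
* **LASSO**: minimizes $\mathrm{SSR} + \sum_c \lambda_c |b_c|$ by cyclic
  coordinate descent with soft-thresholding.

Unpenalized coefficients are carried as zeros on the penalty diagonal
inside the same linear system, not absorbed out, so eRRBLUP-2 is literally
the "fixed additive effects" model.

## Translations and why completeness matters

A coding translation replaces $M$ by $\tilde M = M - 1_n P'$.  Define
$\tilde f(\tilde m) := f(\tilde m + P)$; then $\tilde f$ on the translated
data takes exactly the values of $f$ on the original data, so both have
the same residuals, and expanding the substitution shows that coefficients
of maximal total degree are unchanged while lower-degree coefficients
absorb the shift.  `translate_poly()` implements this expansion exactly
(binomially, for any total degree, although the solvers stop at 2).

The absorption needs a slot for every generated lower-order monomial: the
monomial set must be *complete* (every componentwise-smaller exponent
vector of an included monomial is included).  `is_complete()` tests this;
`translate_poly()` refuses incomplete sets.  Fitting the incomplete model
$\{1, M_1, M_1M_2\}$ on the packaged toy data shows the consequence: OLS
interaction estimates of $-0.012$ (raw coding) versus $-1.162$ (centered
coding).

Consequences, each of which is enforced by a property-style test in the
package:

* complete OLS: top-degree estimates and all predictions are
  translation-invariant;
* penalizing **only** the top degree (any penalty type): top-degree
  estimates and predictions invariant — this covers RRBLUP, the additive
  LASSO with free intercept, and eRRBLUP-2;
* penalizing lower degrees as well (eRRBLUP-1, extended LASSO, penalized
  intercept, missing intercept): invariance fails on generic data.

## Kernels and variance components

The additive kernel is $G = MM'$; the epistatic kernel is
$H = \tfrac12 (MM' \circ MM') - \tfrac12 (M \circ M)(M \circ M)'$, whose
$(i,i')$ entry equals $\sum_{j<k} M_{ij}M_{ik}M_{i'j}M_{i'k}$ — the
covariance induced by i.i.d. pairwise interaction effects.  Both kernels
depend on the coding; that dependence is the kernel-level face of the
coding problem.

`reml()` estimates one variance per kernel plus a residual by
average-information REML.  Numerical choices: AI steps with step-halving
at the nonnegativity boundary and an EM fallback when the AI system is
ill-conditioned; components that settle at the zero boundary with an
inward gradient are pinned to avoid oscillation; convergence when the
relative change of the restricted log-likelihood (or of all components)
drops below `tol = 1e-8`, within `max_iter = 200`; standard errors from
the inverse AI matrix.  Nearly proportional kernels (including a kernel
close to the identity, which duplicates the residual) raise an
identifiability warning but estimates are still returned.

**Normalization matters for the penalty factors.**  Dividing $H$ by its
maximum entry (the default, and the convention used for the
residual-variance comparison) rescales $\sigma^2_h$ and hence $\lambda_2$
by the same factor.  The experiment harness therefore estimates variance
components on *unnormalized* kernels when it converts them to penalty
factors, so that kernel-scale variances coincide with per-effect variances
and $\lambda = \sigma^2_\varepsilon / \sigma^2_{\text{component}}$ holds
without a conversion factor.

## The experiment harness

`coding_comparison()` follows a deliberate protocol: variance components
are estimated **once**, on the column-mean-centered coding, and the
resulting $\lambda_1, \lambda_2$ are frozen across codings.  This isolates
the direct effect of the coding from the indirect effect of re-estimated
penalty factors (an invariance statement only holds at fixed penalties).
A flag-free alternative is to pass `lambda` explicitly.  Markers (and
optionally lines) are drawn uniformly without replacement; each repetition
derives its RNG stream from `(seed, repetition)`, so any repetition can be
re-run in isolation and the whole experiment is reproducible bit for bit.
Monomorphic markers are not excluded from the draws; their count per
repetition is recorded in the result object instead.

Ranking of interaction estimates uses descending absolute value with ties
broken by original position (stable).  Aggregates are means with standard
errors over repetitions.  `out_of_sample_eval()` excludes (and counts)
repetitions with constant predictions or constant test phenotypes, where a
Pearson correlation is undefined.

## The simulator

`simulate_genotypes()` draws unlinked biallelic loci: per marker an allele
frequency uniform on `maf_range` (default 0.05–0.5), then
$\mathrm{Binomial}(\text{ploidy}, q_j)$ dosages per line, in the raw
0..ploidy coding.  Translations are applied downstream, never at
generation, because the coding must remain a free analysis choice.
`simulate_phenotypes()` draws $\beta_j \sim N(0, \sigma^2_\beta)$,
$h_{jk} \sim N(0, \sigma^2_h)$, $\varepsilon_i \sim
N(0, \sigma^2_\varepsilon)$ and stores the generating polynomial, so the
truth can be re-expressed in any coding via `translate_poly()` and
compared with estimates coefficient by coefficient.  Default variances
(0.5, 0.05, 0.25) give a heritable, mostly additive trait with a
detectable epistatic layer — a realistic regime for inbred-line panels.
The default `sparsity = 1` matches the i.i.d. normal prior of the ridge
variants; sparse settings exist for LASSO-style experiments.

What the simulator does **not** emulate: linkage disequilibrium and map
structure, population stratification and family relatedness,
multi-environment structure, and genotyping error.  Tests passing on this
generator therefore certify the algebra and the estimation machinery, not
robustness to confounding in real panels — the invariance statements,
however, are algebraic and hold for any data.

## Problem sizes and numerical choices

The test suite exercises: the 5×2 worked example for all printed-table
comparisons (2-decimal agreement, using absolute error < 0.005 since some
exact solutions lie on the rounding half-way point); invariance and
non-invariance properties over 20 random instances at $n = 14, p = 3$;
the experiment-scale invariance check at $n = 300$ lines, $p = 50$
markers, 1225 interactions, 10 repetitions; kernel identities on 50 random
small matrices; and two-kernel REML recovery at $n = 400$ over 50
replicates.  These sizes keep the full suite under a minute on a laptop
while leaving each statistical check comfortably powered.

Other numerical decisions: the ridge/OLS solver refuses systems with
reciprocal condition number below $10^{-12}$ rather than switching to a
pseudo-inverse; LASSO coordinate descent uses deterministic column order,
convergence when the largest coefficient change in a sweep is below `tol`
(default $10^{-8}$; invariance tests tighten this to $10^{-12}$ since the
comparison tolerance must exceed the solver tolerance), and at most
10,000 sweeps; kernel PSD checks accept eigenvalues down to $-10^{-8}$
times the largest.

## Open choices made here

* **Symmetric coding for non-binary dosages**: the ±0.5 convention is only
  defined for presence/absence data in the source tradition; we generalize
  to subtracting `max_dosage / 2`, which reproduces ±0.5 for 0/1 data and
  −1/0/1 for diploid counts.
* **Penalty group of squares $M_j^2$**: treated as degree-2 (factor
  $\lambda_2$) by default, configurable via `lambda_squares`; no standard
  convention exists.
* **VCF dosages**: count of the alternate allele (0/0, 0/1, 1/1 → 0, 1, 2),
  the usual dosage convention; multi-allelic sites are rejected rather than
  recoded.
* **Variance components for the fixed-additive protocol**: when additive
  effects are fixed, only $\sigma^2_\varepsilon$ and $\sigma^2_h$ are
  estimated (single epistatic kernel plus residual), mirroring the
  two-component setup of the frozen-penalty protocol.

## Limitations

Solvers are dense and direct: the full pairwise model with $q = 1 + p +
\binom{p}{2}$ coefficients is practical up to a few thousand coefficients,
which is why the experiment designs subsample markers (the subsampling is
also what makes the fixed-additive, translation-invariant regression
possible, since it needs fewer coefficients than observations for the
fixed block).  Three-way interactions are supported by the polynomial
machinery (`translate_poly()` is exact for any degree) but not by the
solvers.  REML is $O(n^3)$ per iteration and intended for $n$ up to a few
thousand.  No G×E structure, no multi-trait models, no marker scaling —
scaling (as opposed to translation) changes penalties per column and is a
separate problem deliberately left out.
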