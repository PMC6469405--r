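# epiridge

Penalized whole-genome regression with pairwise marker interactions, and
the tools to understand — and when possible eliminate — the dependence of
such models on the numeric coding of the markers.

## The problem

Genomic prediction regresses a phenotype on all markers at once.  The
additive workhorse is ridge-regression BLUP (RRBLUP/GBLUP),

    y_i = mu + sum_j beta_j M_ij + eps_i,

a mixed model that penalizes the additive effects `beta` (penalty factor
`lambda = sigma2_eps / sigma2_beta`) but not the intercept.  Adding all
pairwise products extends this to a first-order epistasis model
(eRRBLUP/eGBLUP),

    y_i = mu + sum_j beta_j M_ij + sum_{j<k} h_jk M_ij M_ik + eps_i,

with a second penalty factor `lambda2 = sigma2_eps / sigma2_h` on the
interaction effects `h`.

Marker dosages have no canonical origin: 0/1/2 allele counts, a symmetric
±0.5 coding and the column-mean-centered coding are all in routine use, and
they differ only by a *translation* — subtracting a constant vector `P`
from every row of the marker matrix.  Predictions and additive estimates of
RRBLUP are famously indifferent to this choice.  In a penalized model with
interactions they are not: translating the coding changes the interaction
estimates, their ranking, the variance the epistatic kernel explains, and
out-of-sample predictions.  The reason is a polynomial-algebra fact: a
translation can be absorbed into the coefficients of *lower* total degree
(the intercept absorbs pieces of the additive terms, the additive terms
absorb pieces of the interactions), and the coefficients of *highest* total
degree are unchanged.  A penalized fit is therefore translation-invariant
exactly when (a) the monomial set is *complete* — every componentwise-smaller
monomial of an included monomial is also in the model — and (b) only the
coefficients of highest total degree are penalized.  Penalize the additive
terms too (the usual eRRBLUP) and the invariance is gone.

`epiridge` implements the whole toolchain:

* **Marker data**: delimited or VCF input, coding translations
  (`translate_markers()`) with the applied shift recorded in the data and
  carried through to prediction time;
* **Polynomial machinery**: monomial enumeration, completeness checking
  (`is_complete()`), design matrices, and the exact coefficient transform
  under a coding translation (`translate_poly()`);
* **Solvers**: one fitting function `epifit()` for OLS, generalized ridge
  (RRBLUP, eRRBLUP-1, eRRBLUP-2) and an l1-penalized LASSO, with
  per-coefficient penalty factors and the classic S3 methods
  (`coef`, `predict`, `summary`, `residuals`, `plot`);
* **Kernels and variance components**: additive `MM'` and epistatic
  Hadamard-product relationship matrices
  (`H = 0.5 (MM' o MM') - 0.5 (MoM)(MoM)'`), and AI-REML with EM fallback
  (`reml()`) whose variance ratios give the penalty factors;
* **Experiments**: the coding-sensitivity study design — random marker
  subsets, frozen penalty factors, cross-coding correlations and rank
  changes of interaction estimates (`coding_comparison()`,
  `rank_change()`), residual variance per coding
  (`residual_variance_by_coding()`), out-of-sample prediction
  (`out_of_sample_eval()`);
* **Simulation**: biallelic genotypes and phenotypes from the generative
  epistatic model (`simulate_genotypes()`, `simulate_phenotypes()`), so
  every claim is testable without external data.

## A worked example

Five lines, two diploid markers, one interaction.  Fit the same model in
the raw 0/1/2 coding and in the column-mean-centered coding:

```r
library(epiridge)
M <- read_marker_matrix(system.file("extdata", "toy_markers.tsv",
                                    package = "epiridge"))
y <- read_phenotype(system.file("extdata", "toy_pheno.tsv",
                                package = "epiridge"))

# eRRBLUP-1: additive and interaction effects penalized
fit_nc <- epifit(M, y, degree = 2, lambda1 = 1, lambda2 = 1)
fit_c  <- epifit(M, y, degree = 2, lambda1 = 1, lambda2 = 1,
                 coding = "centered")
round(rbind(noncentered = coef(fit_nc), centered = coef(fit_c)), 2)
#>                1    M1   M2 M1*M2
#> noncentered 1.81 -0.89 0.71 -0.48
#> centered    0.33 -1.15 0.09 -0.57
```

Every coefficient — including the interaction — depends on the coding.
Now penalize *only* the interaction (`lambda1 = 0`, eRRBLUP-2):

```r
fix_nc <- epifit(M, y, degree = 2, lambda1 = 0, lambda2 = 1)
fix_c  <- epifit(M, y, degree = 2, lambda1 = 0, lambda2 = 1,
                 coding = "centered")
round(rbind(noncentered = coef(fix_nc), centered = coef(fix_c)), 2)
#>                1    M1   M2 M1*M2
#> noncentered 2.68 -1.54 1.03 -0.57
#> centered    0.33 -2.11 0.11 -0.57
```

The lower-degree coefficients adapt to the coding, but the interaction
estimate (−0.57) and all fitted/predicted phenotypes are identical under
both codings — the degree-selective penalty restores translation
invariance.

The coefficient transform itself is available directly.  Shifting the
coding of `f = 1 + 2 M1 + 0.5 M2 + 0.25 M1*M2` by `P = (0.5, 0.3)`:

```r
f  <- poly_model(enumerate_monomials(2, 2), c(1, 2, 0.5, 0.25))
ft <- translate_poly(f, c(0.5, 0.3))
coef(ft)
#>      1     M1     M2  M1*M2
#> 2.1875 2.0750 0.6250 0.2500
c(evaluate_poly(f, c(2, 2)), evaluate_poly(ft, c(1.5, 1.7)))
#> [1] 7 7
```

The top-degree coefficient is untouched and the two polynomials take the
same value at corresponding points.

## Command line

A thin front end over the same functions lives in
`inst/scripts/epiridge.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/epiridge.R", package="epiridge"))') \
    simulate --n-lines 300 --n-markers 50 --seed 1 --out-prefix sim
# ... fit --markers sim_markers.tsv --pheno sim_pheno.tsv --coding centered \
#         --lambda1 0 --lambda2 1 --out effects.tsv
# ... varcomp --markers sim_markers.tsv --pheno sim_pheno.tsv --kernels both
```

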