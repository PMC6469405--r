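# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Simulate biallelic marker genotypes
#'
#' Draws, for each marker j, an allele frequency `q_j` uniformly from
#' `maf_range`, then line dosages `Binomial(ploidy, q_j)` independently
#' across lines -- unlinked biallelic loci in the raw 0..ploidy coding
#' (presence/absence for `ploidy = 1`, diploid counts for `ploidy = 2`).
#' Translations of the coding are deliberately left to downstream code.
#'
#' @param n_lines number of lines (individuals).
#' @param n_markers number of markers.
#' @param maf_range interval in (0, 0.5] for the minor-allele frequency
#'   (a scalar fixes the frequency).
#' @param ploidy 1 or 2.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return A `marker_matrix` with `shift = 0`.
#' @export
simulate_genotypes <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                               ploidy = 1L, seed = NULL) {
  if (length(maf_range) == 1L) maf_range <- rep(maf_range, 2)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  with_seed(seed, {
    q <- stats::runif(n_markers, maf_range[1], maf_range[2])
    values <- vapply(seq_len(n_markers),
                     function(j) stats::rbinom(n_lines, ploidy, q[j]),
                     numeric(n_lines))
    marker_matrix(matrix(values, nrow = n_lines))
  })
}

#' Simulate phenotypes from an epistatic polynomial model
#'
#' Generates `y = mu + M beta + sum_{j<k} h_jk M_j M_k + eps` with
#' `beta_j ~ N(0, sigma2_beta)`, `h_jk ~ N(0, sigma2_h)` and
#' `eps_i ~ N(0, sigma2_eps)`, all i.i.d.  `sparsity` keeps a random
#' fraction of the additive and interaction effects nonzero (1 = dense,
#' matching the i.i.d. normal prior; sparse settings are for LASSO-style
#' tests).  Effects are drawn in the matrix's current coding; the generating
#' model is returned so it can be re-expressed in any translated coding via
#' [translate_poly()].
#'
#' @param M a `marker_matrix` or numeric dosage matrix.
#' @param mu intercept.
#' @param sigma2_beta,sigma2_h,sigma2_eps variances of additive effects,
#'   interaction effects, and residual noise (any may be 0).
#' @param sparsity fraction of effects that are nonzero, in (0, 1].
#' @param seed optional integer seed.
#' @return List of class `sim_dataset`: `markers`, `phenotype` (named
#'   vector), `true_model` (a `poly_model`), `noise`, and `varcomps` (the
#'   generating variances).
#' @export
simulate_phenotypes <- function(M, mu = 0, sigma2_beta = 0.5,
                                sigma2_h = 0.05, sigma2_eps = 0.25,
                                sparsity = 1, seed = NULL) {
  M <- as_marker_matrix(M)
  if (sigma2_beta < 0 || sigma2_h < 0 || sigma2_eps < 0)
    stop("variances must be nonnegative")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  n <- nrow(M$values); p <- ncol(M$values)
  monomials <- enumerate_monomials(p, 2L)
  deg <- vapply(monomials, monomial_degree, integer(1))
  with_seed(seed, {
    coefs <- numeric(length(monomials))
    coefs[deg == 0L] <- mu
    coefs[deg == 1L] <- stats::rnorm(sum(deg == 1L), 0, sqrt(sigma2_beta))
    coefs[deg == 2L] <- stats::rnorm(sum(deg == 2L), 0, sqrt(sigma2_h))
    if (sparsity < 1) {
      for (d in 1:2) {
        idx <- which(deg == d)
        nzero <- round((1 - sparsity) * length(idx))
        if (nzero > 0) coefs[sample(idx, nzero)] <- 0
      }
    }
    truth <- poly_model(monomials, coefs, p = p)
    noise <- stats::rnorm(n, 0, sqrt(sigma2_eps))
    y <- evaluate_poly(truth, M) + noise
    structure(list(markers = M,
                   phenotype = stats::setNames(y, rownames(M$values)),
                   true_model = truth,
                   noise = noise,
                   varcomps = c(sigma2_beta = sigma2_beta,
                                sigma2_h = sigma2_h,
                                sigma2_eps = sigma2_eps)),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d lines x %d markers; var components (beta, h, eps) = %s\n",
    nrow(x$markers$values), ncol(x$markers$values),
    paste(signif(x$varcomps, 3), collapse = ", ")))
  invisible(x)
}
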