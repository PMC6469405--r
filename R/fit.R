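#' Per-coefficient penalty factors for an epistatic model
#'
#' Builds the diagonal penalty vector of the generalized ridge system from
#' the two variance-ratio penalty factors of the mixed-model formulation:
#' `lambda1 = sigma2_eps / sigma2_beta` on additive (degree-1) terms and
#' `lambda2 = sigma2_eps / sigma2_h` on interaction (degree-2) terms.  The
#' intercept is never penalized; a factor of 0 leaves a term unpenalized
#' (fixed).  Squares `Mj^2`, if present, take `lambda_squares` (default:
#' the interaction factor).
#'
#' @param monomials list of monomials (the model's columns, in order).
#' @param lambda1 penalty factor for degree-1 monomials.
#' @param lambda2 penalty factor for degree-2 pair monomials.
#' @param lambda_squares penalty factor for square monomials `Mj^2`.
#' @return Named nonnegative numeric vector, one entry per monomial.
#' @export
penalty_spec <- function(monomials, lambda1 = 0, lambda2 = 0,
                         lambda_squares = lambda2) {
  if (lambda1 < 0 || lambda2 < 0 || lambda_squares < 0)
    stop("penalty factors must be nonnegative")
  deg <- vapply(monomials, monomial_degree, integer(1))
  if (any(deg > 2L))
    stop("penalty_spec handles total degree <= 2 only")
  is_square <- vapply(monomials, function(m)
    length(unclass(m)) == 1L && unclass(m)[[1]] == 2L, logical(1))
  lam <- numeric(length(monomials))
  lam[deg == 1L] <- lambda1
  lam[deg == 2L & !is_square] <- lambda2
  lam[is_square] <- lambda_squares
  stats::setNames(lam, vapply(monomials, monomial_key, character(1)))
}

# Generalized ridge solve: b = (X'X + diag(d))^-1 X'y, with a reciprocal
# condition number guard instead of a silent pseudo-inverse.
.solve_penalized <- function(X, y, d, rcond_tol = 1e-12) {
  C <- crossprod(X) + diag(d, ncol(X))
  rc <- rcond(C)
  if (!is.finite(rc) || rc < rcond_tol)
    stop(sprintf(
      "penalized normal equations are singular or ill-conditioned (rcond = %.3g)",
      rc))
  drop(solve(C, crossprod(X, y)))
}

# Cyclic coordinate descent for SSR + sum lambda_c |b_c|; deterministic
# column order, soft-thresholding updates.
.solve_lasso <- function(X, y, lam, tol = 1e-8, max_iter = 10000L) {
  q <- ncol(X)
  xtx <- colSums(X^2)
  if (any(xtx == 0 & lam == 0))
    stop("zero column with zero penalty: coefficient not identifiable")
  b <- numeric(q)
  r <- y  # residual y - Xb
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(q)) {
      if (xtx[j] == 0) next
      z <- sum(X[, j] * r) + xtx[j] * b[j]
      bj <- if (lam[j] > 0) soft(z, lam[j] / 2) / xtx[j] else z / xtx[j]
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (delta < tol)
      return(list(coefficients = b, iterations = it, converged = TRUE))
  }
  stop("coordinate descent did not converge within ", max_iter,
       " sweeps (last max change ", signif(delta, 3), ")")
}

#' Fit a penalized polynomial whole-genome regression
#'
#' The workhorse of the package: fits an additive (`degree = 1`) or
#' first-order epistatic (`degree = 2`) regression of a phenotype on marker
#' dosages, by ordinary least squares, generalized ridge (the mixed-model
#' RRBLUP / eRRBLUP solutions), or an l1-penalized LASSO.
#'
#' The ridge solution is `(X'X + D)^-1 X'y` with `D` the diagonal of
#' per-coefficient penalty factors: the intercept is never penalized,
#' additive effects carry `lambda1` and interactions `lambda2`.  The
#' classical variants are
#' \describe{
#'   \item{RRBLUP}{`degree = 1`, `lambda1 > 0`.}
#'   \item{eRRBLUP-1}{`degree = 2`, `lambda1 > 0`, `lambda2 > 0` (penalizes
#'     additive and interaction effects; coding-sensitive).}
#'   \item{eRRBLUP-2}{`degree = 2`, `lambda1 = 0`, `lambda2 > 0` (additive
#'     effects fixed, only interactions penalized; interaction estimates and
#'     predictions are invariant to translations of the marker coding).}
#' }
#'
#' `coding` translates the markers before fitting; the total shift relative
#' to the raw coding is recorded in the fit and re-applied by
#' [predict.epifit()], so new data is always expressed in the training
#' coding.
#'
#' @param markers a `marker_matrix` or numeric dosage matrix.
#' @param y numeric phenotype vector (named vectors are aligned by line ID).
#' @param degree total degree of the polynomial model, 1 or 2.
#' @param method `"ridge"`, `"ols"` or `"lasso"`.
#' @param lambda1,lambda2 penalty factors for additive and interaction
#'   effects (ridge: quadratic penalty weights; lasso: l1 weights).
#' @param lambda_squares penalty factor for `Mj^2` terms when
#'   `squares = TRUE`.
#' @param squares include dominance terms `Mj^2`.
#' @param pairs optional 2-column matrix restricting the interaction pairs.
#' @param monomials optional explicit monomial list, overriding
#'   `degree`/`squares`/`pairs` (allows deliberately incomplete models).
#' @param penalty optional explicit per-coefficient penalty vector,
#'   overriding the `lambda*` arguments (allows e.g. a penalized intercept).
#' @param coding translation applied before fitting: `"asis"` (keep the
#'   matrix's current coding), `"centered"` (subtract column means),
#'   `"symmetric"` (subtract `max_dosage / 2`), or `"shift"` (subtract the
#'   vector `shift`).
#' @param shift translation vector for `coding = "shift"`.
#' @param max_dosage maximum raw dosage, required for
#'   `coding = "symmetric"`.
#' @param tol,max_iter convergence control for `method = "lasso"`.
#' @return An object of class `epifit`: a list with the fitted `poly_model`
#'   (`$model`), `$fitted`, `$residuals`, `$ssr`, the `$penalty` vector, the
#'   training coding `$shift`, and `$method`.  Supports `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `predict` and `plot`.
#' @examples
#' M <- marker_matrix(matrix(c(2, 2, 1, 2, 2, 0, 2, 1, 1, 0),
#'   ncol = 2, byrow = TRUE))
#' y <- c(-0.72, 2.34, 0.08, -0.89, 0.86)
#' # eRRBLUP-2: additive effects fixed, interaction penalized
#' fit <- epifit(M, y, degree = 2, lambda1 = 0, lambda2 = 1)
#' coef(fit)
#' interaction_effects(fit)
#' @export
epifit <- function(markers, y, degree = 2L,
                   method = c("ridge", "ols", "lasso"),
                   lambda1 = 0, lambda2 = 1, lambda_squares = lambda2,
                   squares = FALSE, pairs = NULL, monomials = NULL,
                   penalty = NULL,
                   coding = c("asis", "centered", "symmetric", "shift"),
                   shift = NULL, max_dosage = NULL,
                   tol = 1e-8, max_iter = 10000L) {
  method <- match.arg(method)
  coding <- match.arg(coding)
  M <- as_marker_matrix(markers)
  y <- align_phenotype(M, y)
  M <- switch(coding,
    asis = M,
    centered = translate_markers(M, "column_mean"),
    symmetric = translate_markers(M, "symmetric", max_dosage = max_dosage),
    shift = translate_markers(M, "constant", P = shift))
  if (is.null(monomials))
    monomials <- enumerate_monomials(ncol(M$values), degree,
                                     include_squares = squares,
                                     selected_pairs = pairs)
  X <- build_design(M, monomials)
  if (is.null(penalty)) {
    penalty <- if (method == "ols")
      penalty_spec(monomials, 0, 0, 0)
    else
      penalty_spec(monomials, lambda1, lambda2, lambda_squares)
  }
  if (length(penalty) != ncol(X))
    stop("penalty length does not match the number of model terms")
  if (any(penalty < 0)) stop("penalty factors must be nonnegative")

  iterations <- NA_integer_
  b <- switch(method,
    ols = {
      if (ncol(X) > nrow(X))
        stop("OLS requires at least as many observations as coefficients")
      .solve_penalized(X, y, rep(0, ncol(X)))
    },
    ridge = .solve_penalized(X, y, penalty),
    lasso = {
      res <- .solve_lasso(X, y, penalty, tol = tol, max_iter = max_iter)
      iterations <- res$iterations
      res$coefficients
    })
  fitted <- drop(X %*% b)
  structure(list(model = poly_model(monomials, b, p = ncol(M$values)),
                 fitted = stats::setNames(fitted, rownames(X)),
                 residuals = stats::setNames(y - fitted, rownames(X)),
                 ssr = sum((y - fitted)^2),
                 y = y,
                 penalty = stats::setNames(penalty, colnames(X)),
                 shift = M$shift,
                 method = method,
                 iterations = iterations,
                 call = match.call()),
            class = "epifit")
}

#' @export
print.epifit <- function(x, digits = 4, ...) {
  deg <- vapply(x$model$monomials, monomial_degree, integer(1))
  cat(sprintf(
    "epifit (%s): %d lines, %d loci, %d terms (degree-1: %d, degree-2: %d)\n",
    x$method, length(x$fitted), x$model$p, length(deg),
    sum(deg == 1L), sum(deg == 2L)))
  cat("SSR:", signif(x$ssr, digits), "\n")
  if (any(x$shift != 0))
    cat("training coding shift (first entries):",
        paste(signif(utils::head(x$shift, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.epifit <- function(object, ...) {
  deg <- vapply(object$model$monomials, monomial_degree, integer(1))
  eff <- as.data.frame(object$model)
  eff$penalty <- as.numeric(object$penalty)
  structure(list(fit = object, effects = eff,
                 n = length(object$fitted), ssr = object$ssr,
                 by_degree = tapply(abs(eff$coefficient), eff$degree,
                                    function(z) c(mean = mean(z),
                                                  max = max(z)))),
            class = "summary.epifit")
}

#' @export
print.summary.epifit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nEffect size summary (mean / max |coefficient| by total degree):\n")
  for (d in names(x$by_degree))
    cat(sprintf("  degree %s: mean %.4g, max %.4g\n", d,
                x$by_degree[[d]]["mean"], x$by_degree[[d]]["max"]))
  cat("\nLargest effects:\n")
  eff <- x$effects[order(-abs(x$effects$coefficient)), ]
  print(utils::head(eff, 8), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.epifit <- function(object, ...) coef(object$model)

#' @export
fitted.epifit <- function(object, ...) object$fitted

#' @export
residuals.epifit <- function(object, ...) object$residuals

#' Extract effects of a given total degree from a fit
#'
#' @param fit an `epifit`.
#' @param degree total degree to extract (2 = pairwise interactions).
#' @return Named numeric vector of coefficients.
#' @export
interaction_effects <- function(fit, degree = 2L) {
  deg <- vapply(fit$model$monomials, monomial_degree, integer(1))
  coef(fit$model)[deg == degree]
}

#' Predict phenotypes for new lines
#'
#' New marker data is translated into the training coding first: the fit
#' stores the total shift of the coding it was trained in, and any shift
#' already applied to `newdata` is accounted for.  This makes it impossible
#' to silently mix codings between training and prediction.
#'
#' @param object an `epifit`.
#' @param newdata a `marker_matrix` or numeric dosage matrix (raw coding
#'   unless it carries its own shift record).
#' @param ... unused.
#' @return Numeric vector of predicted phenotypes.
#' @export
predict.epifit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  M <- as_marker_matrix(newdata)
  if (length(M$shift) != length(object$shift))
    stop(sprintf("newdata has %d markers but the fit was trained on %d",
                 length(M$shift), length(object$shift)))
  extra <- object$shift - M$shift
  if (any(extra != 0))
    M <- translate_markers(M, "constant", P = extra)
  evaluate_poly(object$model, M)
}

#' @export
plot.epifit <- function(x, ...) {
  plot(x$fitted, x$y, xlab = "fitted", ylab = "observed",
       main = sprintf("epifit (%s)", x$method), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
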