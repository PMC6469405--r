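#' REML variance components for a multi-kernel mixed model
#'
#' Estimates one variance component per relationship kernel plus a residual
#' variance in the model `y = Xb + sum_k u_k + e`, with
#' `u_k ~ N(0, sigma2_k K_k)` and `e ~ N(0, sigma2_eps I)`, by restricted
#' maximum likelihood.  Updates use the average-information algorithm with
#' expectation-maximization fallback steps whenever an AI step proposes a
#' negative variance; variances are constrained to be nonnegative (boundary
#' estimates are clamped to a small floor relative to `var(y)`).  Standard
#' errors come from the inverse average-information matrix at convergence.
#'
#' Ratios of the resulting components give the penalty factors of the
#' corresponding generalized ridge regression; see
#' [penalty_from_varcomp()].
#'
#' @param y numeric phenotype vector.
#' @param kernels named list of n x n symmetric positive semidefinite
#'   relationship matrices (e.g. from [additive_kernel()] and
#'   [epistatic_kernel()]).  May be empty for a residual-only model.
#' @param X fixed-effect design matrix (default: intercept only).
#' @param init optional named initial values for the variance components.
#' @param tol convergence tolerance on the relative change of the
#'   restricted log-likelihood.
#' @param max_iter maximum number of iterations.
#' @param verbose print the likelihood trajectory.
#' @return Object of class `varcomp`: list with `sigma2` (named vector,
#'   kernels then `"residual"`), `se`, `converged`, `iterations`, `loglik`,
#'   and `identifiability_warning` (TRUE when two kernels, or a kernel and
#'   the residual identity, are nearly proportional so their components are
#'   not separable).
#' @export
reml <- function(y, kernels = list(), X = NULL, init = NULL,
                 tol = 1e-8, max_iter = 200L, verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X must have one row per observation")
  r <- qr(X)$rank
  if (n <= ncol(X))
    stop("need more observations than fixed-effect columns")
  m <- length(kernels)
  if (m > 0 && is.null(names(kernels)))
    names(kernels) <- paste0("K", seq_len(m))
  for (k in seq_len(m)) {
    K <- kernels[[k]]
    if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8)))
      stop("kernel '", names(kernels)[k], "' is not symmetric")
    if (nrow(K) != n) stop("kernel dimension does not match length(y)")
  }
  comp_names <- c(names(kernels), "residual")

  # near-proportional kernels (or kernel vs identity) are not separable
  ident_warn <- FALSE
  mats <- c(lapply(kernels, function(K) unclass(as.matrix(K))),
            list(diag(n)))
  if (length(mats) > 1) {
    vecs <- vapply(mats, as.numeric, numeric(n * n))
    cc <- suppressWarnings(stats::cor(vecs))
    cc[!is.finite(cc)] <- 1  # a constant (e.g. zero) kernel is degenerate
    diag(cc) <- 0
    if (any(abs(cc) > 0.999)) {
      ident_warn <- TRUE
      warning("two variance structures are nearly proportional; ",
              "their components are not separately identifiable")
    }
  }

  vy <- stats::var(y)
  if (!is.finite(vy) || vy < .Machine$double.eps) {
    # degenerate input: no variance left for any component
    sig <- stats::setNames(rep(0, m + 1L), comp_names)
    return(structure(list(sigma2 = sig,
                          se = stats::setNames(rep(NA_real_, m + 1L),
                                               comp_names),
                          converged = TRUE, iterations = 0L,
                          loglik = NA_real_,
                          identifiability_warning = ident_warn),
                     class = "varcomp"))
  }

  if (m == 0L) {  # residual-only model: closed form
    qrX <- qr(X)
    res <- qr.resid(qrX, y)
    s2 <- sum(res^2) / (n - r)
    ll <- -0.5 * ((n - r) * log(s2) + (n - r) +
                    determinant(crossprod(X), logarithm = TRUE)$modulus)
    return(structure(list(
      sigma2 = stats::setNames(s2, "residual"),
      se = stats::setNames(sqrt(2 * s2^2 / (n - r)), "residual"),
      converged = TRUE, iterations = 0L, loglik = as.numeric(ll),
      identifiability_warning = ident_warn), class = "varcomp"))
  }

  scale_k <- vapply(kernels, function(K) mean(diag(as.matrix(K))),
                    numeric(1))
  scale_k[scale_k <= 0] <- 1
  theta <- if (!is.null(init)) {
    as.numeric(init[comp_names])
  } else {
    c(vy / ((m + 1) * scale_k), vy / (m + 1))
  }
  floor_v <- 1e-8 * vy
  theta <- pmax(theta, floor_v)

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(max_iter)) {
    V <- diag(theta[m + 1L], n)
    for (k in seq_len(m)) V <- V + theta[k] * as.matrix(kernels[[k]])
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch))
      stop("covariance matrix not positive definite at iteration ", it)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    XtViX_i <- solve(XtViX)
    ViX <- Vi %*% X
    P <- Vi - ViX %*% XtViX_i %*% t(ViX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(XtViX, logarithm = TRUE)$modulus +
                    sum(y * Py))
    ll <- as.numeric(ll)
    loglik_trace <- c(loglik_trace, ll)
    if (verbose)
      cat(sprintf("iter %d: loglik %.6f, sigma2 = %s\n", it, ll,
                  paste(signif(theta, 4), collapse = ", ")))
    # score and average information
    Kmats <- c(lapply(kernels, as.matrix), list(diag(n)))
    v <- lapply(Kmats, function(K) drop(K %*% Py))   # K_i P y
    w <- lapply(v, function(vi) drop(P %*% vi))       # P K_i P y
    score <- numeric(m + 1L)
    for (i in seq_len(m + 1L))
      score[i] <- -0.5 * (sum(P * Kmats[[i]]) - sum(Py * v[[i]]))
    AI <- matrix(0, m + 1L, m + 1L)
    for (i in seq_len(m + 1L))
      for (j in i:(m + 1L))
        AI[i, j] <- AI[j, i] <- 0.5 * sum(v[[i]] * w[[j]])

    if (it > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    # components pinned at the zero boundary with an inward-pointing
    # gradient stay there; updating them would only oscillate
    pinned <- theta <= floor_v * 1.0001 & score < 0
    free <- which(!pinned)
    theta_new <- theta
    step_ok <- FALSE
    if (length(free) > 0L) {
      AIf <- AI[free, free, drop = FALSE]
      if (rcond(AIf) > 1e-12) {
        delta <- solve(AIf, score[free])
        if (all(is.finite(delta))) {
          # shorten the AI step if it overshoots the nonnegativity
          # boundary, then clamp; the pinning rule above retires
          # components that settle at zero
          gamma <- 1
          while (gamma > 1 / 32 &&
                 any(theta[free] + gamma * delta < -floor_v))
            gamma <- gamma / 2
          theta_new[free] <- pmax(theta[free] + gamma * delta, floor_v)
          step_ok <- TRUE
        }
      }
      if (!step_ok) {
        # EM fallback: guaranteed-direction update, always nonnegative
        for (i in free) {
          theta_new[i] <- theta[i] +
            theta[i]^2 * (sum(Py * v[[i]]) - sum(P * Kmats[[i]])) / n
        }
        theta_new <- pmax(theta_new, floor_v)
      }
    }
    if (max(abs(theta_new - theta) / (abs(theta) + floor_v)) < tol) {
      converged <- TRUE
      theta <- theta_new
      break
    }
    theta <- theta_new
  }
  if (!converged && max_iter > 0L)
    warning("REML did not converge in ", max_iter, " iterations ",
            "(relative log-likelihood change above tolerance)")
  se <- rep(NA_real_, m + 1L)
  if (!is.null(AI) && rcond(AI) > 1e-12)
    se <- sqrt(pmax(diag(solve(AI)), 0))
  theta[theta <= floor_v * 1.0001] <- 0  # boundary estimates report as zero
  structure(list(sigma2 = stats::setNames(theta, comp_names),
                 se = stats::setNames(se, comp_names),
                 converged = converged,
                 iterations = length(loglik_trace),
                 loglik = if (length(loglik_trace))
                   loglik_trace[length(loglik_trace)] else NA_real_,
                 loglik_trace = loglik_trace,
                 identifiability_warning = ident_warn),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, digits = 4, ...) {
  cat("REML variance components",
      if (isTRUE(x$converged)) "(converged" else "(NOT converged",
      sprintf("in %d iterations)\n", x$iterations))
  df <- data.frame(component = names(x$sigma2),
                   estimate = as.numeric(x$sigma2),
                   se = as.numeric(x$se))
  print(df, digits = digits, row.names = FALSE)
  if (isTRUE(x$identifiability_warning))
    cat("warning: nearly proportional variance structures\n")
  invisible(x)
}

#' Penalty factors from REML variance components
#'
#' The generalized ridge penalty factor of a random-effect block is the
#' ratio of the residual variance to the block's variance component:
#' `lambda_k = sigma2_eps / sigma2_k`.
#'
#' @param vc a `varcomp` object from [reml()].
#' @param components which kernel components to form ratios for (default:
#'   all non-residual components, in order).
#' @return Named numeric vector of penalty factors.
#' @export
penalty_from_varcomp <- function(vc, components = NULL) {
  sig <- vc$sigma2
  if (!"residual" %in% names(sig)) stop("varcomp lacks a residual component")
  if (is.null(components))
    components <- setdiff(names(sig), "residual")
  miss <- setdiff(components, names(sig))
  if (length(miss))
    stop("unknown component(s): ", paste(miss, collapse = ", "))
  bad <- components[sig[components] <= 0]
  if (length(bad))
    stop("component variance is zero for ", paste(bad, collapse = ", "),
         "; the penalty factor is infinite -- drop the term instead")
  stats::setNames(sig[["residual"]] / as.numeric(sig[components]),
                  components)
}
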