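#' Monomials in the marker variables
#'
#' A monomial is a product of powers of marker dosages, represented as a
#' named integer vector: names are locus indices, values are positive powers.
#' The empty vector is the intercept monomial (total degree 0).  `monomial()`
#' builds a canonical representation (loci sorted, zero powers dropped).
#'
#' @param loci integer vector of locus indices (may repeat: `c(1, 2)` is
#'   `M1*M2`, `c(3, 3)` is `M3^2`).  Alternatively a named integer vector of
#'   powers.
#' @return Canonical monomial (named integer vector of class `monomial`).
#' @examples
#' monomial(integer(0))   # intercept
#' monomial(c(1, 2))      # M1*M2
#' monomial(c(3, 3))      # M3^2
#' @export
monomial <- function(loci) {
  if (length(loci) == 0L)
    return(structure(integer(0), class = "monomial"))
  if (!is.null(names(loci))) {
    pow <- as.integer(loci)
    idx <- as.integer(names(loci))
  } else {
    tab <- table(as.integer(loci))
    idx <- as.integer(names(tab))
    pow <- as.integer(tab)
  }
  keep <- pow > 0L
  idx <- idx[keep]; pow <- pow[keep]
  if (any(pow < 0L)) stop("monomial powers must be nonnegative")
  o <- order(idx)
  structure(stats::setNames(pow[o], idx[o]), class = "monomial")
}

#' Total degree of a monomial
#' @param m a monomial.
#' @return Integer, the sum of the powers.
#' @export
monomial_degree <- function(m) sum(unclass(m))

# Canonical string key, e.g. "1", "M3", "M1*M2", "M3^2".
monomial_key <- function(m) {
  m <- unclass(m)
  if (length(m) == 0L) return("1")
  paste(ifelse(m == 1L, paste0("M", names(m)),
               paste0("M", names(m), "^", m)),
        collapse = "*")
}

# Parse "M1*M2", "M3^2", "1" back into a monomial.
parse_monomial <- function(s) {
  s <- trimws(s)
  if (s == "1" || s == "") return(monomial(integer(0)))
  parts <- strsplit(s, "*", fixed = TRUE)[[1]]
  idx <- integer(0); pow <- integer(0)
  for (part in parts) {
    mm <- regmatches(part, regexec("^M([0-9]+)(\\^([0-9]+))?$", part))[[1]]
    if (length(mm) == 0L) stop("cannot parse monomial '", s, "'")
    idx <- c(idx, as.integer(mm[2]))
    pow <- c(pow, if (mm[4] == "") 1L else as.integer(mm[4]))
  }
  monomial(stats::setNames(pow, idx))
}

#' @export
print.monomial <- function(x, ...) {
  cat(monomial_key(x), "\n")
  invisible(x)
}

#' Enumerate the monomials of an additive or first-order epistasis model
#'
#' Produces, in a fixed deterministic order, the intercept, the p additive
#' (degree-1) monomials, and for `degree = 2` all pairwise products `Mj*Mk`
#' with j < k in lexicographic order, optionally followed by the squares
#' `Mj^2` (the dominance variant).  `selected_pairs` restricts the degree-2
#' pairs to a given subset.
#'
#' @param p number of loci.
#' @param degree total degree of the model, 1 or 2.
#' @param include_squares include `Mj^2` terms (dominance) after the pairs.
#' @param selected_pairs optional 2-column matrix (or list of length-2
#'   vectors) of locus pairs restricting the interaction set.
#' @return List of monomials.
#' @examples
#' length(enumerate_monomials(50, 2)) # 1 + 50 + 1225
#' @export
enumerate_monomials <- function(p, degree = 2L, include_squares = FALSE,
                                selected_pairs = NULL) {
  if (p < 1L) stop("p must be at least 1")
  if (!degree %in% c(1L, 2L))
    stop("only total degree 1 or 2 is supported, got ", degree)
  out <- list(monomial(integer(0)))
  for (j in seq_len(p)) out[[length(out) + 1L]] <- monomial(j)
  if (degree == 2L) {
    if (is.null(selected_pairs)) {
      if (p >= 2L) {
        for (j in seq_len(p - 1L))
          for (k in seq.int(j + 1L, p))
            out[[length(out) + 1L]] <- monomial(c(j, k))
      }
    } else {
      if (is.list(selected_pairs))
        selected_pairs <- do.call(rbind, selected_pairs)
      selected_pairs <- matrix(as.integer(selected_pairs), ncol = 2L)
      for (r in seq_len(nrow(selected_pairs))) {
        jk <- sort(selected_pairs[r, ])
        if (jk[1] == jk[2]) stop("selected_pairs must contain j != k")
        out[[length(out) + 1L]] <- monomial(jk)
      }
    }
    if (include_squares)
      for (j in seq_len(p)) out[[length(out) + 1L]] <- monomial(c(j, j))
  }
  out
}

#' Is a monomial set complete?
#'
#' A monomial set is complete when, for every monomial present, every
#' componentwise-smaller exponent vector is also present.  Completeness is
#' exactly the condition under which a polynomial model can absorb a
#' translation of the marker coding: substituting shifted variables generates
#' all smaller monomials, and each needs a coefficient slot.
#'
#' @param monomials list of monomials.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_complete(enumerate_monomials(2, 2))          # TRUE
#' is_complete(list(monomial(integer(0)), monomial(1), monomial(c(1, 2))))
#' @export
is_complete <- function(monomials) {
  keys <- vapply(monomials, monomial_key, character(1))
  if (anyDuplicated(keys)) stop("monomials must be pairwise distinct")
  for (m in monomials) {
    for (sub in .sub_monomials(m)) {
      if (!(monomial_key(sub) %in% keys)) return(FALSE)
    }
  }
  TRUE
}

# All componentwise-smaller monomials of m (including m and the intercept).
.sub_monomials <- function(m) {
  pow <- unclass(m)
  if (length(pow) == 0L) return(list(monomial(integer(0))))
  grids <- lapply(pow, function(d) 0:d)
  grid <- do.call(expand.grid, grids)
  lapply(seq_len(nrow(grid)), function(r)
    monomial(stats::setNames(as.integer(grid[r, ]), names(pow))))
}

#' Polynomial model over marker dosages
#'
#' Bundles an ordered monomial set with a matching coefficient vector:
#' the intercept (degree 0), additive effects (degree 1) and interaction
#' effects (degree 2) of an epistatic regression live here.
#'
#' @param monomials list of monomials (pairwise distinct).
#' @param coefficients numeric vector, one per monomial.
#' @param p number of loci; inferred from the monomials when omitted.
#' @return Object of class `poly_model`.
#' @export
poly_model <- function(monomials, coefficients, p = NULL) {
  keys <- vapply(monomials, monomial_key, character(1))
  if (anyDuplicated(keys)) stop("monomials must be pairwise distinct")
  if (length(coefficients) != length(monomials))
    stop("need one coefficient per monomial")
  loci <- unlist(lapply(monomials, function(m) as.integer(names(m))))
  if (is.null(p)) p <- if (length(loci)) max(loci) else 1L
  if (length(loci) && max(loci) > p)
    stop("monomial references locus beyond p")
  structure(list(monomials = monomials,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                keys),
                 p = as.integer(p)),
            class = "poly_model")
}

#' @export
print.poly_model <- function(x, digits = 4, ...) {
  deg <- vapply(x$monomials, monomial_degree, integer(1))
  cat(sprintf("poly_model: %d monomials over %d loci, total degree %d\n",
              length(x$monomials), x$p, max(deg)))
  print(utils::head(as.data.frame(x), 10), digits = digits)
  if (length(x$monomials) > 10) cat("...\n")
  invisible(x)
}

#' @export
coef.poly_model <- function(object, ...) object$coefficients

#' Total degree of a polynomial model
#' @param f a `poly_model`.
#' @return Integer.
#' @export
total_degree <- function(f) {
  max(vapply(f$monomials, monomial_degree, integer(1)))
}

#' @export
as.data.frame.poly_model <- function(x, ...) {
  data.frame(monomial = names(x$coefficients),
             degree = vapply(x$monomials, monomial_degree, integer(1)),
             coefficient = as.numeric(x$coefficients),
             stringsAsFactors = FALSE)
}

#' Write / read a polynomial model as a delimited effects table
#'
#' Two tab-separated columns: `monomial` (e.g. `1`, `M13`, `M13*M27`,
#' `M5^2`) and `coefficient`.
#'
#' @param f a `poly_model`.
#' @param path file path.
#' @return `write_effects` returns `path` invisibly; `read_effects` returns
#'   a `poly_model`.
#' @export
write_effects <- function(f, path) {
  utils::write.table(as.data.frame(f)[, c("monomial", "coefficient")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @param p number of loci (optional; inferred when omitted).
#' @export
read_effects <- function(path, p = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  poly_model(lapply(df$monomial, parse_monomial), df$coefficient, p = p)
}

#' Build the design matrix of a monomial set
#'
#' Column c is the rowwise product of dosage powers for monomial c; the
#' intercept monomial gives a column of ones.  Columns appear in the order
#' of `monomials` and are named by their canonical monomial strings.
#'
#' @param M a `marker_matrix` or numeric matrix (used as-is, in its current
#'   coding).
#' @param monomials list of monomials.
#' @return n x q numeric matrix with attribute `monomials`.
#' @export
build_design <- function(M, monomials) {
  V <- as.matrix(as_marker_matrix(M))
  p <- ncol(V)
  q <- length(monomials)
  X <- matrix(1, nrow(V), q)
  for (c in seq_len(q)) {
    m <- unclass(monomials[[c]])
    if (length(m) > 0L) {
      idx <- as.integer(names(m))
      if (max(idx) > p) stop("monomial references locus beyond p = ", p)
      col <- rep(1, nrow(V))
      for (i in seq_along(idx)) col <- col * V[, idx[i]]^m[i]
      X[, c] <- col
    }
  }
  colnames(X) <- vapply(monomials, monomial_key, character(1))
  rownames(X) <- rownames(V)
  attr(X, "monomials") <- monomials
  X
}

#' Evaluate a polynomial model at marker data
#'
#' @param f a `poly_model`.
#' @param M a `marker_matrix`, numeric matrix, or single numeric vector of
#'   dosages (taken as one line).
#' @return Numeric n-vector of polynomial values.
#' @export
evaluate_poly <- function(f, M) {
  if (is.numeric(M) && is.null(dim(M))) M <- matrix(M, nrow = 1)
  X <- build_design(M, f$monomials)
  unname(drop(X %*% f$coefficients))
}

#' @export
predict.poly_model <- function(object, newdata, ...) {
  evaluate_poly(object, newdata)
}

#' Translate a polynomial model to a shifted marker coding
#'
#' Given a polynomial f in the raw coding and a translation P of the marker
#' coding (`M_tilde = M - 1 P^t`), returns the polynomial f_tilde defined by
#' `f_tilde(m) = f(m + P)`, so that f_tilde evaluated at the translated data
#' equals f at the original data, point for point.  Coefficients are obtained
#' by exact binomial expansion of each shifted monomial; any total degree is
#' supported.  Coefficients of monomials of maximal total degree are
#' unchanged by construction.
#'
#' The monomial set must be complete: the expansion generates every
#' componentwise-smaller monomial, and each needs a slot in the model.
#'
#' @param f a `poly_model` with a complete monomial set.
#' @param P numeric translation vector, length p (or scalar, recycled).
#' @return A `poly_model` over the same monomial set, expressed in the
#'   translated coding.
#' @examples
#' f <- poly_model(enumerate_monomials(2, 2), c(1, 2, 0.5, 0.25))
#' translate_poly(f, c(0.5, 0.3))  # intercept becomes 2.1875
#' @export
translate_poly <- function(f, P) {
  if (length(P) == 1L) P <- rep(P, f$p)
  if (length(P) != f$p)
    stop(sprintf("P has length %d but the model has p = %d loci",
                 length(P), f$p))
  keys <- names(f$coefficients)
  new_coef <- stats::setNames(numeric(length(keys)), keys)
  for (c in seq_along(f$monomials)) {
    a <- f$coefficients[[c]]
    if (a == 0) next
    m <- unclass(f$monomials[[c]])
    for (sub in .sub_monomials(f$monomials[[c]])) {
      spow <- unclass(sub)
      # binomial weight: prod_j choose(d_j, delta_j) * P_j^(d_j - delta_j)
      w <- 1
      for (nm in names(m)) {
        d <- m[[nm]]
        delta <- if (nm %in% names(spow)) spow[[nm]] else 0L
        w <- w * choose(d, delta) * P[as.integer(nm)]^(d - delta)
      }
      contrib <- a * w
      if (contrib == 0) next
      key <- monomial_key(sub)
      slot <- match(key, keys)
      if (is.na(slot))
        stop("monomial set is not complete: translation generates '",
             key, "' which has no coefficient slot")
      new_coef[[slot]] <- new_coef[[slot]] + contrib
    }
  }
  poly_model(f$monomials, new_coef, p = f$p)
}
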