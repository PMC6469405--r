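#' Additive genomic relationship matrix
#'
#' Computes `G = M M^t` under the matrix's current coding.  Note that G
#' depends on the coding: centred and raw dosages give different matrices,
#' which is the starting point of the coding-sensitivity question for
#' Hadamard-product interaction kernels.
#'
#' @param M a `marker_matrix` or numeric dosage matrix.
#' @param normalization `"none"` (default) or `"trace_n"` (scale so that
#'   `mean(diag(G)) = 1`).
#' @return n x n symmetric matrix with attributes `kind` and
#'   `normalization`.
#' @export
additive_kernel <- function(M, normalization = c("none", "trace_n")) {
  normalization <- match.arg(normalization)
  V <- as.matrix(as_marker_matrix(M))
  G <- tcrossprod(V)
  if (normalization == "trace_n") {
    tr <- sum(diag(G))
    if (tr <= 0) stop("cannot trace-normalize a zero kernel")
    G <- G * (nrow(G) / tr)
  }
  structure(G, kind = "additive", normalization = normalization)
}

#' Epistatic (pairwise-interaction) relationship matrix
#'
#' Computes `H = 0.5 (MM^t o MM^t) - 0.5 (M o M)(M o M)^t`, where `o` is
#' the Hadamard (entrywise) product.  Entry (i, i') equals
#' `sum_{j < k} M_ij M_ik M_i'j M_i'k`, the covariance structure induced by
#' i.i.d. pairwise interaction effects; the subtraction removes the j = k
#' diagonal terms of the squared additive kernel.  By default H is divided
#' by its maximum entry, which rescales the associated variance component
#' (and hence any penalty factor derived from it) but not the model itself.
#'
#' @param M a `marker_matrix` or numeric dosage matrix (p >= 2 for a
#'   nonzero result).
#' @param normalization `"max"` (default; error if H is identically zero)
#'   or `"none"`.
#' @return n x n symmetric matrix with attributes `kind` and
#'   `normalization`.
#' @export
epistatic_kernel <- function(M, normalization = c("max", "none")) {
  normalization <- match.arg(normalization)
  V <- as.matrix(as_marker_matrix(M))
  G <- tcrossprod(V)
  H <- 0.5 * (G * G) - 0.5 * tcrossprod(V * V)
  if (normalization == "max") {
    mx <- max(H)
    if (mx <= 0)
      stop("epistatic kernel is identically zero; cannot max-normalize")
    H <- H / mx
  }
  structure(H, kind = "epistatic", normalization = normalization)
}
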