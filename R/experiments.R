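# Apply one of the three study codings to a marker matrix.
.apply_coding <- function(M, coding, max_dosage) {
  switch(coding,
         original = translate_markers(M, "none"),
         centered = translate_markers(M, "column_mean"),
         symmetric = translate_markers(M, "symmetric",
                                       max_dosage = max_dosage),
         stop("unknown coding '", coding, "'"))
}

# Subset a marker_matrix by line / marker index, keeping the raw coding.
.subset_markers <- function(M, lines = NULL, markers = NULL) {
  V <- M$values
  s <- M$shift
  if (!is.null(markers)) {
    V <- V[, markers, drop = FALSE]
    s <- s[markers]
  }
  if (!is.null(lines)) V <- V[lines, , drop = FALSE]
  marker_matrix(V, shift = s)
}

# Penalty factors per the study protocol: variance components estimated
# once, on the column-mean-centered coding, then frozen across codings.
# Unnormalized kernels keep the kernel-scale variances equal to the
# per-effect variances, so lambda = sigma2_eps / sigma2_component directly.
.protocol_lambda <- function(M, y, penalize_additive) {
  Mc <- translate_markers(M, "column_mean")
  H <- epistatic_kernel(Mc, normalization = "none")
  kernels <- if (penalize_additive)
    list(additive = additive_kernel(Mc), epistatic = H)
  else
    list(epistatic = H)
  vc <- reml(y, kernels)
  lam2 <- penalty_from_varcomp(vc, "epistatic")
  lam1 <- if (penalize_additive)
    penalty_from_varcomp(vc, "additive") else 0
  c(lambda1 = unname(lam1), lambda2 = unname(lam2))
}

#' Rank changes of interaction-effect estimates between two codings
#'
#' Estimates are ranked by descending absolute value (rank 1 = largest;
#' ties broken by original position); the per-interaction rank change is
#' the absolute difference of ranks between the two vectors.
#'
#' @param e_a,e_b numeric vectors of interaction estimates, equal length.
#' @return List with `max_change` (integer) and `per_interaction`
#'   (integer vector of |rank_a - rank_b|).
#' @export
rank_change <- function(e_a, e_b) {
  if (length(e_a) != length(e_b))
    stop("estimate vectors must have equal length")
  ra <- rank(-abs(e_a), ties.method = "first")
  rb <- rank(-abs(e_b), ties.method = "first")
  ch <- abs(ra - rb)
  list(max_change = as.integer(max(ch)), per_interaction = as.integer(ch))
}

#' Compare interaction-effect estimates across marker codings
#'
#' The coding-sensitivity experiment: repeatedly draw random marker subsets
#' (and optionally reduced line sets), fit the complete degree-2 ridge model
#' under each coding with penalty factors held fixed, and correlate the
#' interaction-estimate vectors between codings.  Penalty factors are
#' estimated once by REML on the column-mean-centered coding of the full
#' data and then frozen, so the comparison isolates the direct effect of
#' the coding from the indirect effect of re-estimated variance components;
#' pass `lambda` to skip the REML step.
#'
#' With `penalize_additive = FALSE` (additive effects fixed, only
#' interactions penalized) the interaction estimates are translation
#' invariant and every cross-coding correlation is 1 up to numerical error.
#'
#' @param M full `marker_matrix` (raw coding) or numeric dosage matrix.
#' @param y phenotype vector.
#' @param codings subset of `c("original", "symmetric", "centered")`.
#' @param n_markers markers drawn per repetition.
#' @param n_lines lines used per repetition (`NULL` = all).
#' @param repetitions number of random draws.
#' @param penalize_additive penalize additive effects (eRRBLUP-1) or model
#'   them as fixed (eRRBLUP-2).
#' @param lambda optional `c(lambda1, lambda2)` overriding the REML
#'   protocol.
#' @param max_dosage maximum raw dosage (default: max of the matrix), used
#'   by the symmetric coding.
#' @param seed integer; each repetition uses a stream derived from
#'   `(seed, repetition)` so runs are reproducible and individually
#'   re-runnable.
#' @return Object of class `coding_comparison`: per-pair mean/SE Pearson
#'   correlations of interaction estimates, rank-change summaries, the
#'   per-repetition correlation matrix, and the penalty factors used.
#' @export
coding_comparison <- function(M, y,
                              codings = c("original", "symmetric",
                                          "centered"),
                              n_markers = 50L, n_lines = NULL,
                              repetitions = 50L,
                              penalize_additive = TRUE,
                              lambda = NULL, max_dosage = NULL,
                              seed = 1L) {
  M <- as_marker_matrix(M)
  y <- align_phenotype(M, y)
  n <- nrow(M$values); p <- ncol(M$values)
  if (n_markers > p) stop("n_markers exceeds the number of markers")
  n_train <- if (is.null(n_lines)) n else n_lines
  if (!penalize_additive && n_markers + 1L >= n_train)
    stop("with fixed (unpenalized) additive effects, n_markers + 1 must be ",
         "below the number of lines")
  if (is.null(max_dosage)) max_dosage <- max(M$values)
  if (is.null(lambda)) lambda <- .protocol_lambda(M, y, penalize_additive)
  lambda1 <- if (penalize_additive) lambda[[1]] else 0
  lambda2 <- lambda[[length(lambda)]]

  pairs <- if (length(codings) >= 2L) utils::combn(codings, 2L)
           else matrix(rep(codings, 2L), nrow = 2L)
  npair <- ncol(pairs)
  cors <- matrix(NA_real_, repetitions, npair)
  maxrank <- matrix(NA_integer_, repetitions, npair)
  pair_names <- paste(pairs[1, ], pairs[2, ], sep = " vs ")
  monomorphic <- integer(repetitions)

  for (rep_i in seq_len(repetitions)) {
    est <- with_seed(seed + 1009L * rep_i, {
      mk <- sample.int(p, n_markers)
      ln <- if (is.null(n_lines)) seq_len(n) else sample.int(n, n_lines)
      Msub <- .subset_markers(M, lines = ln, markers = mk)
      monomorphic[rep_i] <- sum(apply(Msub$values, 2,
                                      function(v) length(unique(v)) == 1L))
      lapply(stats::setNames(codings, codings), function(cd) {
        fit <- epifit(.apply_coding(Msub, cd, max_dosage), y[ln],
                      degree = 2L, method = "ridge",
                      lambda1 = lambda1, lambda2 = lambda2)
        interaction_effects(fit)
      })
    })
    for (j in seq_len(npair)) {
      ea <- est[[pairs[1, j]]]; eb <- est[[pairs[2, j]]]
      cors[rep_i, j] <- if (identical(pairs[1, j], pairs[2, j])) 1
                        else stats::cor(ea, eb)
      maxrank[rep_i, j] <- rank_change(ea, eb)$max_change
    }
  }
  colnames(cors) <- colnames(maxrank) <- pair_names
  structure(list(
    pairwise_correlations = data.frame(
      pair = pair_names,
      mean = colMeans(cors),
      se = apply(cors, 2, stats::sd) / sqrt(repetitions),
      row.names = NULL),
    rank_stats = data.frame(
      pair = pair_names,
      mean_max_change = colMeans(maxrank),
      max_change = apply(maxrank, 2, max),
      row.names = NULL),
    correlations = cors,
    max_rank_changes = maxrank,
    lambda = c(lambda1 = lambda1, lambda2 = lambda2),
    penalize_additive = penalize_additive,
    n_markers = n_markers, repetitions = repetitions,
    monomorphic_drawn = monomorphic,
    seed = seed), class = "coding_comparison")
}

#' @export
print.coding_comparison <- function(x, digits = 4, ...) {
  cat(sprintf(
    "coding comparison: %d reps, %d markers, additive effects %s\n",
    x$repetitions, x$n_markers,
    if (x$penalize_additive) "penalized" else "fixed"))
  cat(sprintf("penalty factors: lambda1 = %.4g, lambda2 = %.4g\n",
              x$lambda[["lambda1"]], x$lambda[["lambda2"]]))
  cat("\nPearson correlation of interaction estimates:\n")
  print(x$pairwise_correlations, digits = digits, row.names = FALSE)
  cat("\nAbsolute-value rank changes:\n")
  print(x$rank_stats, digits = digits, row.names = FALSE)
  if (any(x$monomorphic_drawn > 0))
    cat(sprintf("note: %d repetition(s) drew monomorphic markers\n",
                sum(x$monomorphic_drawn > 0)))
  invisible(x)
}

#' Out-of-sample prediction under different marker codings
#'
#' Per repetition: draw a random marker subset and a random test set of
#' lines, fit the degree-2 ridge model on the remaining (training) lines
#' under each coding with frozen penalty factors, and predict the test
#' lines.  Reports the predictive ability (Pearson correlation of predicted
#' and observed test phenotypes) per coding and the cross-coding correlation
#' of the predictions.  Repetitions in which a prediction or the test
#' phenotype is constant are excluded from the means and counted.
#'
#' @inheritParams coding_comparison
#' @param test_size number of held-out lines per repetition (>= 2).
#' @param n_train training lines per repetition (`NULL` = all remaining).
#' @return Object of class `oos_eval` with `predictive_ability` (per-coding
#'   mean/SE), `cross_coding` (per-pair mean/SE of prediction correlations),
#'   the per-repetition matrices, and the number of excluded repetitions.
#' @export
out_of_sample_eval <- function(M, y,
                               codings = c("original", "symmetric",
                                           "centered"),
                               n_markers = 50L, test_size = 60L,
                               n_train = NULL, repetitions = 200L,
                               penalize_additive = TRUE,
                               lambda = NULL, max_dosage = NULL,
                               seed = 1L) {
  M <- as_marker_matrix(M)
  y <- align_phenotype(M, y)
  n <- nrow(M$values); p <- ncol(M$values)
  if (test_size < 2L) stop("test_size must be at least 2")
  if (test_size >= n) stop("test_size must leave training lines")
  if (n_markers > p) stop("n_markers exceeds the number of markers")
  if (is.null(max_dosage)) max_dosage <- max(M$values)
  if (is.null(lambda)) lambda <- .protocol_lambda(M, y, penalize_additive)
  lambda1 <- if (penalize_additive) lambda[[1]] else 0
  lambda2 <- lambda[[length(lambda)]]

  pairs <- if (length(codings) >= 2L) utils::combn(codings, 2L)
           else matrix(rep(codings, 2L), nrow = 2L)
  pair_names <- paste(pairs[1, ], pairs[2, ], sep = " vs ")
  ability <- matrix(NA_real_, repetitions, length(codings),
                    dimnames = list(NULL, codings))
  cross <- matrix(NA_real_, repetitions, ncol(pairs),
                  dimnames = list(NULL, pair_names))
  excluded <- 0L

  for (rep_i in seq_len(repetitions)) {
    res <- with_seed(seed + 1009L * rep_i, {
      mk <- sample.int(p, n_markers)
      test <- sample.int(n, test_size)
      train_pool <- setdiff(seq_len(n), test)
      train <- if (is.null(n_train)) train_pool
               else sample(train_pool, n_train)
      Mtr <- .subset_markers(M, lines = train, markers = mk)
      Mte <- .subset_markers(M, lines = test, markers = mk)
      preds <- lapply(stats::setNames(codings, codings), function(cd) {
        fit <- epifit(.apply_coding(Mtr, cd, max_dosage), y[train],
                      degree = 2L, method = "ridge",
                      lambda1 = lambda1, lambda2 = lambda2)
        predict(fit, Mte)
      })
      list(preds = preds, ytest = y[test])
    })
    const <- stats::sd(res$ytest) == 0 ||
      any(vapply(res$preds, stats::sd, numeric(1)) == 0)
    if (const) {
      excluded <- excluded + 1L
      next
    }
    for (cd in codings)
      ability[rep_i, cd] <- stats::cor(res$preds[[cd]], res$ytest)
    for (j in seq_len(ncol(pairs)))
      cross[rep_i, j] <- if (identical(pairs[1, j], pairs[2, j])) 1
                         else stats::cor(res$preds[[pairs[1, j]]],
                                         res$preds[[pairs[2, j]]])
  }
  agg <- function(mat) data.frame(
    name = colnames(mat),
    mean = colMeans(mat, na.rm = TRUE),
    se = apply(mat, 2, function(v) stats::sd(v, na.rm = TRUE)) /
      sqrt(colSums(!is.na(mat))),
    row.names = NULL)
  structure(list(predictive_ability = agg(ability),
                 cross_coding = agg(cross),
                 ability = ability, cross = cross,
                 lambda = c(lambda1 = lambda1, lambda2 = lambda2),
                 excluded = excluded,
                 repetitions = repetitions, n_markers = n_markers,
                 test_size = test_size, seed = seed),
            class = "oos_eval")
}

#' @export
print.oos_eval <- function(x, digits = 4, ...) {
  cat(sprintf(
    "out-of-sample evaluation: %d reps, %d markers, test size %d\n",
    x$repetitions, x$n_markers, x$test_size))
  cat("\nPredictive ability (cor of predicted and observed, test set):\n")
  print(x$predictive_ability, digits = digits, row.names = FALSE)
  cat("\nCross-coding correlation of predictions:\n")
  print(x$cross_coding, digits = digits, row.names = FALSE)
  if (x$excluded > 0)
    cat(sprintf("%d repetition(s) excluded (constant predictions or y)\n",
                x$excluded))
  invisible(x)
}

#' Residual variance of an interactions-only kernel model, per coding
#'
#' For each coding, builds the max-normalized epistatic relationship matrix
#' from the translated markers and estimates, by REML, the model with that
#' single kernel plus residual.  The residual variance -- the phenotypic
#' variance the epistatic relationship cannot capture -- depends on the
#' coding, unlike the additive counterpart.
#'
#' @inheritParams coding_comparison
#' @return List of class `residual_by_coding` with `sigma2_eps` (named
#'   per-coding vector) and `varcomps` (the full `varcomp` objects).
#' @export
residual_variance_by_coding <- function(M, y,
                                        codings = c("original", "symmetric",
                                                    "centered"),
                                        max_dosage = NULL) {
  M <- as_marker_matrix(M)
  y <- align_phenotype(M, y)
  if (is.null(max_dosage)) max_dosage <- max(M$values)
  vcs <- lapply(stats::setNames(codings, codings), function(cd) {
    H <- epistatic_kernel(.apply_coding(M, cd, max_dosage),
                          normalization = "max")
    reml(y, list(epistatic = H))
  })
  structure(list(sigma2_eps = vapply(vcs, function(v)
                   v$sigma2[["residual"]], numeric(1)),
                 varcomps = vcs),
            class = "residual_by_coding")
}

#' @export
print.residual_by_coding <- function(x, digits = 4, ...) {
  cat("Residual variance of the interactions-only kernel model:\n")
  print(round(x$sigma2_eps, digits))
  invisible(x)
}
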