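test_that("rank changes are computed on descending absolute values", {
  expect_equal(rank_change(c(3, -2, 1), c(3, -2, 1))$max_change, 0L)
  # hand enumeration: ranks of (3, 2, 1) are (1, 2, 3); ranks of
  # (1, 3, 2) are (3, 1, 2); per-interaction |difference| = (2, 1, 1)
  rc <- rank_change(c(3, 2, 1), c(1, 3, 2))
  expect_equal(rc$per_interaction, c(2L, 1L, 1L))
  expect_equal(rc$max_change, 2L)
  # exactly reversed order: extremal change q - 1
  q <- 7
  expect_equal(rank_change(seq_len(q), rev(seq_len(q)))$max_change,
               q - 1L)
  # ranking uses absolute values
  expect_equal(rank_change(c(-5, 1), c(-5, 1))$max_change, 0L)
  expect_error(rank_change(1:3, 1:4), "equal length")
})

test_that("interactions-only penalty makes codings agree exactly", {
  M <- simulate_genotypes(60, 8, ploidy = 1, seed = 101)
  sim <- simulate_phenotypes(M, sigma2_beta = 0.3, sigma2_h = 0.1,
                             sigma2_eps = 0.2, seed = 102)
  cc <- coding_comparison(M, sim$phenotype, n_markers = 6,
                          repetitions = 3, penalize_additive = FALSE,
                          lambda = c(0, 1), seed = 103)
  expect_true(all(abs(cc$correlations - 1) < 1e-6))
})

test_that("penalizing additive effects breaks cross-coding agreement", {
  M <- simulate_genotypes(60, 8, ploidy = 1, seed = 104)
  sim <- simulate_phenotypes(M, sigma2_beta = 0.3, sigma2_h = 0.1,
                             sigma2_eps = 0.2, seed = 105)
  cc <- coding_comparison(M, sim$phenotype, n_markers = 6,
                          repetitions = 3, penalize_additive = TRUE,
                          lambda = c(1, 1), seed = 106)
  expect_true(all(cc$correlations < 1))
  expect_true(all(cc$correlations > -1))
})

test_that("a single coding yields the trivial self-comparison", {
  M <- simulate_genotypes(40, 6, seed = 107)
  sim <- simulate_phenotypes(M, seed = 108)
  cc <- coding_comparison(M, sim$phenotype, codings = "original",
                          n_markers = 4, repetitions = 2,
                          lambda = c(1, 1), seed = 109)
  expect_equal(unname(cc$pairwise_correlations$mean), 1)
})

test_that("experiments are reproducible given seed and config", {
  M <- simulate_genotypes(50, 8, seed = 110)
  sim <- simulate_phenotypes(M, seed = 111)
  run <- function() coding_comparison(M, sim$phenotype, n_markers = 5,
                                      repetitions = 3, lambda = c(1, 1),
                                      seed = 112)
  expect_identical(run()$correlations, run()$correlations)
})

test_that("fixed additive effects need enough lines", {
  M <- simulate_genotypes(20, 19, seed = 113)
  expect_error(
    coding_comparison(M, rnorm(20), n_markers = 19, repetitions = 1,
                      penalize_additive = FALSE, lambda = c(0, 1)),
    "below the number of lines")
})

test_that("out-of-sample harness reports abilities and cross correlations", {
  M <- simulate_genotypes(90, 10, seed = 114)
  sim <- simulate_phenotypes(M, sigma2_beta = 0.5, sigma2_h = 0.05,
                             sigma2_eps = 0.1, seed = 115)
  ev <- out_of_sample_eval(M, sim$phenotype, n_markers = 8,
                           test_size = 15, repetitions = 5,
                           penalize_additive = FALSE, lambda = c(0, 1),
                           seed = 116)
  # interactions-only penalty: predictions identical across codings
  expect_true(all(abs(ev$cross - 1) < 1e-6, na.rm = TRUE))
  # strong signal, little noise: clearly positive predictive ability
  expect_true(all(ev$predictive_ability$mean > 0.3))
  expect_equal(ev$excluded, 0L)
})

test_that("phenotypes independent of the markers predict at chance", {
  M <- simulate_genotypes(80, 8, seed = 117)
  set.seed(118)
  y <- rnorm(80)
  ev <- out_of_sample_eval(M, y, n_markers = 6, test_size = 20,
                           repetitions = 40, lambda = c(1, 1),
                           seed = 119)
  for (i in seq_along(ev$predictive_ability$mean)) {
    expect_lt(abs(ev$predictive_ability$mean[i]),
              2.5 * ev$predictive_ability$se[i] + 0.05)
  }
})

test_that("predictive ability grows with the training set", {
  M <- simulate_genotypes(320, 12, ploidy = 1, seed = 120)
  sim <- simulate_phenotypes(M, sigma2_beta = 0.4, sigma2_h = 0.1,
                             sigma2_eps = 0.3, seed = 121)
  sizes <- c(60, 140, 280)
  means <- vapply(sizes, function(sz) {
    ev <- out_of_sample_eval(M, sim$phenotype, codings = "original",
                             n_markers = 10, test_size = 30,
                             n_train = sz, repetitions = 25,
                             lambda = c(1, 1), seed = 122)
    mean(ev$predictive_ability$mean)
  }, numeric(1))
  expect_true(means[3] > means[1])
  # allow at most one inversion along the size trend
  expect_lte(sum(diff(means) < 0), 1)
})

test_that("residual variance is lowest for the generating coding", {
  # phenotypes built from interactions in a given coding should be best
  # explained by the epistatic kernel of that same coding
  hits <- 0L
  reps <- 12
  for (r in seq_len(reps)) {
    M <- simulate_genotypes(80, 10, ploidy = 1, seed = 200 + r)
    Msym <- translate_markers(M, "symmetric", max_dosage = 1)
    sim <- simulate_phenotypes(Msym, mu = 0, sigma2_beta = 0,
                               sigma2_h = 0.4, sigma2_eps = 0.1,
                               seed = 300 + r)
    rv <- residual_variance_by_coding(M, sim$phenotype,
                                      codings = c("original", "symmetric"),
                                      max_dosage = 1)
    if (rv$sigma2_eps[["symmetric"]] < rv$sigma2_eps[["original"]])
      hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})

test_that("pure noise leaves the residual close to the sample variance", {
  # low-rank kernel (28 pair dimensions) against n = 300 observations,
  # so the kernel cannot soak up appreciable noise variance
  M <- simulate_genotypes(300, 8, seed = 130)
  set.seed(131)
  y <- rnorm(300, sd = sqrt(0.8))
  rv <- residual_variance_by_coding(M, y, codings = "centered")
  expect_equal(unname(rv$sigma2_eps), var(y), tolerance = 0.15)
})

test_that("identical codings give identical residual variances", {
  M <- simulate_genotypes(60, 8, seed = 132)
  sim <- simulate_phenotypes(M, seed = 133)
  rv <- residual_variance_by_coding(M, sim$phenotype,
                                    codings = c("centered", "centered"))
  expect_equal(rv$sigma2_eps[[1]], rv$sigma2_eps[[2]], tolerance = 1e-12)
})
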