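test_that("monomial enumeration has the expected size and order", {
  m2 <- enumerate_monomials(2, 2)
  expect_equal(vapply(m2, monomial_key, character(1)),
               c("1", "M1", "M2", "M1*M2"))
  expect_equal(vapply(enumerate_monomials(2, 1), monomial_key,
                      character(1)), c("1", "M1", "M2"))
  expect_length(enumerate_monomials(50, 2), 1 + 50 + 1225)
  expect_length(enumerate_monomials(3, 2, include_squares = TRUE),
                1 + 3 + 3 + 3)
  # degenerate single-locus interaction request: no pairs, no error
  expect_equal(vapply(enumerate_monomials(1, 2), monomial_key,
                      character(1)), c("1", "M1"))
  expect_error(enumerate_monomials(3, 3), "degree")
  sel <- enumerate_monomials(5, 2, selected_pairs = rbind(c(2, 4)))
  expect_equal(monomial_key(sel[[length(sel)]]), "M2*M4")
  expect_length(sel, 7)
})

test_that("monomial keys serialize and parse canonically", {
  keys <- c("1", "M3", "M1*M2", "M5^2", "M2*M7^2")
  for (k in keys)
    expect_equal(monomial_key(epiridge:::parse_monomial(k)), k)
  expect_equal(monomial_key(monomial(c(2, 1))), "M1*M2")
  expect_equal(monomial_key(monomial(c(3, 3))), "M3^2")
  expect_equal(monomial_degree(monomial(c(3, 3))), 2L)
})

test_that("completeness detects missing lower-order terms", {
  expect_true(is_complete(enumerate_monomials(2, 2)))
  expect_true(is_complete(enumerate_monomials(4, 2,
                                              include_squares = TRUE)))
  incomplete <- list(monomial(integer(0)), monomial(1), monomial(c(1, 2)))
  expect_false(is_complete(incomplete))
  expect_true(is_complete(list(monomial(integer(0)))))
  # missing intercept also breaks completeness
  expect_false(is_complete(list(monomial(1))))
})

test_that("design matrices are rowwise products of dosage powers", {
  M <- toy_markers()
  X <- build_design(M, enumerate_monomials(2, 2))
  expect_equal(unname(X[, 1]), rep(1, 5))
  expect_equal(unname(X[, 4]), c(4, 2, 0, 2, 0))
  Xc <- build_design(translate_markers(M, "column_mean"),
                     enumerate_monomials(2, 2))
  expect_equal(unname(Xc[, 4]), c(0.4, -0.6, -0.4, 0, 0.6),
               tolerance = 1e-12)
  X1 <- build_design(M, list(monomial(integer(0))))
  expect_equal(unname(X1), matrix(1, 5, 1), ignore_attr = TRUE)
  # squares
  Xsq <- build_design(M, list(monomial(c(1, 1))))
  expect_equal(unname(Xsq[, 1]), unname(as.matrix(M)[, 1]^2))
})

test_that("translating a polynomial preserves its values pointwise", {
  # direct-evaluation oracle: f_tilde(m - P) must equal f(m) everywhere
  for (seed in 1:10) {
    f <- rand_poly(4, seed)
    set.seed(seed + 500)
    P <- rnorm(4)
    ft <- translate_poly(f, P)
    pts <- matrix(rnorm(100 * 4), 100, 4)
    expect_equal(evaluate_poly(ft, pts - rep(P, each = 100)),
                 evaluate_poly(f, pts), tolerance = 1e-10)
    # top-degree coefficients are unchanged exactly
    deg <- vapply(f$monomials, monomial_degree, integer(1))
    expect_identical(coef(ft)[deg == 2], coef(f)[deg == 2])
    # inverse shift recovers the original coefficients
    back <- translate_poly(ft, -P)
    expect_equal(coef(back), coef(f), tolerance = 1e-10)
  }
})

test_that("degree-2 closed form of the translated coefficients holds", {
  f <- poly_model(enumerate_monomials(2, 2), c(1, 2, 0.5, 0.25))
  ft <- translate_poly(f, c(0.5, 0.3))
  expect_equal(unname(coef(ft)), c(2.1875, 2.075, 0.625, 0.25))
  expect_equal(evaluate_poly(f, c(2, 2)), 7)
  expect_equal(evaluate_poly(ft, c(1.5, 1.7)), 7)
  # zero shift is the identity
  expect_equal(coef(translate_poly(f, c(0, 0))), coef(f))
  # zero polynomial stays zero
  z <- poly_model(enumerate_monomials(2, 2), rep(0, 4))
  expect_equal(unname(coef(translate_poly(z, c(1, 2)))), rep(0, 4))
  expect_equal(evaluate_poly(z, c(3, 3)), 0)
})

test_that("translation handles higher degrees by binomial expansion", {
  # cubic in one variable: f(x) = (x + 1)^3 has known shifted coefficients
  mono <- list(monomial(integer(0)), monomial(1), monomial(c(1, 1)),
               monomial(c(1, 1, 1)))
  f <- poly_model(mono, c(0, 0, 0, 1), p = 1)  # f(x) = x^3
  ft <- translate_poly(f, 2)  # f_tilde(u) = (u + 2)^3
  expect_equal(unname(coef(ft)), c(8, 12, 6, 1))
  set.seed(9)
  u <- rnorm(20)
  expect_equal(evaluate_poly(ft, matrix(u)), (u + 2)^3, tolerance = 1e-10)
})

test_that("translating an incomplete model is a completeness error", {
  f <- poly_model(list(monomial(integer(0)), monomial(1),
                       monomial(c(1, 2))), c(1, 2, 3), p = 2)
  expect_error(translate_poly(f, c(0.5, 0.5)), "complete")
})

test_that("a locus absent from higher monomials keeps its coefficient", {
  # model mu + b1 M1 + b2 M2 + b3 M3 + h23 M2 M3: M1's coefficient is
  # invariant under translation even though degree 1 < total degree 2
  mono <- list(monomial(integer(0)), monomial(1), monomial(2), monomial(3),
               monomial(c(2, 3)))
  f <- poly_model(mono, c(0.3, 1.7, -0.8, 0.6, 0.9), p = 3)
  ft <- translate_poly(f, c(0.4, -1.2, 2.5))
  expect_equal(coef(ft)[["M1"]], coef(f)[["M1"]])
  expect_equal(coef(ft)[["M2*M3"]], coef(f)[["M2*M3"]])
  expect_false(isTRUE(all.equal(coef(ft)[["M2"]], coef(f)[["M2"]])))
})

test_that("SSR is preserved when model and data are translated together", {
  for (seed in 1:5) {
    M <- rand_markers(12, 3, seed)
    set.seed(seed + 900)
    y <- rnorm(12)
    P <- rnorm(3)
    f <- rand_poly(3, seed + 50)
    ft <- translate_poly(f, P)
    Mt <- translate_markers(M, "constant", P = P)
    ssr <- function(f, M) sum((y - evaluate_poly(f, M))^2)
    expect_equal(ssr(f, M), ssr(ft, Mt), tolerance = 1e-10)
  }
})

test_that("effects tables round-trip through delimited text", {
  f <- rand_poly(3, 77)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_effects(f, path)
  f2 <- read_effects(path, p = 3)
  expect_equal(coef(f2), coef(f))
  expect_equal(vapply(f2$monomials, monomial_key, character(1)),
               vapply(f$monomials, monomial_key, character(1)))
})
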