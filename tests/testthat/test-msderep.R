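test_that("formula parsing round-trips and rejects bad input", {
  expect_equal(unclass(parse_formula("C18H33NO4"))[c("C", "H", "N", "O")],
               c(C = 18L, H = 33L, N = 1L, O = 4L))
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L),
               ignore_attr = TRUE)
  cc <- parse_formula("C29H40BrClO9")
  expect_equal(unclass(cc)[c("C", "H", "Br", "Cl", "O")],
               c(C = 29L, H = 40L, Br = 1L, Cl = 1L, O = 9L))
  expect_equal(attr(cc, "formula"), "C29H40BrClO9")  # Hill order
  expect_equal(attr(parse_formula("O4NC18H33"), "formula"), "C18H33NO4")
  expect_error(parse_formula("C5Xx2"), "unknown element")
  expect_error(parse_formula("C18h33"), "malformed|unknown")
})

test_that("monoisotopic masses match a pinned-table sum and printed values", {
  expect_equal(monoisotopic_mass("SO3"), 79.9568, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("H2O"), 2 * 1.0078250 + 15.9949146,
               tolerance = 1e-6)
  # independent table-sum oracle for the statine macrolide formula
  oracle <- 18 * 12 + 33 * 1.007825032 + 14.003074005 + 4 * 15.994914620
  expect_equal(monoisotopic_mass("C18H33NO4"), oracle, tolerance = 1e-9)
  expect_equal(round(monoisotopic_mass("C18H33NO4"), 4), 327.2410)
  # additivity over disjoint formulas
  expect_equal(monoisotopic_mass("C10H15NO2") + monoisotopic_mass("C8H18O2"),
               monoisotopic_mass("C18H33NO4"), tolerance = 1e-9)
})

test_that("adduct m/z agree with reported dereplication values", {
  expect_equal(adduct_mz("C18H33NO4", "[M+H]+"), 328.2483, tolerance = 0.001)
  expect_equal(adduct_mz("C29H40BrClO9", "[M-H2O+H]+"), 629.1512,
               tolerance = 0.001)
  # a zero-mass neutral picks up exactly one proton
  expect_equal(adduct_mz(0, "[M+H]+"), 1.00728, tolerance = 1e-5)
  expect_error(adduct_mz("C6H6", "[M+K]+"), "unsupported adduct")
})

test_that("ppm errors are signed and zero at equality", {
  expect_equal(round(ppm_error(328.2485, 328.2483), 2), 0.61)
  expect_equal(round(ppm_error(629.1510, 629.1512), 2), -0.32)
  expect_equal(ppm_error(500.123, 500.123), 0)
  for (i in 1:20) {
    obs <- runif(1, 100, 1000); calc <- runif(1, 100, 1000)
    expect_equal(sign(ppm_error(obs, calc)), sign(obs - calc))
  }
  expect_error(ppm_error(100, 0), "positive")
})

test_that("degrees of unsaturation follow the CHNOPS+halogen rule", {
  expect_equal(rdbe("C18H33NO4"), 3)
  expect_equal(rdbe("C29H40BrClO9"), 9)
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C6H6"), 4)
  expect_error(rdbe("C2H6NaO"), "valence")
})

test_that("isotope patterns reproduce halogen signatures", {
  p <- isotope_pattern("CH3Cl")
  m2 <- p$abundance[p$offset == 2] / p$abundance[p$offset == 0]
  expect_equal(m2, 0.320, tolerance = 0.005)
  p <- isotope_pattern("C6H5Br")
  m2 <- p$abundance[p$offset == 2] / p$abundance[p$offset == 0]
  expect_equal(m2, 0.973, tolerance = 0.005)
  p <- isotope_pattern("C10H20")
  expect_lt(p$abundance[p$offset == 2] / p$abundance[p$offset == 0], 0.03)
})

test_that("isotope patterns match the closed-form binomial for Cl_n", {
  for (n in 1:3) {
    p <- isotope_pattern(c(Cl = n))
    got <- p$abundance[match(seq(0, 2 * n, 2), p$offset)]
    expect_equal(got, cl_cluster_oracle(n), tolerance = 1e-6)
  }
})

test_that("halogen inference recovers Cl/Br counts", {
  expect_equal(infer_halogens(isotope_pattern("C29H40BrClO9")),
               c(n_Cl = 1L, n_Br = 1L))
  expect_equal(infer_halogens(isotope_pattern("C20H30O5")),
               c(n_Cl = 0L, n_Br = 0L))
  expect_equal(infer_halogens(isotope_pattern(c(Cl = 2))),
               c(n_Cl = 2L, n_Br = 0L))
})

test_that("neutral-loss annotation matches reported sulfate loss", {
  ann <- annotate_neutral_losses(c(381.0906, 301.1396), tolerance_da = 0.01)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$loss, "SO3")
  expect_equal(ann$delta_observed, 79.9510, tolerance = 1e-4)
  expect_equal(ann$delta_calcd, 79.9568, tolerance = 1e-4)
  ann <- annotate_neutral_losses(c(200.0, 200.0 + 18.0106))
  expect_equal(ann$loss, "H2O")
  expect_equal(nrow(annotate_neutral_losses(c(200, 250))), 0L)
})

test_that("spectrum filtering removes precursor region and ranks windows", {
  s <- new_spectrum(c(100, 295, 300), c(1, 1, 1), precursor_mz = 300)
  f <- preprocess_spectrum(s)
  expect_equal(f$mz, 100)  # peaks at precursor - 5 and at precursor removed
  # 8 distinctly-intense peaks inside one 50 Da span: top 6 survive
  s <- new_spectrum(150 + seq(0, 35, 5), 8:1, precursor_mz = 600)
  f <- preprocess_spectrum(s)
  expect_equal(length(f$mz), 6L)
  expect_setequal(f$intensity, 3:8)
  e <- preprocess_spectrum(new_spectrum(numeric(0), numeric(0), 500))
  expect_equal(length(e$mz), 0L)
})

test_that("modified cosine handles identity, disjoint, and toy cases", {
  a <- new_spectrum(c(100, 150, 200), c(5, 2, 1), 400)
  self <- modified_cosine(a, a)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$matched, 3L)
  b <- new_spectrum(c(110, 160), c(5, 2), 400)
  expect_equal(modified_cosine(a, b, allow_precursor_shift = FALSE),
               list(score = 0, matched = 0L))
  # hand calculation with sqrt-intensity weighting: 4 / (sqrt5 * sqrt5)
  a <- new_spectrum(c(100, 200), c(4, 1), 300)
  b <- new_spectrum(c(100, 300), c(4, 1), 300)
  res <- modified_cosine(a, b)
  expect_equal(res$score, 0.8, tolerance = 1e-12)
  expect_equal(res$matched, 1L)
})

test_that("modified cosine is symmetric, bounded, and matches the
           exhaustive-assignment oracle on random small spectra", {
  set.seed(401)
  for (i in 1:300) {
    pr <- random_spectrum_pair()
    got <- modified_cosine(pr$a, pr$b)
    rev <- modified_cosine(pr$b, pr$a)
    expect_gte(got$score, 0); expect_lte(got$score, 1)
    expect_equal(got$score, rev$score, tolerance = 1e-10)
    oracle <- modified_cosine_oracle(pr$a, pr$b)
    expect_equal(got$score, oracle$score, tolerance = 1e-10)
    expect_equal(got$matched, oracle$matched)
  }
})

test_that("network edges respect cutoff and matched-fragment rules", {
  # high cosine but only 3 matched fragments: no edge
  a <- new_spectrum(c(100, 150, 200), c(10, 10, 10), 400)
  b <- new_spectrum(c(100, 150, 200), c(10, 10, 10), 460)
  net <- build_network(list(a, b), preprocess = FALSE)
  expect_equal(nrow(net$edges), 0L)
  # sub-cutoff cosine with >= 4 matches: no edge either
  a <- new_spectrum(c(100, 150, 200, 250, 301, 351), rep(10, 6), 500)
  b <- new_spectrum(c(100, 150, 200, 250, 302.5, 352.5), rep(10, 6), 500)
  sc <- modified_cosine(a, b)$score
  expect_lt(sc, 0.7)
  expect_gte(modified_cosine(a, b)$matched, 4L)
  net <- build_network(list(a, b), preprocess = FALSE)
  expect_equal(nrow(net$edges), 0L)
  # and a compliant pair gets exactly one edge
  b2 <- new_spectrum(c(100, 150, 200, 250, 300), rep(10, 5), 500)
  a2 <- new_spectrum(c(100, 150, 200, 250, 300, 350), rep(10, 6), 500)
  net <- build_network(list(a2, b2), preprocess = FALSE)
  expect_equal(nrow(net$edges), 1L)
  expect_gte(net$edges$score, 0.7)
  expect_gte(net$edges$matched, 4L)
})

test_that("single-point quantitation is linear through the origin", {
  expect_equal(quantify_by_standard(10, 10, 1), 1)
  expect_equal(quantify_by_standard(0, 10, 1), 0)
  expect_equal(quantify_by_standard(5, 10, 1), 0.5)
  expect_error(quantify_by_standard(5, 0, 1), "positive")
})
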