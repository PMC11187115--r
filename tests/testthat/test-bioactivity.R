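test_that("reference space enforces rank bounds and shrinkage limits", {
  set.seed(201)
  # rank bound: 8 wells in 1000 dimensions can support at most k = 7
  x <- matrix(rnorm(8 * 1000), 8, 1000)
  sp <- fit_reference_space(x, k = 50)
  expect_lte(sp$k, 7L)
  # lambda = 1 gives an exactly diagonal covariance
  x <- matrix(rnorm(50 * 6), 50, 6)
  sp <- fit_reference_space(x, k = 4, lambda = 1)
  off <- sp$cov; diag(off) <- 0
  expect_equal(max(abs(off)), 0)
  # covariance stays symmetric positive definite
  sp <- fit_reference_space(x, k = 4, lambda = 0.1)
  expect_equal(sp$cov, t(sp$cov))
  expect_true(all(eigen(sp$cov, symmetric = TRUE)$values > 0))
  expect_error(fit_reference_space(x[1:3, ]), "at least 4")
})

test_that("held-out null distances follow a chi distribution at full rank", {
  set.seed(202)
  fit <- matrix(rnorm(4000 * 5), 4000, 5)
  sp <- fit_reference_space(fit, k = 5, lambda = 0)
  held <- matrix(rnorm(2000 * 5), 2000, 5)
  d <- mahalanobis_distance(held, sp)
  ks <- suppressWarnings(
    stats::ks.test(d, function(q) stats::pchisq(q^2, df = 5)))
  expect_gt(ks$p.value, 0.01)
})

test_that("Mahalanobis distances match closed forms", {
  sp <- structure(list(center = c(0, 0), basis = diag(2),
                       cov = diag(2), cov_inv = diag(2), k = 2L,
                       lambda = 0), class = "reduced_space")
  expect_equal(mahalanobis_distance(c(0, 0), sp), 0)
  expect_equal(mahalanobis_distance(c(1, 0), sp), 1)
  sp$cov <- diag(c(4, 1)); sp$cov_inv <- diag(c(0.25, 1))
  expect_equal(mahalanobis_distance(c(2, 0), sp), 1)
  expect_error(mahalanobis_distance(c(1, 2, 3), sp), "dimension")
})

test_that("distances are invariant under invertible linear maps at full rank", {
  set.seed(203)
  x <- matrix(rnorm(60 * 5), 60, 5)
  probe <- matrix(rnorm(10 * 5), 10, 5)
  a <- matrix(rnorm(25), 5, 5) + diag(5)
  d1 <- mahalanobis_distance(probe, fit_reference_space(x, k = 5, lambda = 0))
  d2 <- mahalanobis_distance(probe %*% t(a),
                             fit_reference_space(x %*% t(a), k = 5, lambda = 0))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("kernel null p-values match closed forms and quadrature", {
  # single null point: kernel symmetry puts p = 0.5 at the point itself
  nm1 <- structure(list(distances = 1, h = 0.7, q99 = NA), class = "null_model")
  expect_equal(p_value(nm1, 1), 0.5)
  # two-point mixture closed form
  nm2 <- structure(list(distances = c(0, 2), h = 1, q99 = NA),
                   class = "null_model")
  expect_equal(p_value(nm2, 2), (pnorm(-2) + pnorm(0)) / 2, tolerance = 1e-12)
  expect_equal(p_value(nm2, 2), 0.2614, tolerance = 1e-4)
  # quadrature oracle over random nulls
  set.seed(204)
  for (i in 1:100) {
    d0 <- runif(sample(4:12, 1), 0, 5)
    h <- runif(1, 0.1, 1)
    nm <- structure(list(distances = d0, h = h, q99 = NA),
                    class = "null_model")
    q <- runif(1, 0, 6)
    dens <- function(t) vapply(t, function(ti) mean(dnorm((ti - d0) / h) / h),
                               numeric(1))
    p_int <- integrate(dens, q, Inf, rel.tol = 1e-12)$value
    expect_equal(p_value(nm, q), p_int, tolerance = 1e-9)
  }
})

test_that("p-values are strictly decreasing and vanish in the far tail", {
  set.seed(205)
  nm <- fit_null(abs(rnorm(30, 3)))
  d <- seq(0, 8, by = 0.25)
  p <- p_value(nm, d)
  expect_true(all(diff(p) < 0))
  expect_true(all(diff(-log10(p)) > 0))
  expect_lt(p_value(nm, max(nm$distances) + 20 * nm$h), 1e-12)
  expect_gt(p_value(nm, 0), 0.5)  # all null points sit above 0
  expect_true(all(p > 0))
})

test_that("fitted nulls bracket the empirical tail and reject degenerate input", {
  set.seed(206)
  for (i in 1:30) {
    d <- abs(rnorm(sample(10:200, 1), mean = 3))
    nm <- fit_null(d)
    expect_gte(nm$q99, unname(quantile(d, 0.99)) - nm$h)
    expect_lte(nm$q99, max(d) + 5 * nm$h)
    expect_gte(nm$q99, median(d))
  }
  expect_error(fit_null(rep(2, 10)), "equal")
  expect_error(fit_null(c(1, 2)), "at least 4")
})

test_that("bioactivity calls apply both criteria with inclusive boundaries", {
  set.seed(207)
  nm <- fit_null(abs(rnorm(50, 3, 0.5)))
  low <- call_bioactivity(rep(nm$q99 * 0.5, 3), nm)
  expect_false(low$bioactive_by_p)
  expect_false(low$bioactive_by_distance)
  edge <- call_bioactivity(rep(2 * nm$q99, 3), nm)
  expect_true(edge$bioactive_by_distance)  # ">= 2X" is inclusive
  expect_equal(edge$distance, 2 * nm$q99)
  expect_equal(attr(edge, "well_distances"), rep(2 * nm$q99, 3))
  expect_error(call_bioactivity(numeric(0), nm), "at least one")
})

test_that("PCA embeddings are centered, uncorrelated, and separate clusters", {
  set.seed(208)
  # identical profiles project to the origin
  same <- matrix(1, 5, 4)
  expect_equal(max(abs(pca_embed(same))), 0)
  # orthonormal components are uncorrelated
  x <- matrix(rnorm(100 * 6), 100, 6)
  co <- pca_embed(x, 3)
  cors <- cor(co)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-10)
  # two well-separated clusters: silhouette on PC1-2 above 0.5
  y <- rbind(matrix(rnorm(30 * 6), 30, 6),
             matrix(rnorm(30 * 6, mean = 6), 30, 6))
  sil <- silhouette_oracle(as.matrix(pca_embed(y)), rep(1:2, each = 30))
  expect_gt(sil, 0.5)
  expect_error(pca_embed(x[1:2, ]), "at least 3")
})

test_that("reference classification scores margins and ties", {
  means <- rbind(classA = c(1, 0, 0), classB = c(0, 1, 0), classC = c(0, 0, 1))
  hit <- classify_reference(c(1, 0, 0), means)
  expect_equal(hit$label, "classA")
  expect_gt(hit$confidence, 0.95)
  expect_true(hit$unique_profile)
  tie <- classify_reference(c(1, 1, 0) / sqrt(2), means[1:2, ])
  expect_equal(tie$confidence, 0, tolerance = 1e-12)
  expect_false(tie$unique_profile)
  # threshold is applied to the margin
  margin03 <- classify_reference(c(1, 0.5, 0), means)
  expect_equal(margin03$unique_profile, margin03$confidence > 0.1)
  expect_error(classify_reference(c(1, 0), means[1, , drop = FALSE]),
               "at least 2")
})

test_that("detection rate is non-decreasing in effect size", {
  rates <- vapply(c(0.5, 1, 2, 4), function(delta) {
    cfg <- screen_config(n_cell_lines = 1, n_dmso_wells = 16,
                         n_compounds = 20, n_compound_wells = 1,
                         cells_per_well_mean = 150, n_features = 30,
                         affected_feature_fraction = 0.1,
                         effect_size_delta = delta, active_lines = 1,
                         seed = 209)
    res <- run_screen_pipeline(cfg)
    mean(res$calls$bioactive_by_p)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[4], 1)  # a 4 SD shift is always caught
})
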