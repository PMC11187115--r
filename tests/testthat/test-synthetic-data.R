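test_that("equal seeds give identical outputs from every generator", {
  cfg <- screen_config(n_cell_lines = 2, n_dmso_wells = 4,
                       cells_per_well_mean = 50, n_features = 5, seed = 9)
  expect_identical(gen_screen(cfg), gen_screen(cfg))
  expect_identical(gen_ca_trace(1, 5, seed = 9), gen_ca_trace(1, 5, seed = 9))
  expect_identical(gen_spectra("C20H30O5", seed = 9),
                   gen_spectra("C20H30O5", seed = 9))
  expect_identical(gen_fraction_plate(c(5, 8), seed = 9),
                   gen_fraction_plate(c(5, 8), seed = 9))
  # and a different seed changes the data
  expect_false(identical(gen_ca_trace(1, 5, seed = 9),
                         gen_ca_trace(1, 5, seed = 10)))
})

test_that("screen generator obeys its configuration contract", {
  expect_error(screen_config(n_dmso_wells = 3), "n_dmso_wells")
  expect_error(screen_config(cells_per_well_mean = -5), "positive")
  expect_error(screen_config(n_features = 1), "n_features")
  expect_error(screen_config(n_features = 5, affected_feature_fraction = 0.01,
                             effect_size_delta = 1), "affected")
  cfg <- screen_config(n_cell_lines = 9, n_dmso_wells = 4,
                       cells_per_well_mean = 30, n_features = 10,
                       effect_size_delta = 2, active_lines = c(1, 2, 4, 5, 7, 9),
                       seed = 10)
  sim <- gen_screen(cfg)
  # ground truth lists exactly the 6 active (compound, line) pairs
  expect_equal(sum(sim$truth$active$active), 6L)
  expect_equal(nrow(sim$truth$active), 9L)
  # every generated well appears with >= 10 cells (truncated Poisson)
  counts <- table(sim$table$well)
  expect_true(all(counts >= 10))
  expect_equal(length(counts), 9L * (4L + 3L))
  expect_equal(length(sim$truth$affected_features), 1L)  # 10% of 10 features
})

test_that("a zero effect size leaves compound wells exchangeable with DMSO", {
  cfg <- screen_config(n_cell_lines = 1, n_dmso_wells = 6,
                       cells_per_well_mean = 500, n_features = 20,
                       effect_size_delta = 0, seed = 11)
  sim <- gen_screen(cfg)
  prof <- plate_profiles(sim$table)
  cmpd <- prof$profiles[prof$wells$role == "compound", , drop = FALSE]
  expect_lt(median(abs(cmpd)), 0.1)
})

test_that("trace generator matches the recording geometry", {
  g <- gen_ca_trace(1.0, 5, duration_s = 20, rate_hz = 30, seed = 12)
  expect_equal(length(g$trace$intensity), 600L)
  expect_gte(g$truth$n_transients, 19L)
  expect_lte(g$truth$n_transients, 21L)
  # amplitude 0: drift + noise only, no detectable transients downstream
  g0 <- gen_ca_trace(1.0, 0, seed = 13)
  expect_equal(transient_metrics(g0$trace)$n_peaks, 0L)
  expect_equal(g0$truth$amplitude, 0)
  expect_error(gen_ca_trace(10, 5, rate_hz = 30), "rate_hz / 4")
})

test_that("spectrum generator encodes formulas, families, and SO3 losses", {
  g <- gen_spectra(c("C15H22O8S", "C20H30O5", "C20H32O5"),
                   families = c(1, 2, 2), seed = 14)
  expect_true(g$truth$table$has_so3_loss[1])
  expect_false(any(g$truth$table$has_so3_loss[-1]))
  s1 <- g$spectra[[1]]
  ann <- annotate_neutral_losses(c(s1$precursor_mz, s1$mz),
                                 tolerance_da = 0.02)
  expect_true("SO3" %in% ann$loss)
  # precursors are consistent with formula + adduct
  expect_equal(g$truth$table$precursor_mz[2], adduct_mz("C20H30O5", "[M+H]+"),
               tolerance = 1e-6)
  # same-family spectra share enough fragments to link in a network
  link <- modified_cosine(preprocess_spectrum(g$spectra[[2]]),
                          preprocess_spectrum(g$spectra[[3]]))
  expect_gte(link$matched, 4L)
  # duplicated spectra are perfectly similar
  expect_equal(modified_cosine(s1, s1)$score, 1, tolerance = 1e-12)
  # halogen ground-truth patterns are recoverable
  gh <- gen_spectra("C29H40BrClO9", seed = 15)
  expect_equal(infer_halogens(gh$truth$patterns[[1]]),
               c(n_Cl = 1L, n_Br = 1L))
})

test_that("fraction plate generator hits its inhibition targets", {
  flat <- gen_fraction_plate(active_window = c(20, 24), strength = 0, seed = 16)
  im <- score_fraction_plate(flat$plate)
  expect_lt(max(im$inhibition_pct), 10)
  hot <- gen_fraction_plate(active_window = c(22, 25), strength = 1, seed = 17)
  im <- score_fraction_plate(hot$plate)
  inside <- im$fraction %in% 22:25
  expect_true(all(im$inhibition_pct[inside] > 95))
  expect_true(all(im$inhibition_pct[!inside] < 10))
  # fractions 22-25 map to 7.05-8.05 min under the collection schedule
  win <- map_active_fractions(im)
  expect_equal(win$rt_start_min, 7.05)
  expect_equal(win$rt_end_min, 8.05)
  expect_error(gen_fraction_plate(active_window = c(0, 5)), "within")
  expect_error(gen_fraction_plate(active_window = c(70, 85)), "within")
})

test_that("an inactive screen produces at most one distance-criterion call", {
  cfg <- screen_config(n_cell_lines = 1, n_dmso_wells = 16,
                       n_compounds = 200, n_compound_wells = 1,
                       cells_per_well_mean = 150, n_features = 30,
                       effect_size_delta = 0, seed = 18)
  res <- run_screen_pipeline(cfg)
  expect_lte(sum(res$calls$bioactive_by_distance), 1L)
})
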