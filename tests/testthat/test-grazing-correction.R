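test_that("Frost log-ratio rate matches hand values and is antisymmetric", {
  expect_equal(frost_raw_rate(1000, 1000, t = 1, Z = 10), 0)
  expect_equal(frost_raw_rate(1000, 500, t = 1, Z = 10), log(2) / 10,
               tolerance = 1e-12)
  expect_equal(frost_raw_rate(500, 1000, t = 1, Z = 10), -log(2) / 10,
               tolerance = 1e-12)
  # antisymmetry under control/treatment swap
  set.seed(5)
  for (i in 1:20) {
    cc <- stats::runif(2, 10, 5000)
    expect_equal(frost_raw_rate(cc[1], cc[2], 1.5, 3),
                 -frost_raw_rate(cc[2], cc[1], 1.5, 3),
                 tolerance = 1e-12)
  }
  expect_equal(community_raw_rate(1000, 500, t = 2), log(2) / 2,
               tolerance = 1e-12)
  expect_error(frost_raw_rate(1000, 500, t = 0, Z = 10), "duration")
  expect_error(frost_raw_rate(1000, 500, t = 1, Z = 0), "positive")
  expect_error(frost_raw_rate(-1, 500, t = 1, Z = 1), "positive")
})

test_that("Level-2 background subtraction behaves as a pure shift", {
  expect_equal(level2_adjust(0.1, 0.6, 0.6), 0.1)
  expect_equal(level2_adjust(0.05, 0.8, 0.5), 0.35, tolerance = 1e-12)
  expect_equal(level2_adjust(-0.02, 0.6, 0.1), 0.48, tolerance = 1e-12)
})

test_that("TC compensation is bounded, monotone and saturating", {
  d <- cascade_drivers(alpha = 0.3, CI = 0.5, B_meso = 2)
  expect_equal(tc_compensation(0.8, d), 0.8 * (1 - exp(-0.3)),
               tolerance = 1e-12)
  expect_equal(tc_compensation(0.8, cascade_drivers(0.3, 0.5, 0)), 0)
  # saturation limit
  expect_equal(tc_compensation(0.8, cascade_drivers(50, 1, 1)), 0.8,
               tolerance = 1e-10)
  # bounds and monotonicity over random driver grids
  set.seed(17)
  for (i in 1:40) {
    g <- stats::runif(1, 0, 2)
    a <- stats::runif(1, 0, 2); ci <- stats::runif(1); b <- stats::runif(1, 0, 5)
    tc <- tc_compensation(g, cascade_drivers(a, ci, b))
    expect_gte(tc, 0)
    expect_lte(tc, g)
    expect_gte(tc_compensation(g, cascade_drivers(a * 1.3, ci, b)), tc)
    expect_gte(tc_compensation(g, cascade_drivers(a, min(1, ci * 1.3), b)), tc)
    expect_gte(tc_compensation(g, cascade_drivers(a, ci, b * 1.3)), tc)
  }
  expect_error(cascade_drivers(-0.1, 0.5, 1), "alpha")
  expect_error(cascade_drivers(0.3, 1.5, 1), "CI")
})

test_that("Level-3 adjustment is the exact TC shift", {
  expect_equal(level3_adjust(0.0693, 0.20735), 0.27665, tolerance = 1e-12)
  expect_equal(level3_adjust(-0.05, 0.30), 0.25, tolerance = 1e-12)
  expect_identical(level3_adjust(0.12, 0), 0.12)
})

test_that("workflow reproduces the substitution oracle", {
  ex <- grazing_experiment(
    C_control_initial = 1000, C_control_final = 900,
    C_treatment_initial = 1000, C_treatment_final = 950,
    t = 1, Z = 10,
    M_control_mean = 10, M_treatment_mean = 4,
    P_control_mean = 1093, P_treatment_mean = 1500)
  est <- estimate_cascade_workflow(ex, ciliate_fr())
  expect_equal(est$g_micro_control, 10 * 38 / 2186, tolerance = 1e-6)
  expect_equal(est$g_micro_treatment, 4 * 38 / 2593, tolerance = 1e-6)
  expect_equal(est$TC, 10 * 38 / 2186 - 4 * 38 / 2593, tolerance = 1e-6)
  expect_equal(est$g_raw, log(900 / 950), tolerance = 1e-12)
  expect_equal(est$g_raw_per_grazer, log(900 / 950) / 10,
               tolerance = 1e-12)
  # identity g_level3 - g_raw = TC, and Level-2 consistency
  expect_equal(est$g_level3 - est$g_raw, est$TC, tolerance = 1e-12)
  expect_equal(est$g_level2, est$g_raw + est$TC, tolerance = 1e-12)
})

test_that("workflow with identical bottles yields a null cascade", {
  ex <- grazing_experiment(1000, 1100, 1000, 1100, t = 1, Z = 5,
                           M_control_mean = 8, M_treatment_mean = 8)
  est <- estimate_cascade_workflow(ex, ciliate_fr())
  expect_equal(est$TC, 0)
  expect_equal(est$g_level3, est$g_raw)
  expect_false(est$inverse_cascade)
})

test_that("inverse cascades are reported, not clamped", {
  ex <- grazing_experiment(1000, 900, 1000, 950, t = 1, Z = 5,
                           M_control_mean = 4, M_treatment_mean = 10,
                           P_control_mean = 1093, P_treatment_mean = 1093)
  est <- estimate_cascade_workflow(ex, ciliate_fr())
  expect_lt(est$TC, 0)
  expect_true(est$inverse_cascade)
})

test_that("workflow TC inverts to the Level-3 driver model", {
  # construct means so the two-factor model is exact, then check that the
  # alpha implied by 1 - TC/g = exp(-alpha CI B) reproduces TC through
  # tc_compensation (round-trip identity)
  p <- ciliate_fr()
  ex <- grazing_experiment(2000, 1800, 2000, 1900, t = 1, Z = 2,
                           M_control_mean = 12, M_treatment_mean = 5,
                           P_control_mean = 1500, P_treatment_mean = 1600)
  est <- estimate_cascade_workflow(ex, p)
  CI <- 0.6; B <- 2
  alpha_implied <- -log(1 - est$TC / est$g_micro_control) / (CI * B)
  tc_back <- tc_compensation(est$g_micro_control,
                             cascade_drivers(alpha_implied, CI, B))
  expect_equal(tc_back, est$TC, tolerance = 1e-10)
})

test_that("workflow rejects unit mismatches", {
  ex <- grazing_experiment(1000, 900, 1000, 950, t = 1, Z = 5,
                           M_control_mean = 10, M_treatment_mean = 4,
                           units = "mgC_per_L")
  expect_error(estimate_cascade_workflow(ex, ciliate_fr()),
               "units mismatch")
})

test_that("experiment constructor fills geometric-mean standing stocks", {
  ex <- grazing_experiment(1000, 1600, 900, 1100, t = 1, Z = 1,
                           M_control_mean = 5, M_treatment_mean = 5)
  expect_equal(ex$P_control_mean, sqrt(1000 * 1600), tolerance = 1e-12)
  expect_equal(ex$P_treatment_mean, sqrt(900 * 1100), tolerance = 1e-12)
})
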