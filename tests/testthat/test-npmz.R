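test_that("NPMZ derivatives conserve total mass identically", {
  # all-zero state has zero rates
  expect_equal(unname(npmz_derivatives(npmz_state(0, 0, 0, 0),
                                       midpoint_params())),
               rep(0, 4))
  # componentwise sum is zero at 100 random admissible states/params,
  # in both literal and guarded modes
  set.seed(101)
  for (i in 1:100) {
    p <- suppressWarnings(random_npmz_params())
    s <- random_npmz_state()
    expect_lt(abs(sum(npmz_derivatives(s, p))), 1e-12)
    expect_lt(abs(sum(npmz_derivatives(s, p, guard = TRUE))), 1e-12)
  }
})

test_that("NPMZ derivatives match a hand computation", {
  p <- suppressWarnings(npmz_params(rmax = 1, kN = 0.5, lPN = 0.1,
                                    gM = 0.9, gZ = 0.3, GZ = 0.7))
  d <- npmz_derivatives(npmz_state(N = 1, P = 1, M = 0, Z = 0), p)
  expect_equal(unname(d[["P"]]), 1 / 1.5 - 0.1, tolerance = 1e-12)
  expect_equal(unname(d[["M"]]), 0)
  expect_equal(unname(d[["Z"]]), 0)
})

test_that("integration conserves mass and keeps extinct pools extinct", {
  tr <- npmz_integrate(benchmark_state(), midpoint_params(), t_end = 30)
  expect_lt(attr(tr, "max_drift"), 1e-8)
  # Z(0) = 0 stays 0 (invariant subspace), as do M and Z jointly
  tr0 <- npmz_integrate(npmz_state(1, 0.5, 0.1, 0), midpoint_params(),
                        t_end = 10)
  expect_true(all(tr0$Z == 0))
  expect_lt(attr(tr0, "max_drift"), 1e-8)
  trm <- npmz_integrate(npmz_state(1, 0.5, 0, 0), midpoint_params(),
                        t_end = 10)
  expect_true(all(trm$M == 0) && all(trm$Z == 0))
})

test_that("adaptive integration agrees with the fixed-step RK4 reference", {
  fin <- unlist(npmz_integrate(benchmark_state(), midpoint_params(),
                               t_end = 30)[301, c("N", "P", "M", "Z")])
  ref <- npmz_rk4_reference(benchmark_state(), midpoint_params(),
                            t_end = 30, dt = 1e-3)
  expect_lt(max(abs(fin - ref)) / max(abs(ref)), 1e-5)
})

test_that("parameter-range guard warns without clamping", {
  expect_warning(p <- npmz_params(rmax = 3), "rmax")
  expect_equal(p$rmax, 3)
  expect_error(npmz_params(gammaZ = 1.5), "\\[0, 1\\]")
  expect_error(npmz_params(gM = -0.2), "non-negative")
})

test_that("equilibrium finder certifies residuals and classifies roots", {
  p <- midpoint_params()
  # extinction state: exact trivial equilibrium at any N
  eq0 <- find_equilibrium(p, c(1.65, 0, 0, 0))
  expect_true(eq0$converged)
  expect_true(eq0$trivial)
  expect_lt(eq0$residual_norm, 1e-12)
  # long integration converges to a fixed point the root-finder confirms
  tr <- npmz_integrate(benchmark_state(), p, t_end = 400, output_dt = 1)
  fin <- unlist(tr[nrow(tr), c("N", "P", "M", "Z")])
  eq <- find_equilibrium(p, fin)
  expect_true(eq$converged)
  expect_lt(eq$residual_norm, 1e-10)
  expect_lt(max(abs(eq$state - fin)), 1e-6)
})

test_that("cascade intensity has the expected structure and direction", {
  proto <- cascade_protocol()
  base <- cascade_intensity(midpoint_params(), proto)
  expect_gt(base$intensity, 0)      # mesozooplankton release phytoplankton
  expect_gt(base$P_mean_withoutZ, 0)
  # inert mesozooplankton (gZ = GZ = 0): metric near 0 (the residual is
  # the nutrient-timing transient of remineralising the initial Z pool,
  # an order of magnitude below the active-cascade metric)
  inert <- suppressWarnings(npmz_params(gZ = 0, GZ = 0))
  expect_lt(abs(cascade_intensity(inert, proto)$intensity),
            0.1 * base$intensity)
  # pure cascade pathway (GZ > 0, gZ = 0) releases phytoplankton
  pure <- suppressWarnings(npmz_params(gZ = 0))
  expect_gt(cascade_intensity(pure, proto)$intensity, 0)
  # increasing in GZ near the midpoint (finite-difference sign check)
  up <- suppressWarnings(npmz_params(GZ = 0.7 * 1.05))
  dn <- suppressWarnings(npmz_params(GZ = 0.7 * 0.95))
  expect_gt(cascade_intensity(up, proto)$intensity,
            cascade_intensity(dn, proto)$intensity)
  # continuity in GZ: shrinking perturbations shrink the response
  d1 <- abs(cascade_intensity(
    suppressWarnings(npmz_params(GZ = 0.72)), proto)$intensity -
    base$intensity)
  d2 <- abs(cascade_intensity(
    suppressWarnings(npmz_params(GZ = 0.702)), proto)$intensity -
    base$intensity)
  expect_lt(d2, d1)
})

test_that("sensitivity analysis ranks all ten parameters", {
  sens <- sensitivity_analysis(midpoint_params())
  expect_setequal(sens$parameter,
                  c("rmax", "kN", "gM", "gZ", "GZ", "gammaM", "gammaZ",
                    "lPN", "lMN", "lZN"))
  expect_equal(nrow(sens), 10)
  expect_setequal(sens$rank, 1:10)
  # predation on microzooplankton promotes phytoplankton: S_GZ > 0
  expect_gt(sens$sensitivity[sens$parameter == "GZ"], 0)
})

test_that("parameters with no pathway to the metric have zero sensitivity", {
  # with gM = 0, microzooplankton never feed, so their assimilated
  # fraction gammaM cannot influence the metric
  p <- suppressWarnings(npmz_params(gM = 0))
  sens <- sensitivity_analysis(p)
  expect_equal(sens$sensitivity[sens$parameter == "gammaM"], 0,
               tolerance = 1e-10)
})

test_that("warming scenario reports the GZ band and a positive response", {
  ws <- warming_scenario(midpoint_params(), delta_T = 2)
  expect_equal(ws$delta_GZ, 0.175, tolerance = 1e-12)
  expect_gte(ws$delta_GZ, 0.15)
  expect_lte(ws$delta_GZ, 0.20)
  expect_gt(ws$percent_change, 0)
  # null scenario
  ws0 <- warming_scenario(midpoint_params(), delta_T = 0)
  expect_equal(ws0$percent_change, 0, tolerance = 1e-9)
})
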