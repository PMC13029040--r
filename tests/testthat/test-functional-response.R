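test_that("Michaelis-Menten ingestion obeys its closed-form identities", {
  p <- ciliate_fr()
  expect_identical(mm_ingestion(0, p), 0)
  # half-saturation identity I(kd) = Imax/2, for arbitrary valid params
  set.seed(11)
  for (i in 1:25) {
    q <- fr_params(stats::runif(1, 0.1, 100), stats::runif(1, 1, 5000))
    expect_equal(mm_ingestion(q$kd, q), q$Imax / 2, tolerance = 1e-12)
  }
  # direct substitutions
  expect_equal(mm_ingestion(1093, p), 19)
  expect_equal(mm_ingestion(10 * 1093, p), 38 * 10 / 11,
               tolerance = 1e-12)
})

test_that("ingestion is monotone in prey and bounded by Imax", {
  set.seed(21)
  for (i in 1:10) {
    q <- fr_params(stats::runif(1, 1, 60), stats::runif(1, 100, 4000))
    x <- sort(stats::runif(50, 0, 1e5))
    I <- mm_ingestion(x, q)
    expect_true(all(diff(I) >= 0))
    expect_true(all(I <= q$Imax))
  }
})

test_that("invalid functional-response inputs are rejected", {
  expect_error(fr_params(-1, 100), "Imax")
  expect_error(fr_params(38, 0), "kd")
  expect_error(mm_ingestion(-5, ciliate_fr()), "non-negative")
  expect_error(two_factor_grazing(-1, 2, ciliate_fr()), "x")
  expect_error(two_factor_grazing(1, -2, ciliate_fr()), "y")
})

test_that("noiseless Michaelis-Menten fit recovers generating parameters", {
  p <- ciliate_fr()
  x <- seq(50, 6000, length.out = 12)
  fit <- fit_michaelis_menten(x, mm_ingestion(x, p))
  expect_true(fit$converged)
  expect_equal(fit$params$Imax, 38, tolerance = 1e-6)
  expect_equal(fit$params$kd, 1093, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # identity fit over random parameter draws
  set.seed(31)
  for (i in 1:10) {
    q <- fr_params(stats::runif(1, 5, 80), stats::runif(1, 200, 3000))
    xs <- seq(q$kd / 20, 6 * q$kd, length.out = 10)
    f2 <- fit_michaelis_menten(xs, mm_ingestion(xs, q))
    expect_equal(f2$params$Imax, q$Imax, tolerance = 1e-6)
    expect_equal(f2$params$kd, q$kd, tolerance = 1e-6)
  }
})

test_that("noisy fit recovers parameters to within 10%", {
  d <- generate_fr_data(ciliate_fr(), seq(50, 6000, length.out = 12),
                        noise_cv = 0.05, seed = 20260901)
  fit <- fit_michaelis_menten(d$prey_conc, d$ingestion_rate)
  expect_lt(abs(fit$params$Imax - 38) / 38, 0.10)
  expect_lt(abs(fit$params$kd - 1093) / 1093, 0.10)
})

test_that("degenerate fitting inputs raise informative errors", {
  expect_error(fit_michaelis_menten(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_michaelis_menten(rep(100, 5), 1:5), "distinct")
  expect_error(fit_michaelis_menten(1:10, rep(3, 10)), "unidentifiable")
})

test_that("two-factor grazing matches its algebraic composition", {
  p <- ciliate_fr()
  expect_identical(two_factor_grazing(500, 0, p), 0)
  expect_equal(two_factor_grazing(1093, 10, p), 10 * 38 / 2186,
               tolerance = 1e-12)
  # g(x,y) == ingestion -> community-rate composition on a grid
  grid <- expand.grid(x = c(10, 200, 1093, 4000), y = c(0.5, 2, 10, 40))
  comp <- ingestion_to_community_grazing(mm_ingestion(grid$x, p),
                                         grid$y, grid$x)
  expect_equal(two_factor_grazing(grid$x, grid$y, p), comp,
               tolerance = 1e-12)
  # round trip via clearance
  FF <- mm_ingestion(grid$x, p) / grid$x
  expect_equal(FF * grid$y, comp, tolerance = 1e-12)
  expect_equal(mm_clearance(grid$x, p) * grid$y, comp, tolerance = 1e-12)
})

test_that("ingestion-to-community conversion validates its domain", {
  expect_identical(ingestion_to_community_grazing(19, 0, 1093), 0)
  expect_equal(ingestion_to_community_grazing(19, 10, 1093),
               19 * 10 / 1093, tolerance = 1e-12)
  expect_error(ingestion_to_community_grazing(19, 10, 0), "P_mean")
})

test_that("dilution regression recovers exact and noisy lines", {
  d <- c(0.2, 0.4, 0.6, 0.8, 1)
  fit <- dilution_regression(d, 1.2 - 0.8 * d)
  expect_equal(fit$mu, 1.2, tolerance = 1e-12)
  expect_equal(fit$g, 0.8, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$clamped)

  flat <- dilution_regression(d, rep(0.5, 5))
  expect_equal(flat$mu, 0.5, tolerance = 1e-12)
  expect_equal(flat$g, 0, tolerance = 1e-12)

  ser <- generate_dilution_series(1.2, 0.8, d, noise_sd = 0.05,
                                  seed = 314)
  nf <- dilution_regression(ser$fraction, ser$apparent_growth)
  expect_lt(abs(nf$mu - 1.2), 2 * nf$se_mu)
  expect_lt(abs(nf$g - 0.8), 2 * nf$se_slope)
})

test_that("dilution regression flags anomalies and bad input", {
  expect_warning(fit <- dilution_regression(c(0.2, 0.5, 1),
                                            c(0.1, 0.3, 0.5)),
                 "clamped")
  expect_identical(fit$g, 0)
  expect_true(fit$clamped)
  expect_error(dilution_regression(c(0.5, 1), c(1, 2)), "at least 3")
  expect_error(dilution_regression(rep(0.5, 4), 1:4), "identical")
  expect_error(dilution_regression(c(0, 0.5, 1), c(1, 2, 3)), "\\(0, 1\\]")
})
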