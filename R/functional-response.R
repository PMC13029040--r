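#' Michaelis-Menten functional-response parameters
#'
#' Container for the two parameters of the saturating ingestion curve
#' \eqn{I(x) = I_{max} x / (k_d + x)}: the maximum per-capita ingestion rate
#' and the half-saturation prey concentration.
#'
#' @param Imax Maximum per-capita ingestion rate (prey cells grazer^-1 d^-1).
#'   Must be > 0.
#' @param kd Half-saturation prey concentration, i.e. the prey concentration
#'   at which ingestion reaches \code{Imax / 2}. Same units as the prey
#'   concentrations it will be evaluated at. Must be > 0.
#' @param units Character label for the prey-concentration units (default
#'   \code{"cells_per_mL"}). Carried with the object and checked against the
#'   units of any dataset the parameters are applied to; no silent conversion
#'   is ever performed.
#'
#' @return An object of class \code{"fr_params"}: a list with elements
#'   \code{Imax}, \code{kd} and \code{units}.
#' @examples
#' p <- fr_params(Imax = 38, kd = 1093)
#' mm_ingestion(1093, p)  # half saturation: 19
#' @export
fr_params <- function(Imax, kd, units = "cells_per_mL") {
  stopifnot(is.numeric(Imax), length(Imax) == 1L,
            is.numeric(kd), length(kd) == 1L)
  if (!is.finite(Imax) || Imax <= 0)
    stop("`Imax` must be a finite positive number, got ", Imax)
  if (!is.finite(kd) || kd <= 0)
    stop("`kd` must be a finite positive number, got ", kd)
  structure(list(Imax = as.numeric(Imax), kd = as.numeric(kd),
                 units = units),
            class = "fr_params")
}

#' @export
print.fr_params <- function(x, ...) {
  cat("Michaelis-Menten functional response\n")
  cat(sprintf("  Imax = %.6g  (prey grazer^-1 d^-1)\n", x$Imax))
  cat(sprintf("  kd   = %.6g  (%s)\n", x$kd, x$units))
  invisible(x)
}

check_fr_params <- function(params) {
  if (!inherits(params, "fr_params"))
    stop("`params` must be an `fr_params` object (see `fr_params()`)")
  params
}

#' Michaelis-Menten per-capita ingestion rate
#'
#' Evaluates the saturating functional response
#' \eqn{I(x) = I_{max} x / (k_d + x)}: ingestion rises near-linearly at low
#' prey concentration and saturates at \code{Imax} when prey is abundant.
#'
#' @param x Prey concentration(s), same units as \code{params$kd}. Must be
#'   non-negative.
#' @param params An [fr_params] object.
#' @return Per-capita ingestion rate(s), bounded above by \code{Imax}.
#' @examples
#' p <- fr_params(38, 1093)
#' mm_ingestion(c(0, 1093, 10930), p)
#' @export
mm_ingestion <- function(x, params) {
  params <- check_fr_params(params)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be finite numeric prey concentration(s)")
  if (any(x < 0))
    stop("prey concentration `x` must be non-negative")
  params$Imax * x / (params$kd + x)
}

#' Per-capita clearance rate implied by the functional response
#'
#' Clearance (volume swept clear per grazer per day) is ingestion divided by
#' prey concentration, \eqn{F = I / x = I_{max} / (k_d + x)}.
#'
#' @inheritParams mm_ingestion
#' @return Clearance rate(s) (mL grazer^-1 d^-1 for prey in cells mL^-1).
#' @export
mm_clearance <- function(x, params) {
  params <- check_fr_params(params)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("`x` must be finite non-negative prey concentration(s)")
  params$Imax / (params$kd + x)
}

#' Fit the Michaelis-Menten functional response by nonlinear least squares
#'
#' Estimates \code{Imax} and \code{kd} from paired observations of prey
#' concentration and per-capita ingestion rate, using Levenberg-Marquardt
#' nonlinear least squares with both parameters bounded below by zero.
#'
#' The default start values are deterministic: \code{Imax0} is the largest
#' observed ingestion rate and \code{kd0} is the observed prey concentration
#' whose ingestion rate is closest to \code{Imax0 / 2}.
#'
#' @param prey_conc Numeric vector of prey concentrations (>= 0).
#' @param ingestion_rate Numeric vector of per-capita ingestion rates (>= 0),
#'   same length.
#' @param weights Either \code{"none"} (default, unweighted) or
#'   \code{"inverse"} for 1/I weights (observations with I = 0 get zero
#'   weight under \code{"inverse"}).
#' @param units Prey-concentration units label attached to the fitted
#'   parameters.
#' @return An object of class \code{"fr_fit"}: a list with \code{params}
#'   (an [fr_params]), \code{rss} (residual sum of squares),
#'   \code{converged} (logical), \code{fitted}, \code{residuals} and
#'   \code{n}.
#' @examples
#' p <- fr_params(38, 1093)
#' x <- seq(50, 6000, length.out = 12)
#' fit <- fit_michaelis_menten(x, mm_ingestion(x, p))
#' fit$params
#' @export
fit_michaelis_menten <- function(prey_conc, ingestion_rate,
                                 weights = c("none", "inverse"),
                                 units = "cells_per_mL") {
  weights <- match.arg(weights)
  x <- as.numeric(prey_conc)
  I <- as.numeric(ingestion_rate)
  if (length(x) != length(I))
    stop("`prey_conc` and `ingestion_rate` must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(I)))
    stop("observations must be finite")
  if (any(x < 0) || any(I < 0))
    stop("prey concentrations and ingestion rates must be non-negative")
  if (length(x) < 3L)
    stop("need at least 3 observations to fit the two-parameter model, got ",
         length(x))
  if (length(unique(x)) < 2L)
    stop("need at least 2 distinct prey concentrations; ",
         "all observations are at x = ", x[1])
  if (diff(range(I)) == 0)
    stop("all ingestion rates are identical (", I[1],
         "): kd is unidentifiable from a flat response")

  Imax0 <- max(I)
  kd0 <- x[which.min(abs(I - Imax0 / 2))]
  if (kd0 <= 0) kd0 <- max(min(x[x > 0]), 1e-8)

  w <- switch(weights, none = rep(1, length(I)),
              inverse = ifelse(I > 0, 1 / I, 0))
  dat <- data.frame(x = x, I = I)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ Imax * x / (kd + x), data = dat,
                      start = list(Imax = Imax0, kd = kd0),
                      lower = c(Imax = 1e-12, kd = 1e-12),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("Michaelis-Menten fit failed: ", conditionMessage(fit))

  est <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged)
    warning("Michaelis-Menten fit did not report convergence; ",
            "estimates are returned flagged (converged = FALSE)")
  structure(list(
    params = fr_params(est[["Imax"]], est[["kd"]], units = units),
    rss = sum(stats::residuals(fit)^2),
    converged = converged,
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(stats::residuals(fit)),
    n = length(x)
  ), class = "fr_fit")
}

#' @export
print.fr_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  n = %d, RSS = %.6g, converged = %s\n",
              x$n, x$rss, x$converged))
  invisible(x)
}

#' Two-factor community grazing rate g(x, y)
#'
#' Community grazing rate of a microzooplankton population as a function of
#' mean prey concentration \code{x} and mean grazer concentration \code{y}:
#' \deqn{g(x, y) = y \, I_{max} / (k_d + x).}
#' This is the per-capita ingestion \eqn{I(x)} converted to a prey-specific
#' mortality by multiplying by grazer concentration and dividing by prey
#' concentration; the prey concentration cancels into the denominator.
#'
#' @param x Mean prey concentration (>= 0, units of \code{params$kd}).
#' @param y Mean grazer concentration (>= 0, grazers mL^-1).
#' @param params An [fr_params] object.
#' @return Community grazing rate (d^-1); linear in \code{y}, decreasing in
#'   \code{x}.
#' @examples
#' two_factor_grazing(1093, 10, fr_params(38, 1093))
#' @export
two_factor_grazing <- function(x, y, params) {
  params <- check_fr_params(params)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("prey concentration `x` must be finite and non-negative")
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0))
    stop("grazer concentration `y` must be finite and non-negative")
  y * params$Imax / (params$kd + x)
}

#' Convert per-capita ingestion to a community grazing rate
#'
#' \eqn{g_{micro} = M_{mean} I_{micro} / P_{mean}}: scales per-capita
#' ingestion by mean grazer concentration and normalises by mean prey
#' concentration to obtain a prey-specific mortality rate (d^-1).
#'
#' @param I_micro Per-capita ingestion rate (>= 0).
#' @param M_mean Mean grazer concentration (>= 0).
#' @param P_mean Mean prey concentration (> 0).
#' @return Community grazing rate (d^-1).
#' @export
ingestion_to_community_grazing <- function(I_micro, M_mean, P_mean) {
  if (any(!is.finite(P_mean)) || any(P_mean <= 0))
    stop("`P_mean` must be positive")
  if (any(I_micro < 0) || any(M_mean < 0))
    stop("`I_micro` and `M_mean` must be non-negative")
  M_mean * I_micro / P_mean
}

#' Dilution-method regression for growth and grazing rates
#'
#' Ordinary least-squares fit of the dilution-method linear model
#' \eqn{k = \mu - g d}, where \code{k} is the apparent (net) phytoplankton
#' growth rate observed at dilution fraction \code{d}. The intercept
#' estimates the intrinsic growth rate \eqn{\mu} and the negative slope the
#' microzooplankton grazing mortality \eqn{g}.
#'
#' A positive fitted slope (apparent growth increasing with dilution) would
#' imply negative grazing; since grazing mortality is non-negative by
#' definition, \code{g} is then reported as 0 with \code{clamped = TRUE} so
#' the anomaly stays diagnosable.
#'
#' @param fraction Dilution fractions, strictly in (0, 1]; at least 3, not
#'   all identical.
#' @param apparent_growth Net growth rates k (d^-1), same length.
#' @return An object of class \code{"dilution_fit"}: list with \code{mu},
#'   \code{g}, \code{r_squared}, \code{clamped}, \code{slope},
#'   \code{se_mu}, \code{se_slope} and \code{n}.
#' @examples
#' d <- c(0.2, 0.4, 0.6, 0.8, 1)
#' dilution_regression(d, 1.2 - 0.8 * d)
#' @export
dilution_regression <- function(fraction, apparent_growth) {
  d <- as.numeric(fraction)
  k <- as.numeric(apparent_growth)
  if (length(d) != length(k))
    stop("`fraction` and `apparent_growth` must have equal length")
  if (any(!is.finite(d)) || any(!is.finite(k)))
    stop("dilution series values must be finite")
  if (any(d <= 0 | d > 1))
    stop("dilution fractions must lie in (0, 1]")
  if (length(d) < 3L)
    stop("need at least 3 dilution levels for the regression, got ",
         length(d))
  if (length(unique(d)) < 2L)
    stop("all dilution fractions are identical (", d[1],
         "): slope is unidentifiable")

  fit <- stats::lm(k ~ d)
  co <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate here
  slope <- unname(co[2])
  g <- -slope
  clamped <- FALSE
  if (g < 0) {
    # distinguish a genuinely positive slope from round-off on flat data
    if (g < -1e-12 * max(1, abs(co[1]))) {
      warning("fitted slope is positive (apparent growth increases with ",
              "dilution); grazing rate clamped to 0")
      clamped <- TRUE
    }
    g <- 0
  }
  structure(list(
    mu = unname(co[1]),
    g = g,
    r_squared = sm$r.squared,
    clamped = clamped,
    slope = slope,
    se_mu = sm$coefficients[1, 2],
    se_slope = sm$coefficients[2, 2],
    n = length(d)
  ), class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat("Dilution-method regression (k = mu - g d)\n")
  cat(sprintf("  mu = %.6g d^-1 (SE %.3g)\n", x$mu, x$se_mu))
  cat(sprintf("  g  = %.6g d^-1%s\n", x$g,
              if (x$clamped) "  [clamped from negative]" else ""))
  cat(sprintf("  R^2 = %.4f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}
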