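#' NPMZ model parameters
#'
#' The ten rate parameters of the four-compartment
#' nutrient-phytoplankton-microzooplankton-mesozooplankton model. Defaults
#' are the midpoints of the published calibration ranges (rmax 0.5-2.0,
#' kN 0.1-1.0, gM 0.3-1.5, GZ 0.2-1.2, gamma 0.2-0.4, l 0.05-0.2); gZ, the
#' mesozooplankton direct grazing coefficient on phytoplankton, has no
#' published range and defaults to 0.3 d^-1 (modest herbivory relative to
#' microzooplankton grazing). Values outside the published ranges trigger a
#' warning, never silent clamping.
#'
#' @param rmax Maximum phytoplankton growth rate (d^-1).
#' @param kN Nutrient half-saturation constant (same currency as the N
#'   pool; see Details).
#' @param gM Microzooplankton grazing coefficient on phytoplankton (d^-1).
#' @param gZ Mesozooplankton grazing coefficient on phytoplankton (d^-1).
#' @param GZ Mesozooplankton grazing coefficient on microzooplankton
#'   (d^-1).
#' @param gammaM,gammaZ Non-assimilated fractions of prey for micro- and
#'   mesozooplankton, in \[0, 1\] (published range 0.2-0.4).
#' @param lPN,lMN,lZN Mortality/mineralisation rates of P, M and Z back to
#'   N (d^-1).
#'
#' @details All four pools are carried in a single carbon currency
#'   (mg C L^-1). The published kN range is printed in umol N L^-1; here kN
#'   is interpreted numerically in the N pool's currency, and any unit
#'   conversion is the caller's explicit responsibility — the model never
#'   converts silently.
#' @return An object of class \code{"npmz_params"} (a named list).
#' @export
npmz_params <- function(rmax = 1.25, kN = 0.55, gM = 0.9, gZ = 0.3,
                        GZ = 0.7, gammaM = 0.3, gammaZ = 0.3,
                        lPN = 0.125, lMN = 0.125, lZN = 0.125) {
  p <- list(rmax = rmax, kN = kN, gM = gM, gZ = gZ, GZ = GZ,
            gammaM = gammaM, gammaZ = gammaZ,
            lPN = lPN, lMN = lMN, lZN = lZN)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0,
    logical(1))]
  if (length(bad))
    stop("parameters must be finite non-negative scalars; invalid: ",
         paste(bad, collapse = ", "))
  if (gammaM > 1 || gammaZ > 1)
    stop("non-assimilated fractions gammaM/gammaZ must lie in [0, 1]")

  ranges <- list(rmax = c(0.5, 2), kN = c(0.1, 1), gM = c(0.3, 1.5),
                 GZ = c(0.2, 1.2), gammaM = c(0.2, 0.4),
                 gammaZ = c(0.2, 0.4), lPN = c(0.05, 0.2),
                 lMN = c(0.05, 0.2), lZN = c(0.05, 0.2))
  for (nm in names(ranges)) {
    v <- p[[nm]]
    r <- ranges[[nm]]
    if (v < r[1] || v > r[2])
      warning(sprintf("`%s` = %g lies outside the published range [%g, %g]",
                      nm, v, r[1], r[2]), call. = FALSE)
  }
  structure(p, class = "npmz_params")
}

#' @export
print.npmz_params <- function(x, ...) {
  cat("NPMZ parameters (d^-1 unless dimensionless):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' NPMZ state vector
#'
#' @param N,P,M,Z Pool sizes (mg C L^-1, >= 0) of dissolved nutrient,
#'   phytoplankton, microzooplankton and mesozooplankton.
#' @return A named numeric vector \code{c(N=, P=, M=, Z=)}.
#' @export
npmz_state <- function(N, P, M, Z) {
  s <- c(N = N, P = P, M = M, Z = Z)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all pools must be finite and non-negative")
  s
}

#' Right-hand side of the NPMZ equations
#'
#' Time-derivatives of the four pools (mg C L^-1 d^-1):
#' \deqn{dN/dt = -u + l_{PN} P + l_{MN} M + l_{ZN} Z
#'       + \gamma_M g_M M + \gamma_Z (g_Z + G_Z) Z}
#' \deqn{dP/dt = u - l_{PN} P - g_M M - g_Z Z}
#' \deqn{dM/dt = (1-\gamma_M) g_M M - l_{MN} M - G_Z Z}
#' \deqn{dZ/dt = (1-\gamma_Z)(g_Z + G_Z) Z - l_{ZN} Z}
#' with nutrient uptake \eqn{u = r_{max} N P / (k_N + N)}. Every flux
#' leaving one pool enters another (partitioned by the assimilated and
#' egested fractions), so the four derivatives sum to zero identically.
#'
#' The grazing losses \eqn{g_M M}, \eqn{g_Z Z} and \eqn{G_Z Z} are
#' proportional to grazer, not prey, biomass, so the literal form can drive
#' a prey pool negative. With \code{guard = TRUE} the state is first
#' floored at zero and each grazing flux is multiplied by a smooth
#' prey-availability factor \eqn{X/(X+\epsilon)} (\eqn{\epsilon} = 1e-4
#' mg C L^-1, far below any ecologically meaningful biomass yet large
#' enough to keep the extinction boundary layer non-stiff; X the prey
#' pool), which vanishes as the prey is exhausted. The factor scales donor
#' and recipient terms of each flux identically, so conservation holds in
#' both modes. The guard is off by default here (the literal equations)
#' and on by default in [npmz_integrate].
#'
#' @param state A state vector from [npmz_state].
#' @param params An [npmz_params] object.
#' @param guard Logical; apply the smooth prey-availability factor.
#' @param eps Guard scale (mg C L^-1).
#' @return Named numeric vector of derivatives \code{c(N=, P=, M=, Z=)}.
#' @examples
#' sum(npmz_derivatives(npmz_state(1, 0.5, 0.1, 0.05), npmz_params()))
#' @export
npmz_derivatives <- function(state, params, guard = FALSE, eps = 1e-4) {
  if (!inherits(params, "npmz_params"))
    stop("`params` must be an `npmz_params` object")
  if (length(state) != 4L || any(!is.finite(state)))
    stop("`state` must be four finite pool values (N, P, M, Z)")
  if (guard) state <- pmax(state, 0)
  N <- state[[1]]; P <- state[[2]]; M <- state[[3]]; Z <- state[[4]]
  phiP <- if (guard) P / (P + eps) else 1
  phiM <- if (guard) M / (M + eps) else 1

  uptake <- params$rmax * N * P / (params$kN + N)
  grazM  <- params$gM * M * phiP   # microzoo on phyto
  grazZP <- params$gZ * Z * phiP   # mesozoo on phyto
  grazZM <- params$GZ * Z * phiM   # mesozoo on microzoo

  dP <- uptake - params$lPN * P - grazM - grazZP
  dM <- (1 - params$gammaM) * grazM - params$lMN * M - grazZM
  dZ <- (1 - params$gammaZ) * (grazZP + grazZM) - params$lZN * Z
  dN <- -uptake + params$lPN * P + params$lMN * M + params$lZN * Z +
    params$gammaM * grazM + params$gammaZ * (grazZP + grazZM)
  c(N = dN, P = dP, M = dM, Z = dZ)
}

#' Integrate the NPMZ model
#'
#' Adaptive error-controlled integration (deSolve, lsoda) of the NPMZ
#' equations from an initial state. The prey-availability guard is on by
#' default so pools cannot be driven negative by the grazer-proportional
#' loss terms; tiny negative excursions from solver round-off are floored
#' at zero in the reported trajectory. Total mass is a conserved quantity
#' of the equations, and the realised relative drift over the run is
#' reported and checked against \code{drift_tol}.
#'
#' @param state0 Initial state from [npmz_state].
#' @param params An [npmz_params] object.
#' @param t_end Simulation end time (d, > 0).
#' @param output_dt Output time step (d, > 0).
#' @param guard Logical; smooth prey-availability factor (default TRUE).
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param drift_tol Maximum allowed relative total-mass drift (default
#'   1e-8); exceeding it is an error.
#' @param method deSolve integration method (default \code{"lsoda"}).
#' @return An object of class \code{"npmz_trajectory"}: a data.frame with
#'   columns \code{time, N, P, M, Z} and attributes \code{params},
#'   \code{guard}, \code{max_drift} (max relative total-mass deviation)
#'   and \code{solver_steps}.
#' @examples
#' tr <- npmz_integrate(npmz_state(1, 0.5, 0.1, 0.05), npmz_params(),
#'                      t_end = 5)
#' attr(tr, "max_drift")
#' @export
npmz_integrate <- function(state0, params, t_end = 30, output_dt = 0.1,
                           guard = TRUE, rtol = 1e-10, atol = 1e-12,
                           drift_tol = 1e-8, method = "lsoda") {
  if (!is.finite(t_end) || t_end <= 0) stop("`t_end` must be positive")
  if (!is.finite(output_dt) || output_dt <= 0)
    stop("`output_dt` must be positive")
  state0 <- npmz_state(state0[[1]], state0[[2]], state0[[3]], state0[[4]])
  times <- seq(0, t_end, by = output_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  rhs <- function(t, y, parms) {
    list(npmz_derivatives(y, parms, guard = guard))
  }
  sol <- deSolve::ode(y = state0, times = times, func = rhs,
                      parms = params, method = method,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed at t = ",
         sol[nrow(sol), "time"], "; last valid state: ",
         paste(sprintf("%s=%.6g", colnames(sol)[-1],
                       sol[nrow(sol), -1]), collapse = ", "))
  out <- as.data.frame(sol)
  # floor solver round-off excursions; magnitudes are below atol
  out[, c("N", "P", "M", "Z")] <-
    pmax(as.matrix(out[, c("N", "P", "M", "Z")]), 0)
  total <- rowSums(out[, c("N", "P", "M", "Z")])
  drift <- max(abs(total - total[1])) / total[1]
  if (drift > drift_tol)
    stop(sprintf("total-mass drift %.3g exceeds tolerance %.3g",
                 drift, drift_tol))
  structure(out, params = params, guard = guard, max_drift = drift,
            solver_steps = attr(sol, "istate")[3],
            class = c("npmz_trajectory", "data.frame"))
}

#' Fixed-step classical Runge-Kutta reference integration
#'
#' Independent 4th-order fixed-step integrator used as a cross-scheme
#' reference for the adaptive solver. Returns only the final state.
#'
#' @inheritParams npmz_integrate
#' @param dt Fixed step size (d).
#' @return Named numeric final state.
#' @export
npmz_rk4_reference <- function(state0, params, t_end = 30, dt = 1e-3,
                               guard = TRUE) {
  y <- npmz_state(state0[[1]], state0[[2]], state0[[3]], state0[[4]])
  n <- ceiling(t_end / dt)
  h <- t_end / n
  f <- function(y) npmz_derivatives(y, params, guard = guard)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

#' Locate an equilibrium of the NPMZ system
#'
#' Root-finding (Gauss-Newton via pracma) on the NPMZ right-hand side from
#' a starting guess. The returned report states whether the residual
#' criterion was met and whether the root is a trivial (extinction)
#' equilibrium with P, M and Z all effectively zero.
#'
#' @param params An [npmz_params] object.
#' @param guess Starting state (named or positional N, P, M, Z).
#' @param guard Passed to [npmz_derivatives].
#' @param tol Residual max-norm required for convergence (default 1e-10).
#' @return A list with \code{state}, \code{residual_norm},
#'   \code{converged} and \code{trivial} (all of P, M, Z below 1e-8).
#' @export
find_equilibrium <- function(params, guess, guard = TRUE, tol = 1e-10) {
  if (!inherits(params, "npmz_params"))
    stop("`params` must be an `npmz_params` object")
  x0 <- as.numeric(guess)
  if (length(x0) != 4L || any(!is.finite(x0)))
    stop("`guess` must be four finite pool values")
  fn <- function(x) unname(npmz_derivatives(
    c(N = x[1], P = x[2], M = x[3], Z = x[4]), params, guard = guard))
  res0 <- max(abs(fn(x0)))
  if (res0 <= tol) {
    root <- x0
  } else {
    sol <- tryCatch(pracma::fsolve(fn, x0, tol = .Machine$double.eps^0.75),
                    error = function(e) NULL)
    root <- if (is.null(sol)) x0 else sol$x
  }
  resid <- max(abs(fn(root)))
  state <- c(N = root[1], P = root[2], M = root[3], Z = root[4])
  list(state = state,
       residual_norm = resid,
       converged = resid <= tol,
       trivial = all(abs(state[c("P", "M", "Z")]) < 1e-8))
}

#' Default protocol for the cascade-intensity metric
#'
#' The default window (days 0-5) covers the bloom phase of the closed
#' batch system. The NPMZ grazing losses are proportional to grazer
#' biomass, so a closed run eventually drives phytoplankton extinct once
#' grazers have bloomed; averaging after that collapse would divide by a
#' near-zero baseline. Within the bloom window both the with- and
#' without-mesozooplankton runs retain positive phytoplankton biomass and
#' the relative-enhancement metric is well defined.
#'
#' @param state0 Initial state (default \code{(N, P, M, Z) =
#'   (1.0, 0.5, 0.1, 0.05)} mg C L^-1).
#' @param window Averaging window in days (default days 0-5).
#' @param output_dt Output step for the time average (d).
#' @return A list used by [cascade_intensity].
#' @export
cascade_protocol <- function(state0 = npmz_state(1.0, 0.5, 0.1, 0.05),
                             window = c(0, 5), output_dt = 0.1) {
  if (length(window) != 2L || window[1] < 0 || window[2] <= window[1])
    stop("`window` must be an increasing pair of non-negative days")
  list(state0 = state0, window = window, output_dt = output_dt)
}

#' Model-implied cascade intensity
#'
#' Runs paired simulations with mesozooplankton present versus absent
#' (Z(0) set to 0) under otherwise identical settings and returns the
#' relative enhancement of time-averaged phytoplankton biomass:
#' \deqn{(\bar P_{withZ} - \bar P_{withoutZ}) / \bar P_{withoutZ}}
#' averaged over the protocol window. Also reports the model-implied
#' Cascade Strength index, using the realised microzooplankton community
#' grazing rate \eqn{g_M \bar M / \bar P} in each run and the time-averaged
#' Z and M biomasses of the with-Z run as the biomass ratio.
#'
#' @param params An [npmz_params] object.
#' @param protocol A [cascade_protocol] list.
#' @param guard Passed to the integrator.
#' @return A list with \code{intensity}, \code{P_mean_withZ},
#'   \code{P_mean_withoutZ}, \code{g_micro_withoutZ}, \code{g_micro_withZ}
#'   and \code{CS_model}.
#' @export
cascade_intensity <- function(params, protocol = cascade_protocol(),
                              guard = TRUE) {
  s0 <- protocol$state0
  s0_noZ <- npmz_state(s0[["N"]] + s0[["Z"]], s0[["P"]], s0[["M"]], 0)
  t_end <- protocol$window[2]

  run <- function(st) npmz_integrate(st, params, t_end = t_end,
                                     output_dt = protocol$output_dt,
                                     guard = guard)
  trZ <- run(s0)
  tr0 <- run(s0_noZ)
  inwin <- trZ$time >= protocol$window[1]

  Pz <- mean(trZ$P[inwin])
  P0 <- mean(tr0$P[inwin])
  if (!is.finite(P0) || P0 < 1e-12)
    stop("degenerate baseline: mean phytoplankton without Z is ~0")
  Mz <- mean(trZ$M[inwin]); M0 <- mean(tr0$M[inwin])
  Zz <- mean(trZ$Z[inwin])

  g_micro_without <- params$gM * M0 / P0
  g_micro_with <- params$gM * Mz / Pz
  CS_model <- if (g_micro_without > 0 && Zz > 0 && Mz > 0)
    cascade_strength(g_micro_without, g_micro_with, Zz, Mz)$CS
  else NA_real_

  list(intensity = (Pz - P0) / P0,
       P_mean_withZ = Pz, P_mean_withoutZ = P0,
       g_micro_withoutZ = g_micro_without, g_micro_withZ = g_micro_with,
       CS_model = CS_model)
}

#' Local sensitivity (elasticity) analysis of cascade intensity
#'
#' Normalised central-difference sensitivities
#' \eqn{S_\theta = (\partial m / \partial \theta)(\theta / m)} of the
#' cascade-intensity metric with respect to each of the ten NPMZ
#' parameters, with each parameter perturbed by \code{rel_perturbation} in
#' both directions. Elasticities are unit-free, so the ranking by absolute
#' value is directly comparable across parameters. A parameter whose
#' perturbed metric cannot be computed is flagged (\code{NA}) while the
#' others are still returned.
#'
#' @param params Base-point [npmz_params].
#' @param protocol A [cascade_protocol].
#' @param rel_perturbation Relative perturbation (default 0.05).
#' @param guard Passed to the integrator.
#' @return A data.frame with columns \code{parameter}, \code{value},
#'   \code{sensitivity} and \code{rank} (1 = largest absolute
#'   elasticity), ordered by rank.
#' @export
sensitivity_analysis <- function(params, protocol = cascade_protocol(),
                                 rel_perturbation = 0.05, guard = TRUE) {
  base <- cascade_intensity(params, protocol, guard = guard)$intensity
  if (!is.finite(base) || base == 0)
    stop("cascade intensity at the base point is ", base,
         "; elasticities are undefined")
  nm <- names(unclass(params))
  sens <- vapply(nm, function(p) {
    th <- params[[p]]
    if (th == 0) return(0)  # no pathway: zero perturbation possible
    up <- unclass(params); up[[p]] <- th * (1 + rel_perturbation)
    dn <- unclass(params); dn[[p]] <- th * (1 - rel_perturbation)
    m <- tryCatch({
      mu <- cascade_intensity(suppressWarnings(do.call(npmz_params, up)),
                              protocol, guard = guard)$intensity
      md <- cascade_intensity(suppressWarnings(do.call(npmz_params, dn)),
                              protocol, guard = guard)$intensity
      (mu - md) / (2 * th * rel_perturbation) * th / base
    }, error = function(e) NA_real_)
    m
  }, numeric(1))
  out <- data.frame(parameter = nm,
                    value = unlist(unclass(params))[nm],
                    sensitivity = unname(sens),
                    row.names = NULL)
  out$rank <- rank(-abs(out$sensitivity), ties.method = "first",
                   na.last = "keep")
  out[order(out$rank), ]
}

#' Warming scenario for the NPMZ model
#'
#' Applies the linear GZ temperature response (and, optionally, the
#' three-phase thermal modifier as a multiplier on the warmed GZ) to the
#' baseline parameters, then compares cascade intensity before and after
#' warming. The realised percent change is reported, not asserted against
#' any expected band: the magnitude depends on the baseline
#' parameterisation.
#'
#' @param params Baseline [npmz_params].
#' @param delta_T Warming (deg C).
#' @param cfg A [thermal_config].
#' @param protocol A [cascade_protocol].
#' @param baseline_T Ambient baseline temperature (deg C) to which
#'   \code{delta_T} is added when \code{use_three_phase = TRUE}.
#' @param use_three_phase Multiply the warmed GZ by the ratio of
#'   three-phase modifiers at the warmed and baseline temperatures
#'   (default FALSE: linear response only).
#' @param guard Passed to the integrator.
#' @return A list with \code{delta_GZ}, \code{GZ_baseline},
#'   \code{GZ_warmed}, \code{intensity_baseline}, \code{intensity_warmed}
#'   and \code{percent_change}.
#' @export
warming_scenario <- function(params, delta_T, cfg = thermal_config(),
                             protocol = cascade_protocol(),
                             baseline_T = 20, use_three_phase = FALSE,
                             guard = TRUE) {
  GZ_warm <- gz_thermal_response(params$GZ, delta_T, cfg)
  if (use_three_phase) {
    mod0 <- three_phase_thermal_modifier(baseline_T, cfg)
    mod1 <- three_phase_thermal_modifier(baseline_T + delta_T, cfg)
    GZ_warm <- GZ_warm * mod1 / mod0
  }
  warmed <- unclass(params)
  warmed$GZ <- GZ_warm
  warmed <- suppressWarnings(do.call(npmz_params, warmed))

  i0 <- cascade_intensity(params, protocol, guard = guard)$intensity
  i1 <- cascade_intensity(warmed, protocol, guard = guard)$intensity
  list(delta_GZ = GZ_warm - params$GZ,
       GZ_baseline = params$GZ, GZ_warmed = GZ_warm,
       intensity_baseline = i0, intensity_warmed = i1,
       percent_change = 100 * (i1 - i0) / abs(i0))
}
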