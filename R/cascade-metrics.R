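#' Cascade Strength index
#'
#' Integrates the relative reduction in microzooplankton grazing caused by
#' mesozooplankton with the biomass structure of the two grazer groups:
#' \deqn{CS = \frac{g_{micro} - g'_{micro}}{g_{micro}}
#'       \ln\!\left(\frac{B_{meso}}{B_{micro}}\right).}
#' CS > 0 indicates a positive (classic) cascade, CS = 0 no cascade, and
#' CS < 0 an inverse cascade. Both the natural logarithm and the sign
#' convention are deliberate: CS vanishes whenever the grazing rates are
#' equal or the two biomasses are equal.
#'
#' @param g_micro_control Microzooplankton grazing rate without
#'   mesozooplankton (d^-1, > 0).
#' @param g_micro_treatment Microzooplankton grazing rate with
#'   mesozooplankton present (d^-1).
#' @param B_meso Mesozooplankton biomass (> 0).
#' @param B_micro Microzooplankton biomass (> 0, same units).
#' @return A list with \code{CS}, \code{grazing_reduction}
#'   (\eqn{(g - g')/g}) and \code{log_biomass_ratio}
#'   (\eqn{\ln(B_{meso}/B_{micro})}).
#' @examples
#' cascade_strength(0.8, 0.4, B_meso = exp(1), B_micro = 1)$CS  # 0.5
#' @export
cascade_strength <- function(g_micro_control, g_micro_treatment,
                             B_meso, B_micro) {
  if (any(!is.finite(g_micro_control)) || any(g_micro_control <= 0))
    stop("`g_micro_control` must be finite and positive")
  if (any(!is.finite(g_micro_treatment)))
    stop("`g_micro_treatment` must be finite")
  if (any(!is.finite(B_meso)) || any(B_meso <= 0) ||
      any(!is.finite(B_micro)) || any(B_micro <= 0))
    stop("biomasses must be finite and positive")
  reduction <- (g_micro_control - g_micro_treatment) / g_micro_control
  logratio <- log(B_meso / B_micro)
  list(CS = reduction * logratio,
       grazing_reduction = reduction,
       log_biomass_ratio = logratio)
}

#' Density-mediated cascade (DMC) ratio
#'
#' The change in phytoplankton biomass per unit change in mesozooplankton
#' predation pressure. The sign is preserved: a negative ratio reports an
#' inverse density-mediated response, it is not clamped.
#'
#' @param delta_phyto_biomass Change in phytoplankton biomass.
#' @param delta_meso_predation_pressure Change in mesozooplankton predation
#'   pressure (non-zero).
#' @return The ratio.
#' @export
dmc_index <- function(delta_phyto_biomass, delta_meso_predation_pressure) {
  if (any(!is.finite(delta_phyto_biomass)) ||
      any(!is.finite(delta_meso_predation_pressure)))
    stop("inputs must be finite")
  if (any(delta_meso_predation_pressure == 0))
    stop("`delta_meso_predation_pressure` must be non-zero")
  delta_phyto_biomass / delta_meso_predation_pressure
}

#' Predator-prey size-matching efficiency kernel
#'
#' Cascade efficiency as a log-Gaussian function of the predator:prey body
#' length ratio \eqn{r = L_{meso}/L_{micro}}:
#' \deqn{\alpha(r) = \alpha_{peak}
#'   \exp\!\left(-\frac{(\ln(r/r_{opt}))^2}{2\sigma^2}\right)}
#' with peak efficiency 0.42 at a 10:1 length ratio and
#' \eqn{\sigma = \sqrt{\ln 2 / 2}}, so that efficiency halves exactly at
#' ratios 5 and 20 — a >50% decline under size mismatch outside the optimal
#' ridge. The log-Gaussian form is a package choice; the peak height,
#' optimal ratio and half-decline landmarks are the calibration constraints.
#'
#' @param L_meso Mesozooplankton (predator) body length, micrometres (> 0).
#' @param L_micro Microzooplankton (prey) body length, micrometres (> 0).
#' @param alpha_peak Peak efficiency (default 0.42).
#' @param ratio_opt Optimal length ratio (default 10).
#' @param sigma Log-scale width (default \code{sqrt(log(2)/2)}).
#' @return Cascade efficiency coefficient alpha (dimensionless).
#' @examples
#' size_matching_alpha(1000, 100)  # 0.42 at the 10:1 optimum
#' size_matching_alpha(500, 100)   # 0.21, half the peak
#' @export
size_matching_alpha <- function(L_meso, L_micro, alpha_peak = 0.42,
                                ratio_opt = 10, sigma = sqrt(log(2) / 2)) {
  if (any(!is.finite(L_meso)) || any(L_meso <= 0) ||
      any(!is.finite(L_micro)) || any(L_micro <= 0))
    stop("body lengths must be finite and positive")
  r <- L_meso / L_micro
  alpha_peak * exp(-(log(r / ratio_opt))^2 / (2 * sigma^2))
}

#' Thermal-response configuration
#'
#' Bundles the tunable constants of the temperature-response functions:
#' the linear warming sensitivity of mesozooplankton grazing on
#' microzooplankton (default slope 0.0875 d^-1 per deg C, so +2 deg C gives
#' +0.175 d^-1, the midpoint of the 0.15-0.2 d^-1 response band), the fold
#' increase of cascade efficiency per +2 deg C warming (default 1.75, the
#' midpoint of the 1.5-2.0 range), and the phase boundaries of the
#' three-phase thermal modifier (enhancement from 15 deg C, optimal plateau
#' 20-24 deg C). The enhancement-phase floor (0.5) and the collapse
#' e-folding scale (2 deg C) shape the modifier outside its landmarks and
#' are free choices exposed here.
#'
#' @param gz_slope_per_degC Linear GZ response slope (d^-1 per deg C, >= 0).
#' @param alpha_fold_at_2degC Fold increase of alpha at +2 deg C (>= 1).
#' @param T_rise_start,T_opt_low,T_opt_high Phase boundaries (deg C),
#'   strictly increasing.
#' @param enhancement_floor Modifier value at and below
#'   \code{T_rise_start}, in (0, 1].
#' @param collapse_efold_degC E-folding temperature scale of the collapse
#'   phase (deg C, > 0).
#' @return An object of class \code{"thermal_config"}.
#' @export
thermal_config <- function(gz_slope_per_degC = 0.0875,
                           alpha_fold_at_2degC = 1.75,
                           T_rise_start = 15, T_opt_low = 20,
                           T_opt_high = 24,
                           enhancement_floor = 0.5,
                           collapse_efold_degC = 2) {
  if (!is.finite(gz_slope_per_degC) || gz_slope_per_degC < 0)
    stop("`gz_slope_per_degC` must be non-negative")
  if (!is.finite(alpha_fold_at_2degC) || alpha_fold_at_2degC < 1)
    stop("`alpha_fold_at_2degC` must be >= 1")
  if (!(T_rise_start < T_opt_low && T_opt_low < T_opt_high))
    stop("phase bounds must satisfy T_rise_start < T_opt_low < T_opt_high")
  if (!is.finite(enhancement_floor) || enhancement_floor <= 0 ||
      enhancement_floor > 1)
    stop("`enhancement_floor` must lie in (0, 1]")
  if (!is.finite(collapse_efold_degC) || collapse_efold_degC <= 0)
    stop("`collapse_efold_degC` must be positive")
  structure(list(gz_slope_per_degC = gz_slope_per_degC,
                 alpha_fold_at_2degC = alpha_fold_at_2degC,
                 T_rise_start = T_rise_start, T_opt_low = T_opt_low,
                 T_opt_high = T_opt_high,
                 enhancement_floor = enhancement_floor,
                 collapse_efold_degC = collapse_efold_degC),
            class = "thermal_config")
}

#' Warming response of mesozooplankton grazing on microzooplankton
#'
#' Linear temperature response \eqn{GZ(\Delta T) = GZ_{base} +
#' s \, \Delta T}, floored at zero. With the default slope a +2 deg C
#' warming raises GZ by 0.175 d^-1, inside the 0.15-0.2 d^-1 band expected
#' for that warming.
#'
#' @param GZ_base Baseline grazing coefficient (d^-1, >= 0).
#' @param delta_T Temperature change (deg C).
#' @param cfg A [thermal_config].
#' @return Adjusted GZ (d^-1, >= 0).
#' @export
gz_thermal_response <- function(GZ_base, delta_T, cfg = thermal_config()) {
  if (any(!is.finite(GZ_base)) || any(GZ_base < 0))
    stop("`GZ_base` must be non-negative")
  if (any(!is.finite(delta_T))) stop("`delta_T` must be finite")
  pmax(0, GZ_base + cfg$gz_slope_per_degC * delta_T)
}

#' Warming scaling of the cascade efficiency coefficient
#'
#' Multiplies alpha by a factor interpolating linearly from 1 at
#' \eqn{\Delta T = 0} to \code{cfg$alpha_fold_at_2degC} at +2 deg C; the
#' factor is floored at 1 for cooling (efficiency is not reduced below its
#' baseline by this pathway).
#'
#' @param alpha_base Baseline cascade efficiency (>= 0).
#' @param delta_T Temperature change (deg C).
#' @param cfg A [thermal_config].
#' @return Adjusted alpha.
#' @export
alpha_thermal_scaling <- function(alpha_base, delta_T,
                                  cfg = thermal_config()) {
  if (any(!is.finite(alpha_base)) || any(alpha_base < 0))
    stop("`alpha_base` must be non-negative")
  if (any(!is.finite(delta_T))) stop("`delta_T` must be finite")
  factor <- pmax(1, 1 + (cfg$alpha_fold_at_2degC - 1) * delta_T / 2)
  alpha_base * factor
}

#' Three-phase thermal modifier of cascade strength
#'
#' Piecewise multiplier in (0, 1] describing how absolute temperature
#' modulates cascade strength: a metabolic enhancement phase where the
#' modifier rises linearly from \code{enhancement_floor} at
#' \code{T_rise_start} (15 deg C) to 1 at \code{T_opt_low} (20 deg C); an
#' optimal plateau at exactly 1 between 20 and 24 deg C; and a functional
#' collapse phase above 24 deg C where the modifier decays exponentially
#' with e-folding scale \code{collapse_efold_degC}. Below the enhancement
#' phase the modifier holds at the floor. The function is continuous.
#'
#' @param T_degC Ambient temperature (deg C), finite; vectorised.
#' @param cfg A [thermal_config].
#' @return Multiplier in (0, 1].
#' @examples
#' three_phase_thermal_modifier(c(10, 17, 22, 27))
#' @export
three_phase_thermal_modifier <- function(T_degC, cfg = thermal_config()) {
  if (any(!is.finite(T_degC))) stop("`T_degC` must be finite")
  vapply(T_degC, function(Tt) {
    if (Tt < cfg$T_rise_start) {
      cfg$enhancement_floor
    } else if (Tt < cfg$T_opt_low) {
      cfg$enhancement_floor + (1 - cfg$enhancement_floor) *
        (Tt - cfg$T_rise_start) / (cfg$T_opt_low - cfg$T_rise_start)
    } else if (Tt <= cfg$T_opt_high) {
      1
    } else {
      exp(-(Tt - cfg$T_opt_high) / cfg$collapse_efold_degC)
    }
  }, numeric(1))
}
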