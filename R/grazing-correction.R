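#' Level-1 Frost log-ratio grazing rate
#'
#' The uncorrected bottle-incubation estimate of mesozooplankton grazing on
#' phytoplankton: the log-ratio of final phytoplankton concentrations in a
#' grazer-free control versus a mesozooplankton-containing treatment, divided
#' by incubation time and (for the per-grazer form) grazer abundance:
#' \deqn{g_{meso}^{raw} = \ln(C_{control} / C_{treatment}) / (t Z).}
#'
#' This estimate conflates direct grazing with the indirect cascade: when
#' mesozooplankton suppress microzooplankton, phytoplankton in the treatment
#' are released from microzooplankton grazing and the log-ratio shrinks,
#' sometimes below zero. Such negative values are the motivation for the
#' Level-2/Level-3 corrections ([level2_adjust], [level3_adjust]).
#'
#' @param C_control Final phytoplankton concentration in the control (> 0).
#' @param C_treatment Final phytoplankton concentration in the treatment
#'   (> 0), same units.
#' @param t Incubation duration (d, > 0).
#' @param Z Mesozooplankton abundance or biomass (> 0). Set \code{Z = 1}
#'   (the default of [community_raw_rate]) for the community-rate form.
#' @return Per-grazer grazing rate; may be negative.
#' @seealso [community_raw_rate] for the community-rate (d^-1) variant used
#'   by the correction pipeline.
#' @examples
#' frost_raw_rate(1000, 500, t = 1, Z = 10)   # ln(2)/10
#' frost_raw_rate(500, 1000, t = 1, Z = 10)   # negative apparent rate
#' @export
frost_raw_rate <- function(C_control, C_treatment, t, Z) {
  if (any(!is.finite(C_control)) || any(C_control <= 0) ||
      any(!is.finite(C_treatment)) || any(C_treatment <= 0))
    stop("phytoplankton concentrations must be finite and positive")
  if (any(!is.finite(t)) || any(t <= 0))
    stop("incubation duration `t` must be positive")
  if (any(!is.finite(Z)) || any(Z <= 0))
    stop("grazer abundance `Z` must be positive for the per-grazer rate")
  log(C_control / C_treatment) / (t * Z)
}

#' Community-rate form of the Frost log-ratio
#'
#' \eqn{\ln(C_{control}/C_{treatment}) / t}, in d^-1. Dimensionally
#' consistent with the microzooplankton community grazing rates added at
#' correction Levels 2 and 3, and therefore the form used by
#' [estimate_cascade_workflow].
#'
#' @inheritParams frost_raw_rate
#' @return Community grazing rate (d^-1); may be negative.
#' @export
community_raw_rate <- function(C_control, C_treatment, t) {
  frost_raw_rate(C_control, C_treatment, t, Z = 1)
}

#' Level-2 correction: microzooplankton background grazing
#'
#' Adjusts the raw rate for the difference in microzooplankton grazing
#' pressure between the control and treatment bottles:
#' \deqn{g^{adj} = g^{raw} + g_{micro} - g'_{micro}}
#' where \eqn{g_{micro}} and \eqn{g'_{micro}} are the microzooplankton
#' community grazing rates measured without and with mesozooplankton.
#'
#' @param g_raw Raw (Level-1, community form) grazing rate (d^-1).
#' @param g_micro_control Microzooplankton grazing rate in the control
#'   (d^-1).
#' @param g_micro_treatment Microzooplankton grazing rate in the treatment
#'   (d^-1).
#' @return Level-2 adjusted grazing rate (d^-1).
#' @export
level2_adjust <- function(g_raw, g_micro_control, g_micro_treatment) {
  if (any(!is.finite(g_raw)) || any(!is.finite(g_micro_control)) ||
      any(!is.finite(g_micro_treatment)))
    stop("all rates must be finite")
  g_raw + (g_micro_control - g_micro_treatment)
}

#' Cascade drivers for the Level-3 compensation
#'
#' @param alpha Cascade efficiency coefficient (dimensionless, >= 0); may be
#'   derived from predator:prey size via [size_matching_alpha] or supplied
#'   from configuration.
#' @param CI Carnivory index: proportion of microzooplankton in the
#'   mesozooplankton diet, in \[0, 1\].
#' @param B_meso Mesozooplankton biomass (>= 0, declared units).
#' @return An object of class \code{"cascade_drivers"}.
#' @export
cascade_drivers <- function(alpha, CI, B_meso) {
  stopifnot(length(alpha) == 1L, length(CI) == 1L, length(B_meso) == 1L)
  if (!is.finite(alpha) || alpha < 0)
    stop("`alpha` must be finite and non-negative, got ", alpha)
  if (!is.finite(CI) || CI < 0 || CI > 1)
    stop("carnivory index `CI` must lie in [0, 1], got ", CI)
  if (!is.finite(B_meso) || B_meso < 0)
    stop("`B_meso` must be finite and non-negative, got ", B_meso)
  structure(list(alpha = as.numeric(alpha), CI = as.numeric(CI),
                 B_meso = as.numeric(B_meso)),
            class = "cascade_drivers")
}

#' Level-3 trophic-cascade compensation term
#'
#' The expected reduction in microzooplankton grazing caused by
#' mesozooplankton predation, modelled as a saturating function of cascade
#' efficiency, carnivory and predator biomass:
#' \deqn{TC = g_{micro} [1 - \exp(-\alpha \, CI \, B_{meso})].}
#' TC is bounded by the control grazing rate and saturates towards it as any
#' driver grows large.
#'
#' @param g_micro_control Microzooplankton grazing rate without
#'   mesozooplankton (d^-1, >= 0).
#' @param drivers A [cascade_drivers] object.
#' @return The cascade compensation TC (d^-1), in
#'   \[0, \code{g_micro_control}\].
#' @examples
#' tc_compensation(0.8, cascade_drivers(alpha = 0.3, CI = 0.5, B_meso = 2))
#' @export
tc_compensation <- function(g_micro_control, drivers) {
  if (!inherits(drivers, "cascade_drivers"))
    stop("`drivers` must be a `cascade_drivers` object")
  if (any(!is.finite(g_micro_control)) || any(g_micro_control < 0))
    stop("`g_micro_control` must be finite and non-negative")
  g_micro_control *
    (1 - exp(-drivers$alpha * drivers$CI * drivers$B_meso))
}

#' Level-3 corrected grazing rate
#'
#' \eqn{g^{adj} = g^{raw} + TC}: adds the cascade compensation to the raw
#' log-ratio rate, recovering the direct grazing that the cascade masked.
#'
#' @param g_raw Raw (community form) grazing rate (d^-1); may be negative.
#' @param TC Trophic-cascade compensation (d^-1, >= 0 when obtained from
#'   [tc_compensation]; workflow-estimated TC may be negative for inverse
#'   cascades).
#' @return Level-3 adjusted grazing rate (d^-1).
#' @export
level3_adjust <- function(g_raw, TC) {
  if (any(!is.finite(g_raw)) || any(!is.finite(TC)))
    stop("inputs must be finite")
  g_raw + TC
}

#' Construct a paired control/treatment grazing experiment
#'
#' One replicate of a bottle-incubation grazing experiment: a grazer-free
#' control and a mesozooplankton treatment, with initial/final phytoplankton
#' concentrations, incubation duration, mesozooplankton abundance, and mean
#' microzooplankton and phytoplankton standing stocks over the incubation.
#' Mean concentrations default to the geometric mean of initial and final
#' values when not recorded directly.
#'
#' @param C_control_initial,C_control_final Control phytoplankton
#'   concentrations at start and end (> 0).
#' @param C_treatment_initial,C_treatment_final Treatment phytoplankton
#'   concentrations at start and end (> 0).
#' @param t Incubation duration (d, > 0).
#' @param Z Mesozooplankton abundance or biomass in the treatment (>= 0).
#' @param M_control_mean,M_treatment_mean Mean microzooplankton
#'   concentrations (>= 0); required.
#' @param P_control_mean,P_treatment_mean Mean phytoplankton concentrations
#'   (> 0); default geometric means of initial/final.
#' @param replicate_id Identifier carried through to estimates.
#' @param units Concentration units label (checked against functional-
#'   response parameter units downstream).
#' @return An object of class \code{"grazing_experiment"}.
#' @export
grazing_experiment <- function(C_control_initial, C_control_final,
                               C_treatment_initial, C_treatment_final,
                               t, Z,
                               M_control_mean, M_treatment_mean,
                               P_control_mean = NULL,
                               P_treatment_mean = NULL,
                               replicate_id = 1L,
                               units = "cells_per_mL") {
  conc <- c(C_control_initial, C_control_final,
            C_treatment_initial, C_treatment_final)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all phytoplankton concentrations must be finite and positive")
  if (!is.finite(t) || t <= 0) stop("`t` must be positive")
  if (!is.finite(Z) || Z < 0) stop("`Z` must be non-negative")
  if (any(!is.finite(c(M_control_mean, M_treatment_mean))) ||
      any(c(M_control_mean, M_treatment_mean) < 0))
    stop("mean microzooplankton concentrations must be non-negative")
  if (is.null(P_control_mean))
    P_control_mean <- sqrt(C_control_initial * C_control_final)
  if (is.null(P_treatment_mean))
    P_treatment_mean <- sqrt(C_treatment_initial * C_treatment_final)
  if (any(c(P_control_mean, P_treatment_mean) <= 0))
    stop("mean phytoplankton concentrations must be positive")
  structure(list(
    C_control_initial = C_control_initial,
    C_control_final = C_control_final,
    C_treatment_initial = C_treatment_initial,
    C_treatment_final = C_treatment_final,
    t = t, Z = Z,
    M_control_mean = M_control_mean,
    M_treatment_mean = M_treatment_mean,
    P_control_mean = P_control_mean,
    P_treatment_mean = P_treatment_mean,
    replicate_id = replicate_id,
    units = units
  ), class = "grazing_experiment")
}

#' Three-step cascade estimation workflow
#'
#' Applies the fitted two-factor grazing relationship to a paired
#' control/treatment incubation: (1) the functional-response parameters give
#' g(x, y); (2) microzooplankton grazing is estimated in both bottles from
#' their mean prey and grazer concentrations; (3) the trophic-cascade rate is
#' the difference, \eqn{TC = g_{micro} - g'_{micro}}. The raw log-ratio rate
#' and the Level-2/Level-3 corrections are reported alongside.
#'
#' A negative TC (treatment microzooplankton grazing exceeding the control's)
#' is reported as-is with \code{inverse_cascade = TRUE}.
#'
#' @param experiment A [grazing_experiment].
#' @param params An [fr_params] object with units matching the experiment's.
#' @return An object of class \code{"cascade_estimate"}: list with
#'   \code{g_raw} (community form, d^-1), \code{g_raw_per_grazer} (Frost
#'   form, \code{NA} when Z = 0), \code{g_micro_control},
#'   \code{g_micro_treatment}, \code{TC}, \code{g_level2}, \code{g_level3},
#'   \code{inverse_cascade}, \code{negative_raw} and \code{replicate_id}.
#' @examples
#' ex <- grazing_experiment(1000, 900, 1000, 950, t = 1, Z = 10,
#'                          M_control_mean = 10, M_treatment_mean = 4)
#' estimate_cascade_workflow(ex, fr_params(38, 1093))
#' @export
estimate_cascade_workflow <- function(experiment, params) {
  if (!inherits(experiment, "grazing_experiment"))
    stop("`experiment` must be a `grazing_experiment` object")
  params <- check_fr_params(params)
  if (!identical(experiment$units, params$units))
    stop("units mismatch: experiment uses '", experiment$units,
         "' but functional-response parameters use '", params$units, "'")

  g_micro_control <- two_factor_grazing(experiment$P_control_mean,
                                        experiment$M_control_mean, params)
  g_micro_treatment <- two_factor_grazing(experiment$P_treatment_mean,
                                          experiment$M_treatment_mean,
                                          params)
  TC <- g_micro_control - g_micro_treatment
  g_raw <- community_raw_rate(experiment$C_control_final,
                              experiment$C_treatment_final, experiment$t)
  g_raw_per_grazer <- if (experiment$Z > 0)
    frost_raw_rate(experiment$C_control_final, experiment$C_treatment_final,
                   experiment$t, experiment$Z) else NA_real_

  structure(list(
    g_raw = g_raw,
    g_raw_per_grazer = g_raw_per_grazer,
    g_micro_control = g_micro_control,
    g_micro_treatment = g_micro_treatment,
    TC = TC,
    g_level2 = level2_adjust(g_raw, g_micro_control, g_micro_treatment),
    g_level3 = level3_adjust(g_raw, TC),
    inverse_cascade = TC < 0,
    negative_raw = g_raw < 0,
    replicate_id = experiment$replicate_id
  ), class = "cascade_estimate")
}

#' @export
print.cascade_estimate <- function(x, ...) {
  cat("Cascade estimate (replicate ", x$replicate_id, ")\n", sep = "")
  cat(sprintf("  g_raw (community)   = %+.5f d^-1%s\n", x$g_raw,
              if (x$negative_raw) "  [negative apparent rate]" else ""))
  if (is.finite(x$g_raw_per_grazer))
    cat(sprintf("  g_raw (per grazer)  = %+.5g\n", x$g_raw_per_grazer))
  cat(sprintf("  g_micro control     = %.5f d^-1\n", x$g_micro_control))
  cat(sprintf("  g_micro treatment   = %.5f d^-1\n", x$g_micro_treatment))
  cat(sprintf("  TC                  = %+.5f d^-1%s\n", x$TC,
              if (x$inverse_cascade) "  [inverse cascade]" else ""))
  cat(sprintf("  g_level2 = %+.5f, g_level3 = %+.5f d^-1\n",
              x$g_level2, x$g_level3))
  invisible(x)
}

#' Tabulate cascade estimates
#'
#' @param estimates A list of [estimate_cascade_workflow] results.
#' @return A data.frame with one row per estimate.
#' @export
cascade_estimates_table <- function(estimates) {
  if (inherits(estimates, "cascade_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(replicate_id = e$replicate_id, g_raw = e$g_raw,
               g_raw_per_grazer = e$g_raw_per_grazer,
               g_micro_control = e$g_micro_control,
               g_micro_treatment = e$g_micro_treatment,
               TC = e$TC, g_level2 = e$g_level2, g_level3 = e$g_level3,
               inverse_cascade = e$inverse_cascade)
  }))
}
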