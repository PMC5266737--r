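#' Blue-light proliferation factor
#'
#' Fluence-dependent multiplier applied to the self-proliferation rates
#' (gamma1, gamma2) of all proliferative keratinocytes on treatment days:
#' \code{a_gamma * exp(b_gamma * F)}, clamped to [0, 1]. With the default
#' coefficients (\code{a_gamma = 1}, \code{b_gamma = -3.4e-3} cm^2/J) it
#' equals 1 at zero fluence and decays exponentially with the daily fluence.
#'
#' @param F daily fluence (J/cm^2), >= 0; vectorized.
#' @param params parameter list.
#' @return dimensionless factor in [0, 1].
#' @export
#' @examples
#' bl_proliferation_factor(90, default_parameters()) # exp(-0.306)
bl_proliferation_factor <- function(F, params = default_parameters()) {
  check_fluence(F)
  pmin(1, pmax(0, params$a_gamma * exp(params$b_gamma * F)))
}

#' Blue-light differentiation factor
#'
#' Fluence-dependent multiplier for division/differentiation rates:
#' \code{c_k - a_k * exp(b_k * F)}, clamped to [0, 1]. With the default
#' coefficients (3.46 - 2.46 * exp(0.0194 F)) it equals 1 at zero fluence,
#' reaches 0 near F = 17.6 J/cm^2 and is clamped to 0 beyond. In the
#' selected mechanism (hypothesis case 1) this factor is not applied at all
#' (the multiplier is identically 1); it matters only for the
#' hypothesis-screen variants.
#'
#' @inheritParams bl_proliferation_factor
#' @return dimensionless factor in [0, 1].
#' @export
bl_differentiation_factor <- function(F, params = default_parameters()) {
  check_fluence(F)
  pmin(1, pmax(0, params$c_k - params$a_k * exp(params$b_k * F)))
}

#' Blue-light apoptosis increment
#'
#' Step function of the daily fluence capturing cytotoxicity at high doses:
#' 0 below 500 J/cm^2, 0.039/d on [500, 750) and 0.05/d at or above 750.
#' Boundaries are left-closed: a session of exactly 500 J/cm^2 already
#' triggers the cytotoxic increment.
#'
#' @inheritParams bl_proliferation_factor
#' @return additive apoptosis rate increment (per day).
#' @export
theta_beta_of_fluence <- function(F, params = default_parameters()) {
  check_fluence(F)
  ifelse(F >= 750, params$theta_beta_gt750,
         ifelse(F >= 500, params$theta_beta_500_750, 0))
}

#' All three blue-light factors at a given daily fluence
#'
#' @inheritParams bl_proliferation_factor
#' @return list with \code{theta_gamma}, \code{theta_k}, \code{theta_beta}.
#' @export
blue_light_factors <- function(F, params = default_parameters()) {
  list(
    theta_gamma = bl_proliferation_factor(F, params),
    theta_k = bl_differentiation_factor(F, params),
    theta_beta = theta_beta_of_fluence(F, params)
  )
}

#' Stem-cell regulation by the transit-amplifying population
#'
#' Healthy stem-cell proliferation and division rates are the homeostatic
#' minima scaled by \code{omega / (1 + (omega - 1) * ((Pta_h + Pta_d) /
#' Pta_hom)^n)}: when the total transit-amplifying density is at its
#' homeostatic value the factor is 1; when it vanishes the rates increase up
#' to the maximum fold \code{omega}. Diseased stem cells are not regulated
#' by this feedback.
#'
#' @param Pta_h,Pta_d healthy and diseased transit-amplifying densities
#'   (cells/mm^2), >= 0.
#' @param params parameter list (uses \code{omega}, \code{n},
#'   \code{Pta_hom}).
#' @return dimensionless factor in (0, omega].
#' @export
#' @examples
#' stem_regulation_factor(0, 0, default_parameters()) # omega = 100
stem_regulation_factor <- function(Pta_h, Pta_d, params = default_parameters()) {
  if (any(Pta_h < 0) || any(Pta_d < 0)) {
    stop("transit-amplifying densities must be non-negative")
  }
  if (!is.numeric(params$Pta_hom) || params$Pta_hom <= 0) {
    stop("Pta_hom must be > 0")
  }
  x <- (Pta_h + Pta_d) / params$Pta_hom
  params$omega / (1 + (params$omega - 1) * x^params$n)
}

#' Immune killing of diseased stem cells
#'
#' Hill-type (n = 2) removal flux of diseased stem cells by the sustained
#' immune response: \code{K_p * Psc_d^2 / (K_a^2 + Psc_d^2)}, bounded above
#' by the maximum killing rate \code{K_p} and half-activated at
#' \code{Psc_d = K_a}.
#'
#' @param Psc_d diseased stem-cell density (cells/mm^2), >= 0.
#' @param params parameter list (uses \code{K_p}, \code{K_a}).
#' @return removal flux (cells/mm^2/day).
#' @export
immune_killing <- function(Psc_d, params = default_parameters()) {
  if (any(Psc_d < 0)) stop("Psc_d must be non-negative")
  params$K_p * Psc_d^2 / (params$K_a^2 + Psc_d^2)
}

check_fluence <- function(F) {
  if (!is.numeric(F) || any(!is.finite(F)) || any(F < 0)) {
    stop("fluence must be a non-negative number (J/cm^2)")
  }
  invisible(F)
}
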