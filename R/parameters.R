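#' Default model parameterization
#'
#' Returns the full parameter set of the epidermal blue-light model: rate
#' constants for the six differentiation stages of the healthy and diseased
#' keratinocyte lineages, the stem-cell niche capacity and its psoriatic fold
#' increase, the transit-amplifying feedback (maximum fold increase
#' \code{omega}, Hill steepness \code{n}, homeostatic density
#' \code{Pta_hom}), the immune killing term (\code{K_p}, \code{K_a}),
#' apoptotic indices, desquamation rates, and the blue-light coefficients of
#' the fluence-dependent proliferation, differentiation and apoptosis
#' factors.
#'
#' All rates are per day, densities in cells per mm^2 and fluences in
#' J/cm^2. Diseased kinetic rates can be taken either as the published
#' reference values (\code{diseased_rates = "table"}, the default) or derived
#' as healthy rate times the psoriatic fold change
#' (\code{diseased_rates = "product"}); the two differ by up to ~15% and both
#' are kept available for transparency.
#'
#' \code{Pta_hom} is not part of the published value set; the default was
#' calibrated once with [calibrate_pta_hom()] so that the untreated
#' all-healthy steady state totals approximately 100,000 cells/mm^2, the
#' literature density of healthy epidermis. \code{k_m1_d} and \code{k_m2_d}
#' (diseased back-conversion) are likewise unpublished and default to the
#' healthy values.
#'
#' @param diseased_rates how the diseased kinetic rates are obtained:
#'   \code{"table"} uses the published reference values, \code{"product"}
#'   multiplies each healthy rate by its psoriatic fold change.
#' @param overrides named list of parameter values replacing defaults.
#' @return a named list of class \code{bluederm_params}.
#' @export
#' @examples
#' p <- default_parameters()
#' p$gamma1_hom
default_parameters <- function(diseased_rates = c("table", "product"),
                               overrides = list()) {
  diseased_rates <- match.arg(diseased_rates)
  p <- list(
    # stem-cell niche
    Psc_max    = 4.5e3,    # growth capacity of stem cells (cells/mm^2)
    lambda_cap = 3.5,      # psoriatic fold change of stem growth capacity
    # healthy stem cells at homeostasis (minimal rates; scaled up by the
    # transit-amplifying feedback when TA density is below Pta_hom)
    gamma1_hom = 3.30e-3,
    k1s_hom    = 1.64e-3,
    k1a_hom    = 1.31e-2,
    # healthy transit amplifying and differentiation rates
    gamma2_h = 1.40e-2,
    k2s_h    = 1.73e-2,
    k2a_h    = 1.38e-1,
    k3_h     = 2.16e-1,
    k4_h     = 5.56e-2,
    k5_h     = 1.11e-1,
    k_m1_h   = 1.00e-6,
    k_m2_h   = 1.00e-6,
    # transit-amplifying feedback on healthy stem rates
    omega   = 100,
    n       = 3,
    Pta_hom = 6678.26,     # calibrated: healthy steady state ~1e5 cells/mm^2
    # apoptotic indices (fraction of total outflux that is apoptosis)
    AI_h = 0.0012,
    AI_d = 0.00035,
    # desquamation
    alpha_h = 7.14e-2,
    alpha_d = 2.50e-1,
    # psoriatic fold changes
    rho_sc = 4,
    rho_ta = 4,
    rho_tr = 5,
    rho_de = 4,
    # immune killing of diseased stem cells
    K_p = 6,
    K_a = 380,
    # diseased rates (filled below)
    gamma1_d = NA_real_, k1s_d = NA_real_, k1a_d = NA_real_,
    gamma2_d = NA_real_, k2s_d = NA_real_, k2a_d = NA_real_,
    k3_d = NA_real_, k4_d = NA_real_, k5_d = NA_real_,
    k_m1_d = 1.00e-6,
    k_m2_d = 1.00e-6,
    # blue-light factor coefficients
    a_gamma = 1,
    b_gamma = -3.40e-3,
    a_k = 2.46,
    b_k = 1.94e-2,
    c_k = 3.46,
    # step increments of the apoptosis rate at cytotoxic fluences (per day)
    theta_beta_500_750 = 3.9e-2,
    theta_beta_gt750   = 5.0e-2,
    # epidermal energy absorbance (type 1-3, low-perfused skin); only used
    # when fluence_absorbed = TRUE in the simulator
    xi_abs = 0.579
  )
  p[names(derived_diseased_rates(p, mode = diseased_rates))] <-
    derived_diseased_rates(p, mode = diseased_rates)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(overrides)] <- overrides
  }
  class(p) <- "bluederm_params"
  validate_parameters(p)
  p
}

#' Diseased kinetic rates
#'
#' The diseased lineage proliferates, divides and differentiates faster than
#' the healthy one by the psoriatic fold changes \code{rho_sc} (stem),
#' \code{rho_ta} (transit amplifying), \code{rho_tr} (transit through the
#' non-proliferative stages) and \code{rho_de} (desquamation). The published
#' reference values (\code{mode = "table"}) do not exactly equal the
#' fold-change products (ratios of printed diseased to healthy rates are
#' roughly 3.5 and 4.5 rather than 4 and 5); both variants are exposed and
#' the printed values are the default ground truth.
#'
#' @param params parameter list (healthy rates and fold changes must be set).
#' @param mode \code{"table"} for published values, \code{"product"} for
#'   healthy rate times fold change.
#' @return named list of the nine diseased kinetic rates plus the diseased
#'   desquamation rate \code{alpha_d}.
#' @export
derived_diseased_rates <- function(params, mode = c("table", "product")) {
  mode <- match.arg(mode)
  if (mode == "table") {
    list(
      gamma1_d = 1.16e-2, k1s_d = 5.70e-3, k1a_d = 4.59e-2,
      gamma2_d = 4.90e-2, k2s_d = 6.06e-2, k2a_d = 4.83e-1,
      k3_d = 9.72e-1, k4_d = 2.50e-1, k5_d = 3.89e-1,
      alpha_d = 2.50e-1
    )
  } else {
    list(
      gamma1_d = params$gamma1_hom * params$rho_sc,
      k1s_d    = params$k1s_hom * params$rho_sc,
      k1a_d    = params$k1a_hom * params$rho_sc,
      gamma2_d = params$gamma2_h * params$rho_ta,
      k2s_d    = params$k2s_h * params$rho_ta,
      k2a_d    = params$k2a_h * params$rho_ta,
      k3_d     = params$k3_h * params$rho_tr,
      k4_d     = params$k4_h * params$rho_tr,
      k5_d     = params$k5_h * params$rho_tr,
      alpha_d  = params$alpha_h * params$rho_de
    )
  }
}

#' Apoptosis rate from apoptotic index
#'
#' The apoptotic index \code{AI} is the fraction of a population's total
#' outflux due to apoptosis. Given the population's differentiation (or
#' symmetric division) rate constant \code{k}, the apoptosis rate solves
#' AI = beta/(beta + k), i.e. beta = AI*k/(1-AI), plus an additive
#' blue-light increment \code{theta_beta} active only at cytotoxic fluences.
#'
#' @param AI apoptotic index, in [0, 1).
#' @param k differentiation/division rate constant (per day), >= 0.
#' @param theta_beta additive apoptosis increment (per day), >= 0.
#' @return apoptosis rate (per day).
#' @export
#' @examples
#' apoptosis_rate(0.0012, 1.64e-3) # healthy stem cells, ~1.97e-6 per day
apoptosis_rate <- function(AI, k, theta_beta = 0) {
  stopifnot(is.numeric(AI), is.numeric(k), is.numeric(theta_beta))
  if (any(AI < 0 | AI >= 1)) {
    stop("apoptotic index AI must lie in [0, 1)")
  }
  if (any(k < 0) || any(theta_beta < 0)) {
    stop("rate constants and theta_beta must be non-negative")
  }
  AI * k / (1 - AI) + theta_beta
}

#' All ten derived apoptosis rates
#'
#' Applies [apoptosis_rate()] to the five healthy and five diseased
#' populations that undergo apoptosis. Stem and transit-amplifying rates use
#' the symmetric division constants; the non-proliferative stages use their
#' differentiation constants.
#'
#' @param params parameter list.
#' @param theta_beta additive blue-light apoptosis increment (per day).
#' @return named numeric vector \code{beta_1h..beta_5h, beta_1d..beta_5d}.
#' @export
derived_apoptosis_rates <- function(params, theta_beta = 0) {
  kh <- c(params$k1s_hom, params$k2s_h, params$k3_h, params$k4_h, params$k5_h)
  kd <- c(params$k1s_d, params$k2s_d, params$k3_d, params$k4_d, params$k5_d)
  out <- c(
    apoptosis_rate(params$AI_h, kh, theta_beta),
    apoptosis_rate(params$AI_d, kd, theta_beta)
  )
  names(out) <- c(paste0("beta_", 1:5, "h"), paste0("beta_", 1:5, "d"))
  out
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model: non-negative rates,
#' apoptotic indices in [0,1), \code{omega > 1}, \code{n >= 1},
#' \code{lambda_cap >= 1}, positive capacities, and the sign constraints of
#' the blue-light coefficients (\code{a_gamma > 0}, \code{b_gamma < 0};
#' \code{a_k}, \code{b_k}, \code{c_k > 0}).
#'
#' @param params parameter list.
#' @return the parameter list, invisibly; errors list every violated key.
#' @export
validate_parameters <- function(params) {
  required <- names(default_parameter_skeleton())
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  bad <- character()
  nonneg <- c(
    "Psc_max", "gamma1_hom", "k1s_hom", "k1a_hom", "gamma2_h", "k2s_h",
    "k2a_h", "k3_h", "k4_h", "k5_h", "k_m1_h", "k_m2_h", "Pta_hom",
    "alpha_h", "alpha_d", "rho_sc", "rho_ta", "rho_tr", "rho_de",
    "K_p", "K_a", "gamma1_d", "k1s_d", "k1a_d", "gamma2_d", "k2s_d",
    "k2a_d", "k3_d", "k4_d", "k5_d", "k_m1_d", "k_m2_d",
    "theta_beta_500_750", "theta_beta_gt750"
  )
  for (nm in nonneg) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      bad <- c(bad, paste0(nm, " must be a non-negative number"))
    }
  }
  if (!(params$AI_h >= 0 && params$AI_h < 1)) bad <- c(bad, "AI_h must lie in [0, 1)")
  if (!(params$AI_d >= 0 && params$AI_d < 1)) bad <- c(bad, "AI_d must lie in [0, 1)")
  if (!(params$omega > 1)) bad <- c(bad, "omega must be > 1")
  if (!(params$n >= 1)) bad <- c(bad, "n must be >= 1")
  if (!(params$lambda_cap >= 1)) bad <- c(bad, "lambda_cap must be >= 1")
  if (!(params$Psc_max > 0)) bad <- c(bad, "Psc_max must be > 0")
  if (!(params$Pta_hom > 0)) bad <- c(bad, "Pta_hom must be > 0")
  if (!(params$a_gamma > 0)) bad <- c(bad, "a_gamma must be > 0")
  if (!(params$b_gamma < 0)) bad <- c(bad, "b_gamma must be < 0")
  if (!(params$a_k > 0 && params$b_k > 0 && params$c_k > 0)) {
    bad <- c(bad, "a_k, b_k, c_k must all be > 0")
  }
  if (!(params$xi_abs > 0 && params$xi_abs <= 1)) {
    bad <- c(bad, "xi_abs must lie in (0, 1]")
  }
  if (length(bad)) {
    stop("invalid parameters:\n  ", paste(bad, collapse = "\n  "))
  }
  invisible(params)
}

# Internal: key skeleton used for validation and config parsing.
default_parameter_skeleton <- function() {
  p <- list(
    Psc_max = 0, lambda_cap = 1, gamma1_hom = 0, k1s_hom = 0, k1a_hom = 0,
    gamma2_h = 0, k2s_h = 0, k2a_h = 0, k3_h = 0, k4_h = 0, k5_h = 0,
    k_m1_h = 0, k_m2_h = 0, omega = 2, n = 1, Pta_hom = 1, AI_h = 0,
    AI_d = 0, alpha_h = 0, alpha_d = 0, rho_sc = 0, rho_ta = 0, rho_tr = 0,
    rho_de = 0, K_p = 0, K_a = 0, gamma1_d = 0, k1s_d = 0, k1a_d = 0,
    gamma2_d = 0, k2s_d = 0, k2a_d = 0, k3_d = 0, k4_d = 0, k5_d = 0,
    k_m1_d = 0, k_m2_d = 0, a_gamma = 1, b_gamma = -1, a_k = 1, b_k = 1,
    c_k = 1, theta_beta_500_750 = 0, theta_beta_gt750 = 0, xi_abs = 0.5
  )
  p
}

#' @export
print.bluederm_params <- function(x, ...) {
  cat("<bluederm_params>", length(x), "parameters\n")
  df <- data.frame(value = unlist(x))
  print(df)
  invisible(x)
}
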