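#' Time derivatives of the 12 keratinocyte compartments
#'
#' Pure-R reference implementation of the model right-hand side. Healthy and
#' diseased lineages each progress through stem, transit amplifying (TA),
#' growth arrested, spinous, granular and corneocyte stages. Stem cells of
#' both lineages share a logistic niche (self-proliferation is gated by
#' \code{1 - (Psc_h + Psc_d)/(lambda_cap * Psc_max)}); healthy stem rates
#' are additionally scaled by the transit-amplifying feedback
#' ([stem_regulation_factor()]); diseased stem cells are removed by the
#' immune Hill term ([immune_killing()]); the diseased granular compartment
#' is constant at zero (parakeratosis).
#'
#' Two conventions are supported. \code{"flux_consistent"} (default)
#' corrects four anomalies of the typeset equations so that every flux has a
#' source and a destination: (i) the stem-to-TA influx
#' \code{(k1a + 2 k1s) theta_k Psc} enters the TA balance with a positive
#' sign; (ii) symmetric TA division delivers two growth-arrested cells,
#' i.e. the TA-to-GA influx is \code{(k2a + 2 k2s) theta_k Pta}; (iii) the
#' diseased spinous outflux uses the diseased rate k4_d; (iv) the diseased
#' corneocyte influx is \code{k4_d theta_k Psp_d} (spinous cells cornify
#' directly, skipping the absent granular layer). \code{"as_printed"}
#' evaluates the published equations literally.
#'
#' @param state 12-vector of densities, ordered as [state_names()].
#' @param params parameter list.
#' @param fluence daily fluence F (J/cm^2); determines the blue-light
#'   factors through \code{case}.
#' @param case hypothesis case (integer id or [hypothesis_case()]).
#' @param convention \code{"flux_consistent"} or \code{"as_printed"}.
#' @return named numeric vector of 12 time derivatives (cells/mm^2/day).
#' @export
#' @examples
#' epidermis_rhs(default_state(), default_parameters())
epidermis_rhs <- function(state, params = default_parameters(), fluence = 0,
                          case = hypothesis_case(1),
                          convention = c("flux_consistent", "as_printed")) {
  convention <- match.arg(convention)
  s <- as.numeric(state)
  if (length(s) != 12) stop("state must have 12 components")
  if (any(s < 0)) stop("state components must be non-negative")
  names(s) <- state_names()
  m <- case_multipliers(case, fluence, params)
  tb <- theta_beta_of_fluence(fluence, params)
  b <- derived_apoptosis_rates(params, theta_beta = tb)
  p <- params

  fc <- convention == "flux_consistent"
  sgn <- if (fc) 1 else -1    # sign of the stem-to-TA influx
  sym2 <- if (fc) 2 else 1    # GA cells produced per symmetric TA division

  cap <- p$lambda_cap * p$Psc_max
  Lg <- 1 - (s["Psc_h"] + s["Psc_d"]) / cap
  th_reg <- stem_regulation_factor(s["Pta_h"], s["Pta_d"], p)

  # healthy stem rates: homeostatic minima x TA feedback x blue-light factor
  g1h <- p$gamma1_hom * th_reg * m["gamma1"]
  k1sh <- p$k1s_hom * th_reg * m["k1s"]
  k1ah <- p$k1a_hom * th_reg * m["k1a"]
  g2h <- p$gamma2_h * m["gamma2"]
  k2sh <- p$k2s_h * m["k2s"]
  k2ah <- p$k2a_h * m["k2a"]
  k3h <- p$k3_h * m["k3"]
  k4h <- p$k4_h * m["k4"]
  k5h <- p$k5_h * m["k5"]

  g1d <- p$gamma1_d * m["gamma1"]
  k1sd <- p$k1s_d * m["k1s"]
  k1ad <- p$k1a_d * m["k1a"]
  g2d <- p$gamma2_d * m["gamma2"]
  k2sd <- p$k2s_d * m["k2s"]
  k2ad <- p$k2a_d * m["k2a"]
  k3d <- p$k3_d * m["k3"]
  k4d <- p$k4_d * m["k4"]
  k5d <- p$k5_d * m["k5"]

  d <- numeric(12)
  names(d) <- state_names()

  d["Psc_h"] <- (g1h * Lg - k1sh - b["beta_1h"]) * s["Psc_h"] +
    p$k_m1_h * s["Pta_h"]
  d["Pta_h"] <- (g2h - k2sh - b["beta_2h"] - p$k_m1_h) * s["Pta_h"] +
    sgn * (k1ah + 2 * k1sh) * s["Psc_h"] + p$k_m2_h * s["Pga_h"]
  d["Pga_h"] <- (k2ah + sym2 * k2sh) * s["Pta_h"] -
    (p$k_m2_h + k3h + b["beta_3h"]) * s["Pga_h"]
  d["Psp_h"] <- k3h * s["Pga_h"] - (k4h + b["beta_4h"]) * s["Psp_h"]
  d["Pgc_h"] <- k4h * s["Psp_h"] - (k5h + b["beta_5h"]) * s["Pgc_h"]
  d["Pcc_h"] <- k5h * s["Pgc_h"] - p$alpha_h * s["Pcc_h"]

  d["Psc_d"] <- (g1d * Lg - k1sd - b["beta_1d"]) * s["Psc_d"] -
    immune_killing(s["Psc_d"], p) + p$k_m1_d * s["Pta_d"]
  d["Pta_d"] <- (g2d - k2sd - b["beta_2d"] - p$k_m1_d) * s["Pta_d"] +
    sgn * (k1ad + 2 * k1sd) * s["Psc_d"] + p$k_m2_d * s["Pga_d"]
  d["Pga_d"] <- (k2ad + sym2 * k2sd) * s["Pta_d"] -
    (p$k_m2_d + k3d + b["beta_3d"]) * s["Pga_d"]
  # diseased spinous outflux: k4_d under flux_consistent, literal k4_h as
  # printed
  k4x <- if (fc) k4d else k4h
  d["Psp_d"] <- k3d * s["Pga_d"] - (k4x + b["beta_4d"]) * s["Psp_d"]
  d["Pgc_d"] <- 0
  d["Pcc_d"] <- (if (fc) k4d * s["Psp_d"] else k5d * s["Pgc_d"]) -
    p$alpha_d * s["Pcc_d"]

  unname(d) -> dv
  names(dv) <- state_names()
  dv
}

#' Flux audit of the right-hand side at a given state
#'
#' Decomposes each compartment's derivative into gross influx (sum of all
#' positive source terms) and gross outflux, and reports the relative
#' residual |dP/dt| / influx. Used to verify that the published initial
#' state is a near-fixed point of the diseased subsystem.
#'
#' @inheritParams epidermis_rhs
#' @return data.frame with compartment, influx, outflux, net and
#'   \code{rel_residual} (0 when influx is 0 and net is 0).
#' @export
flux_audit <- function(state, params = default_parameters(), fluence = 0,
                       case = hypothesis_case(1),
                       convention = "flux_consistent") {
  d <- epidermis_rhs(state, params, fluence, case, convention)
  influx <- gross_influx(state, params, fluence, case, convention)
  outflux <- influx - d
  rel <- ifelse(influx > 0, abs(d) / influx, ifelse(abs(d) > 0, Inf, 0))
  data.frame(
    compartment = state_names(),
    influx = as.numeric(influx),
    outflux = as.numeric(outflux),
    net = as.numeric(d),
    rel_residual = as.numeric(rel),
    row.names = NULL
  )
}

# Gross influx (all positive source terms) per compartment; mirrors
# epidermis_rhs term by term.
gross_influx <- function(state, params, fluence = 0,
                         case = hypothesis_case(1),
                         convention = "flux_consistent") {
  fc <- convention == "flux_consistent"
  s <- as.numeric(state); names(s) <- state_names()
  p <- params
  m <- case_multipliers(case, fluence, p)
  cap <- p$lambda_cap * p$Psc_max
  Lg <- 1 - (s["Psc_h"] + s["Psc_d"]) / cap
  th_reg <- stem_regulation_factor(s["Pta_h"], s["Pta_d"], p)
  g1h <- p$gamma1_hom * th_reg * m["gamma1"]
  k1sh <- p$k1s_hom * th_reg * m["k1s"]
  k1ah <- p$k1a_hom * th_reg * m["k1a"]
  sym2 <- if (fc) 2 else 1
  influx <- c(
    Psc_h = max(g1h * Lg, 0) * s["Psc_h"] + p$k_m1_h * s["Pta_h"],
    Pta_h = p$gamma2_h * m["gamma2"] * s["Pta_h"] +
      (if (fc) (k1ah + 2 * k1sh) * s["Psc_h"] else 0) +
      p$k_m2_h * s["Pga_h"],
    Pga_h = (p$k2a_h * m["k2a"] + sym2 * p$k2s_h * m["k2s"]) * s["Pta_h"],
    Psp_h = p$k3_h * m["k3"] * s["Pga_h"],
    Pgc_h = p$k4_h * m["k4"] * s["Psp_h"],
    Pcc_h = p$k5_h * m["k5"] * s["Pgc_h"],
    Psc_d = max(p$gamma1_d * m["gamma1"] * Lg, 0) * s["Psc_d"] +
      p$k_m1_d * s["Pta_d"],
    Pta_d = p$gamma2_d * m["gamma2"] * s["Pta_d"] +
      (if (fc) (p$k1a_d * m["k1a"] + 2 * p$k1s_d * m["k1s"]) * s["Psc_d"]
       else 0) +
      p$k_m2_d * s["Pga_d"],
    Pga_d = (p$k2a_d * m["k2a"] + sym2 * p$k2s_d * m["k2s"]) * s["Pta_d"],
    Psp_d = p$k3_d * m["k3"] * s["Pga_d"],
    Pgc_d = 0,
    Pcc_d = if (fc) p$k4_d * m["k4"] * s["Psp_d"]
            else p$k5_d * m["k5"] * s["Pgc_d"]
  )
  names(influx) <- state_names()
  influx
}
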