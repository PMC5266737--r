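#' Mechanism hypothesis cases
#'
#' Thirteen alternative in-silico representations of how blue light acts on
#' keratinocyte kinetics. Each case selects which rate families the two
#' fluence-dependent factors multiply: the proliferation factor
#' (theta_gamma, always a decrease) on the self-proliferation rates gamma1
#' and gamma2, and the differentiation factor (theta_k) on subsets of the
#' division/differentiation rates \{k1a, k1s, k2a, k2s, k3, k4, k5\}.
#'
#' Case 1 -- theta_gamma on gamma1 and gamma2 only, theta_k identically 1 --
#' is the mechanism selected by the screen and the package default.
#'
#' For the "increase" cases the screened hypothesis is that division or
#' differentiation rates go up under irradiation, which the bounded
#' differentiation factor (a value in [0, 1]) cannot express. No increasing
#' functional form is published, so the multiplier used is the reciprocal of
#' the differentiation factor, capped at \code{theta_k_max}; this is an
#' interpretation, flagged here and in the vignette.
#'
#' @param case_id integer 1..13.
#' @param theta_k_direction \code{"increase"} (reciprocal factor, the
#'   screened hypothesis for cases 2-13), \code{"decrease"} (the bounded
#'   factor itself) or \code{"off"} (multiplier forced to 1).
#' @param theta_k_max cap for the reciprocal multiplier in increase mode.
#' @return object of class \code{bluederm_case} with fields
#'   \code{case_id}, \code{gamma_targets}, \code{k_targets},
#'   \code{theta_k_direction}, \code{theta_k_max}.
#' @export
#' @examples
#' hypothesis_case(1)
hypothesis_case <- function(case_id,
                            theta_k_direction = c("increase", "decrease", "off"),
                            theta_k_max = 10) {
  theta_k_direction <- match.arg(theta_k_direction)
  if (!is.numeric(case_id) || length(case_id) != 1 ||
      !(case_id %in% 1:13)) {
    stop("case_id must be an integer in 1..13")
  }
  k_prolif_a <- c("k1a", "k2a")            # asymmetric division
  k_prolif_s <- c("k1s", "k2s")            # symmetric division
  k_nonprolif <- c("k3", "k4", "k5")       # differentiation
  k_all <- c(k_prolif_a, k_prolif_s, k_nonprolif)
  gamma_all <- c("gamma1", "gamma2")
  def <- switch(as.character(case_id),
    "1"  = list(g = gamma_all, k = character()),
    "2"  = list(g = character(), k = c(k_prolif_a, k_prolif_s)),
    "3"  = list(g = gamma_all, k = c(k_prolif_a, k_prolif_s)),
    "4"  = list(g = character(), k = k_prolif_a),
    "5"  = list(g = character(), k = k_prolif_s),
    "6"  = list(g = gamma_all, k = k_prolif_a),
    "7"  = list(g = gamma_all, k = k_prolif_s),
    "8"  = list(g = character(), k = k_nonprolif),
    "9"  = list(g = character(), k = k_all),
    "10" = list(g = gamma_all, k = k_nonprolif),
    "11" = list(g = character(), k = c(k_prolif_a, k_nonprolif)),
    "12" = list(g = character(), k = c(k_prolif_s, k_nonprolif)),
    "13" = list(g = gamma_all, k = k_all)
  )
  structure(
    list(case_id = as.integer(case_id),
         gamma_targets = def$g,
         k_targets = def$k,
         theta_k_direction = theta_k_direction,
         theta_k_max = theta_k_max),
    class = "bluederm_case"
  )
}

#' Per-rate blue-light multipliers for a hypothesis case
#'
#' Evaluates the blue-light factors at the daily fluence \code{F} and maps
#' them onto the nine rate families according to the case definition. Rates
#' outside the case's target sets get multiplier 1; on non-treatment days
#' (F = 0) every multiplier is 1.
#'
#' @param case a \code{bluederm_case} (or integer case id).
#' @param F daily fluence (J/cm^2).
#' @param params parameter list.
#' @return named numeric vector of multipliers for
#'   \code{gamma1, gamma2, k1a, k1s, k2a, k2s, k3, k4, k5}.
#' @export
case_multipliers <- function(case, F, params = default_parameters()) {
  if (!inherits(case, "bluederm_case")) case <- hypothesis_case(case)
  check_fluence(F)
  m <- c(gamma1 = 1, gamma2 = 1, k1a = 1, k1s = 1, k2a = 1, k2s = 1,
         k3 = 1, k4 = 1, k5 = 1)
  if (F == 0) return(m)
  tg <- bl_proliferation_factor(F, params)
  m[case$gamma_targets] <- tg
  if (length(case$k_targets) && case$theta_k_direction != "off") {
    tk <- bl_differentiation_factor(F, params)
    if (case$theta_k_direction == "increase") {
      tk <- if (tk <= 0) case$theta_k_max else min(1 / tk, case$theta_k_max)
    }
    m[case$k_targets] <- tk
  }
  m
}

#' @export
print.bluederm_case <- function(x, ...) {
  cat("<bluederm_case>", x$case_id, "\n")
  cat("  theta_gamma on:",
      if (length(x$gamma_targets)) paste(x$gamma_targets, collapse = ", ")
      else "(none)", "\n")
  cat("  theta_k on:",
      if (length(x$k_targets)) paste(x$k_targets, collapse = ", ")
      else "(none)",
      sprintf("[%s]\n", x$theta_k_direction))
  invisible(x)
}
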