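#' In-vitro culture forward model
#'
#' Relative end-point cell density of a proliferating keratinocyte culture
#' whose growth rate is scaled by the blue-light proliferation factor:
#' N(F)/N(0) = exp(r0 * T * (a_gamma * exp(b_gamma * F) - 1)). The assay
#' behind the published coefficients is not described in enough detail to
#' reproduce literally; this exponential-culture readout (growth rate r0,
#' duration T) is the package's documented interpretation and is also what
#' the synthetic generator and the fitting routine share.
#'
#' @param F fluence (J/cm^2), vectorized.
#' @param a_gamma,b_gamma blue-light proliferation coefficients.
#' @param growth_rate baseline culture growth rate r0 (per day; default
#'   log(2), a 24 h doubling time).
#' @param duration_days assay duration T (days; default 3, i.e. 72 h).
#' @return relative cell density (fraction of untreated control).
#' @export
culture_response <- function(F, a_gamma = 1, b_gamma = -3.4e-3,
                             growth_rate = log(2), duration_days = 3) {
  check_fluence(F)
  theta <- pmin(1, pmax(0, a_gamma * exp(b_gamma * F)))
  exp(growth_rate * duration_days * (theta - 1))
}

#' Synthetic dose-response table
#'
#' Simulates an in-vitro dose-response experiment: replicate cultures
#' irradiated at each fluence, relative end-point density from
#' [culture_response()] plus Gaussian measurement noise. Stands in for the
#' published in-vitro data set, which is only available as a figure.
#'
#' @param a_gamma,b_gamma generating coefficients.
#' @param fluences fluence grid (J/cm^2); the default covers the untreated
#'   control plus the three assayed fluences 33, 66 and 100 J/cm^2.
#' @param noise_sd standard deviation of the additive Gaussian noise on the
#'   relative density, >= 0.
#' @param n_reps replicates per fluence.
#' @param seed integer seed.
#' @param growth_rate,duration_days forward-model settings.
#' @return data.frame of class \code{bluederm_doseresponse} with columns
#'   \code{fluence_J_cm2}, \code{rel_density}, \code{replicate}.
#' @export
#' @examples
#' synth_dose_response(noise_sd = 0, n_reps = 1)
synth_dose_response <- function(a_gamma = 1, b_gamma = -3.4e-3,
                                fluences = c(0, 33, 66, 100),
                                noise_sd = 0.02, n_reps = 3, seed = 1,
                                growth_rate = log(2), duration_days = 3) {
  check_fluence(fluences)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  tab <- expand.grid(replicate = seq_len(n_reps), fluence_J_cm2 = fluences)
  mu <- culture_response(tab$fluence_J_cm2, a_gamma, b_gamma,
                         growth_rate, duration_days)
  tab$rel_density <- pmax(0, mu + stats::rnorm(nrow(tab), 0, noise_sd))
  tab <- tab[, c("fluence_J_cm2", "rel_density", "replicate")]
  class(tab) <- c("bluederm_doseresponse", "data.frame")
  tab
}

#' Fit the blue-light proliferation coefficients
#'
#' Nonlinear least squares of the culture forward model against a
#' dose-response table, estimating \code{a_gamma > 0} and
#' \code{b_gamma < 0}. The fit requires at least three distinct fluences
#' including the untreated control.
#'
#' @param table dose-response data.frame with columns \code{fluence_J_cm2}
#'   and \code{rel_density}.
#' @param growth_rate,duration_days forward-model settings (must match the
#'   assay).
#' @param start starting values for \code{c(a_gamma, b_gamma)}.
#' @return list with \code{a_gamma}, \code{b_gamma}, their approximate 95%
#'   confidence intervals (\code{ci}, from the asymptotic standard
#'   errors), and the underlying \code{fit} object.
#' @export
#' @examples
#' tab <- synth_dose_response(noise_sd = 0)
#' fit_bl_coefficients(tab)$b_gamma # ~ -3.4e-3
fit_bl_coefficients <- function(table, growth_rate = log(2),
                                duration_days = 3,
                                start = c(a_gamma = 1, b_gamma = -2e-3)) {
  if (!all(c("fluence_J_cm2", "rel_density") %in% names(table))) {
    stop("table must have columns fluence_J_cm2 and rel_density")
  }
  flu <- table$fluence_J_cm2
  if (length(unique(flu)) < 3 || !any(flu == 0)) {
    stop("unidentifiable dose-response table: need >= 3 distinct fluences ",
         "including the F = 0 control")
  }
  df <- data.frame(F = flu, y = table$rel_density)
  rT <- growth_rate * duration_days
  fit <- minpack.lm::nlsLM(
    y ~ exp(rT * (pmin(1, a * exp(b * F)) - 1)),
    data = df, start = list(a = start[[1]], b = start[[2]]),
    lower = c(a = 1e-8, b = -1), upper = c(a = 10, b = -1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 2))
  ci <- rbind(
    a_gamma = est["a"] + c(-1, 1) * 1.96 * se[1],
    b_gamma = est["b"] + c(-1, 1) * 1.96 * se[2]
  )
  colnames(ci) <- c("lower", "upper")
  list(a_gamma = unname(est["a"]), b_gamma = unname(est["b"]),
       ci = ci, fit = fit)
}
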