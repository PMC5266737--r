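#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum vertical separation between the empirical cumulative
#' distribution functions of two samples, D = max |S_a(x) - S_u(x)|,
#' evaluated over the pooled sample points. This is the separation measure
#' used by the multi-parametric sensitivity analysis to score how strongly
#' a parameter's acceptable and unacceptable value distributions differ.
#'
#' @param x,y numeric vectors (non-empty).
#' @return D in [0, 1].
#' @export
#' @examples
#' ks_statistic(1:10, 11:20) # disjoint supports -> 1
ks_statistic <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  z <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)
  fy <- stats::ecdf(y)
  max(abs(fx(z) - fy(z)))
}

#' Parameters sampled by default in the sensitivity analyses
#'
#' The kinetic, capacity, immune and blue-light parameters of the model --
#' everything that enters the equations as a continuous quantity.
#' Apoptosis rates are not sampled directly: they are derived from the
#' sampled apoptotic indices and division rates and therefore co-vary.
#'
#' @return character vector of parameter names.
#' @export
mpsa_parameter_set <- function() {
  c("Psc_max", "lambda_cap", "gamma1_hom", "k1s_hom", "k1a_hom",
    "gamma2_h", "k2s_h", "k2a_h", "k3_h", "k4_h", "k5_h",
    "k_m1_h", "k_m2_h", "omega", "Pta_hom", "AI_h", "AI_d",
    "alpha_h", "alpha_d", "K_p", "K_a",
    "gamma1_d", "k1s_d", "k1a_d", "gamma2_d", "k2s_d", "k2a_d",
    "k3_d", "k4_d", "k5_d", "k_m1_d", "k_m2_d",
    "a_gamma", "b_gamma")
}

# Parameter families used for qualitative summaries of the MPSA.
proliferation_family <- function() {
  c("gamma1_hom", "k1s_hom", "k1a_hom", "gamma2_h", "k2s_h", "k2a_h",
    "gamma1_d", "k1s_d", "k1a_d", "gamma2_d", "k2s_d", "k2a_d",
    "Psc_max", "lambda_cap", "omega", "Pta_hom", "a_gamma", "b_gamma")
}

#' Multi-parametric sensitivity analysis
#'
#' Latin-hypercube samples the parameter space (default: uniform bands of
#' +/-50% around nominal values), simulates the reference treatment for
#' every sample, scores each sample's deviation from the nominal run by a
#' squared-error cost per output (the 12 end-of-treatment cell densities
#' and the severity index), splits samples into acceptable and unacceptable
#' by a cost threshold (default: the sample median, giving balanced
#' classes), and reports, per parameter and output, the Kolmogorov-Smirnov
#' separation D between the acceptable and unacceptable parameter-value
#' distributions. Large D flags parameters whose value strongly determines
#' whether the model reproduces the nominal outcome.
#'
#' @param params nominal parameter list.
#' @param parameters names of parameters to sample (default
#'   [mpsa_parameter_set()]).
#' @param ranges optional named list of \code{c(lower, upper)} overriding
#'   the +/-50% default band per parameter.
#' @param n_samples number of Latin-hypercube samples (>= 100).
#' @param seed integer seed for the hypercube.
#' @param protocol treatment protocol simulated per sample.
#' @param state initial state.
#' @param threshold_rule \code{"median"} or a numeric absolute cost.
#' @param lpsi0 severity anchor for the LPSI output.
#' @param ... passed to [simulate_treatment()].
#' @return object of class \code{bluederm_mpsa}: list with \code{D}
#'   (matrix, parameter x output), \code{samples} (the LHS design),
#'   \code{costs}, \code{acceptable} (logical matrix, sample x output),
#'   \code{acceptable_counts}, \code{n_samples}, \code{n_failed},
#'   \code{seed}, \code{threshold_rule}.
#' @export
mpsa <- function(params = default_parameters(),
                 parameters = mpsa_parameter_set(),
                 ranges = NULL, n_samples = 5000, seed = 1,
                 protocol = pfaff_protocol(), state = default_state(),
                 threshold_rule = "median", lpsi0 = 5.17, ...) {
  if (n_samples < 100) stop("n_samples must be >= 100")
  stopifnot(all(parameters %in% names(params)))
  nominal <- unlist(params[parameters])
  lower <- nominal * 0.5
  upper <- nominal * 1.5
  # negative nominals (b_gamma): keep the band ordered
  swap <- lower > upper
  tmp <- lower[swap]; lower[swap] <- upper[swap]; upper[swap] <- tmp
  if (!is.null(ranges)) {
    stopifnot(all(names(ranges) %in% parameters))
    for (nm in names(ranges)) {
      r <- ranges[[nm]]
      if (length(r) != 2 || r[1] >= r[2]) {
        stop("range for ", nm, " must be c(lower, upper) with lower < upper")
      }
      lower[nm] <- r[1]; upper[nm] <- r[2]
    }
  }

  set.seed(seed)
  design <- lhs::randomLHS(n_samples, length(parameters))
  colnames(design) <- parameters
  samples <- sweep(sweep(design, 2, upper - lower, `*`), 2, lower, `+`)

  run_outputs <- function(p) {
    sim <- simulate_treatment(p, state, protocol, ...)
    t_end <- treatment_days(protocol)
    i <- match(t_end, sim$time)
    y <- sim$state[i, ]
    c(y, LPSI = unname(lpsi0 * sim$total[i] / sim$total[1]))
  }

  y_ref <- run_outputs(params)
  outputs <- names(y_ref)

  y_sim <- matrix(NA_real_, nrow = n_samples, ncol = length(outputs),
                  dimnames = list(NULL, outputs))
  for (i in seq_len(n_samples)) {
    p_i <- params
    p_i[parameters] <- as.list(samples[i, ])
    y_sim[i, ] <- tryCatch(run_outputs(p_i),
                           error = function(e) rep(NA_real_,
                                                   length(outputs)))
  }
  ok <- stats::complete.cases(y_sim)
  n_failed <- sum(!ok)

  costs <- sweep(y_sim[ok, , drop = FALSE], 2, y_ref, `-`)^2
  acc <- matrix(NA, nrow = sum(ok), ncol = length(outputs),
                dimnames = list(NULL, outputs))
  D <- matrix(NA_real_, nrow = length(parameters), ncol = length(outputs),
              dimnames = list(parameters, outputs))
  smp <- samples[ok, , drop = FALSE]
  for (k in seq_along(outputs)) {
    thr <- if (identical(threshold_rule, "median")) {
      stats::median(costs[, k])
    } else {
      as.numeric(threshold_rule)
    }
    a <- costs[, k] <= thr
    acc[, k] <- a
    if (all(a) || !any(a)) next  # D undefined for a one-class split
    for (j in seq_along(parameters)) {
      D[j, k] <- ks_statistic(smp[a, j], smp[!a, j])
    }
  }

  structure(
    list(D = D, samples = samples, costs = costs, acceptable = acc,
         acceptable_counts = colSums(acc),
         n_samples = n_samples, n_failed = n_failed, seed = seed,
         threshold_rule = threshold_rule, y_ref = y_ref),
    class = "bluederm_mpsa"
  )
}

#' @export
print.bluederm_mpsa <- function(x, ...) {
  cat("<bluederm_mpsa>", x$n_samples, "samples,", nrow(x$D),
      "parameters,", ncol(x$D), "outputs",
      if (x$n_failed) paste0("(", x$n_failed, " failed runs)"), "\n")
  dmax <- apply(x$D, 1, max, na.rm = TRUE)
  cat("  parameters with max D > 0.3:",
      paste(names(sort(dmax[dmax > 0.3], decreasing = TRUE)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Local sensitivity analysis
#'
#' Normalized central-difference sensitivities
#' (dy/dtheta) * (theta/y) of the end-of-treatment outputs (12 densities,
#' total density and severity index) with respect to each parameter,
#' evaluated at the nominal parameter set.
#'
#' @param params nominal parameter list.
#' @param parameters names of parameters to perturb.
#' @param delta relative perturbation (default 1%).
#' @param protocol treatment protocol.
#' @param state initial state.
#' @param lpsi0 severity anchor.
#' @param ... passed to [simulate_treatment()].
#' @return matrix (parameter x output) of normalized sensitivities.
#' @export
lpsa <- function(params = default_parameters(),
                 parameters = mpsa_parameter_set(), delta = 0.01,
                 protocol = pfaff_protocol(), state = default_state(),
                 lpsi0 = 5.17, ...) {
  stopifnot(delta > 0, delta < 1, all(parameters %in% names(params)))
  run_outputs <- function(p) {
    sim <- simulate_treatment(p, state, protocol, ...)
    t_end <- treatment_days(protocol)
    i <- match(t_end, sim$time)
    y <- sim$state[i, ]
    c(y, total = unname(sim$total[i]),
      LPSI = unname(lpsi0 * sim$total[i] / sim$total[1]))
  }
  y0 <- run_outputs(params)
  S <- matrix(NA_real_, nrow = length(parameters), ncol = length(y0),
              dimnames = list(parameters, names(y0)))
  for (nm in parameters) {
    v <- params[[nm]]
    if (v == 0) { S[nm, ] <- 0; next }
    p_hi <- params; p_hi[[nm]] <- v * (1 + delta)
    p_lo <- params; p_lo[[nm]] <- v * (1 - delta)
    y_hi <- run_outputs(p_hi)
    y_lo <- run_outputs(p_lo)
    S[nm, ] <- ifelse(y0 != 0, (y_hi - y_lo) / (2 * delta * y0), 0)
  }
  S
}
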