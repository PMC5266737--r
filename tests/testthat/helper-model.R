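# Shared fixtures: nominal parameters/state built once per test run.
par0 <- default_parameters()
st0 <- default_state()

# Reference values of the published parameter table, used to pin defaults.
table1_values <- c(
  Psc_max = 4.5e3, gamma1_hom = 3.30e-3, k1s_hom = 1.64e-3,
  k1a_hom = 1.31e-2, gamma2_h = 1.40e-2, k2s_h = 1.73e-2, k2a_h = 1.38e-1,
  k3_h = 2.16e-1, k4_h = 5.56e-2, k5_h = 1.11e-1, k_m1_h = 1.00e-6,
  k_m2_h = 1.00e-6, omega = 100, n = 3, AI_h = 0.0012, alpha_h = 7.14e-2,
  rho_sc = 4, rho_ta = 4, rho_tr = 5, rho_de = 4, lambda_cap = 3.5,
  K_p = 6, K_a = 380, gamma1_d = 1.16e-2, k1s_d = 5.70e-3, k1a_d = 4.59e-2,
  gamma2_d = 4.90e-2, k2s_d = 6.06e-2, k2a_d = 4.83e-1, k3_d = 9.72e-1,
  k4_d = 2.50e-1, k5_d = 3.89e-1, AI_d = 0.00035, alpha_d = 2.50e-1,
  a_gamma = 1, b_gamma = -3.40e-3, a_k = 2.46, b_k = 1.94e-2, c_k = 3.46,
  theta_beta_500_750 = 3.9e-2, theta_beta_gt750 = 5.0e-2, xi_abs = 0.579
)

# Published derived apoptosis rates (per day).
table1_betas <- c(
  beta_1h = 1.97e-6, beta_2h = 2.08e-5, beta_3h = 2.60e-4,
  beta_4h = 6.68e-5, beta_5h = 1.33e-4,
  beta_1d = 2.01e-6, beta_2d = 2.12e-5, beta_3d = 3.40e-4,
  beta_4d = 8.76e-5, beta_5d = 1.36e-4
)

# Brute-force two-sample KS oracle: direct ECDF enumeration over the sorted
# pooled sample, independent of the package implementation.
ks_brute <- function(x, y) {
  d <- 0
  for (z in sort(c(x, y))) {
    d <- max(d, abs(mean(x <= z) - mean(y <= z)))
  }
  d
}

# Independent flux audit of the diseased compartments at a given state:
# hand-written influx/outflux sums straight from the model equations
# (flux-consistent convention, no treatment), not using epidermis_rhs().
diseased_flux_oracle <- function(s, p) {
  Lg <- 1 - (s[["Psc_h"]] + s[["Psc_d"]]) / (p$lambda_cap * p$Psc_max)
  beta <- function(AI, k) AI * k / (1 - AI)
  kill <- p$K_p * s[["Psc_d"]]^2 / (p$K_a^2 + s[["Psc_d"]]^2)
  infl <- c(
    Psc_d = p$gamma1_d * Lg * s[["Psc_d"]] + p$k_m1_d * s[["Pta_d"]],
    Pta_d = p$gamma2_d * s[["Pta_d"]] +
      (p$k1a_d + 2 * p$k1s_d) * s[["Psc_d"]] + p$k_m2_d * s[["Pga_d"]],
    Pga_d = (p$k2a_d + 2 * p$k2s_d) * s[["Pta_d"]],
    Psp_d = p$k3_d * s[["Pga_d"]],
    Pgc_d = 0,
    Pcc_d = p$k4_d * s[["Psp_d"]]
  )
  outf <- c(
    Psc_d = (p$k1s_d + beta(p$AI_d, p$k1s_d)) * s[["Psc_d"]] + kill,
    Pta_d = (p$k2s_d + beta(p$AI_d, p$k2s_d) + p$k_m1_d) * s[["Pta_d"]],
    Pga_d = (p$k_m2_d + p$k3_d + beta(p$AI_d, p$k3_d)) * s[["Pga_d"]],
    Psp_d = (p$k4_d + beta(p$AI_d, p$k4_d)) * s[["Psp_d"]],
    Pgc_d = 0,
    Pcc_d = p$alpha_d * s[["Pcc_d"]]
  )
  list(influx = infl, outflux = outf, net = infl - outf)
}
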