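parameters:
  Psc_max: 4500.0
  lambda_cap: 3.5
  gamma1_hom: 0.0033
  k1s_hom: 0.00164
  k1a_hom: 0.0131
  gamma2_h: 0.014
  k2s_h: 0.0173
  k2a_h: 0.138
  k3_h: 0.216
  k4_h: 0.0556
  k5_h: 0.111
  k_m1_h: 1.0e-06
  k_m2_h: 1.0e-06
  omega: 100.0
  'n': 3.0
  Pta_hom: 6678.26
  AI_h: 0.0012
  AI_d: 0.00035
  alpha_h: 0.0714
  alpha_d: 0.25
  rho_sc: 4.0
  rho_ta: 4.0
  rho_tr: 5.0
  rho_de: 4.0
  K_p: 6.0
  K_a: 380.0
  gamma1_d: 0.0116
  k1s_d: 0.0057
  k1a_d: 0.0459
  gamma2_d: 0.049
  k2s_d: 0.0606
  k2a_d: 0.483
  k3_d: 0.972
  k4_d: 0.25
  k5_d: 0.389
  k_m1_d: 1.0e-06
  k_m2_d: 1.0e-06
  a_gamma: 1.0
  b_gamma: -0.0034
  a_k: 2.46
  b_k: 0.0194
  c_k: 3.46
  theta_beta_500_750: 0.039
  theta_beta_gt750: 0.05
  xi_abs: 0.579
state:
  Psc_h: 362.0
  Pta_h: 77.0
  Pga_h: 61.0
  Psp_h: 238.0
  Pgc_h: 119.0
  Pcc_h: 185.0
  Psc_d: 6459.0
  Pta_d: 32098.0
  Pga_d: 20536.0
  Psp_d: 79788.0
  Pgc_d: 0.0
  Pcc_d: 77633.0
protocol:
  follow_up_days: 0
  three_per_week_days:
  - 1
  - 3
  - 5
  phases:
  - days: 28
    cadence: daily
    fluence: 90.0
    session_time: 1800.0
    mode: PW
    duty_cycle: 0.5
  - days: 56
    cadence: three_per_week
    fluence: 90.0
    session_time: 1800.0
    mode: PW
    duty_cycle: 0.5
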