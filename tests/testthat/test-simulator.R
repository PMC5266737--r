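test_that("untreated diseased epidermis holds its quasi-steady state", {
  sim <- simulate_treatment(
    par0, st0, treatment_protocol(list(), follow_up_days = 84))
  expect_true(all(abs(sim$total - 217556) / 217556 < 0.05))
})

test_that("zero initial state stays identically zero", {
  zero <- epidermis_state(stats::setNames(rep(0, 12), state_names()))
  sim <- simulate_treatment(par0, zero, pfaff_protocol())
  expect_true(all(sim$state == 0))
})

test_that("treatment transiently reduces density, then relapse", {
  sim <- simulate_treatment(protocol = pfaff_protocol(follow_up_days = 84))
  expect_lt(sim$total[29], sim$total[1])       # end of daily phase
  expect_lt(sim$total[85], sim$total[1])       # end of treatment
  post <- sim$total[sim$time >= 84]
  expect_true(all(diff(post) > -1e-6 * post[1]))  # monotone rebound
  # relapse heads back toward the untreated diseased state, not past it
  expect_lt(utils::tail(sim$total, 1), 217556 * 1.001)
  expect_gt(utils::tail(sim$total, 1), sim$total[85])
})

test_that("continuous and pulsed modes give identical trajectories", {
  sim_cw <- simulate_treatment(protocol = pfaff_protocol(mode = "CW"))
  sim_pw <- simulate_treatment(protocol = pfaff_protocol(mode = "PW",
                                                         duty_cycle = 0.25))
  expect_identical(sim_cw$theta$fluence, sim_pw$theta$fluence)
  expect_equal(sim_cw$state, sim_pw$state, tolerance = 1e-10)
})

test_that("intensity does not matter at fixed daily fluence", {
  # 100, 200, 600 mW/cm2 at 90 J/cm2 means session times 900, 450, 150 s
  sims <- lapply(c(900, 450, 150), function(tt) {
    simulate_treatment(protocol = treatment_protocol(
      protocol_phase(28, "daily", 90, session_time = tt)))
  })
  lp <- vapply(sims, function(s) final_lpsi(s)[["end_of_treatment"]],
               numeric(1))
  expect_equal(lp[1], lp[2], tolerance = 1e-12)
  expect_equal(lp[1], lp[3], tolerance = 1e-12)
})

test_that("simulation bookkeeping is consistent", {
  sim <- simulate_treatment(protocol = pfaff_protocol(follow_up_days = 7))
  expect_length(sim$time, 92)
  expect_equal(sim$total, rowSums(sim$state))
  expect_equal(sim$total, sim$healthy_total + sim$diseased_total)
  df <- as.data.frame(sim)
  expect_equal(nrow(df), 92 * 12)
  expect_error(
    simulate_treatment(protocol = pfaff_protocol(), horizon_days = 10),
    "horizon"
  )
})

test_that("absorbed-fluence option attenuates the applied dose", {
  sim_inc <- simulate_treatment(protocol = pfaff_protocol())
  sim_abs <- simulate_treatment(protocol = pfaff_protocol(),
                                fluence_absorbed = TRUE)
  expect_equal(sim_abs$theta$theta_gamma[1],
               bl_proliferation_factor(90 * par0$xi_abs, par0))
  # weaker effective dose, milder response
  expect_gt(utils::tail(sim_abs$total, 1), utils::tail(sim_inc$total, 1))
})
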