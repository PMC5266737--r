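test_that("case definitions map the factors onto the right rate families", {
  m1 <- case_multipliers(hypothesis_case(1), 90, par0)
  expect_equal(unname(m1["gamma1"]), exp(-3.4e-3 * 90), tolerance = 1e-12)
  expect_equal(unname(m1["gamma1"]), 0.7364, tolerance = 1e-4)
  expect_equal(unname(m1["gamma2"]), unname(m1["gamma1"]))
  expect_true(all(m1[c("k1a", "k1s", "k2a", "k2s", "k3", "k4", "k5")] == 1))

  m5 <- case_multipliers(hypothesis_case(5), 10, par0)
  expect_true(all(m5[c("gamma1", "gamma2", "k1a", "k2a", "k3", "k4",
                       "k5")] == 1))
  expect_gt(unname(m5["k1s"]), 1)   # symmetric division increased
  expect_equal(unname(m5["k1s"]), unname(m5["k2s"]))

  m8 <- case_multipliers(hypothesis_case(8), 10, par0)
  expect_true(all(m8[c("gamma1", "gamma2", "k1a", "k1s", "k2a",
                       "k2s")] == 1))
  expect_true(all(m8[c("k3", "k4", "k5")] > 1))

  # no-treatment day: every multiplier is 1 in every case
  for (id in 1:13) {
    expect_true(all(case_multipliers(hypothesis_case(id), 0, par0) == 1),
                info = id)
  }
  expect_error(hypothesis_case(14), "case_id")
})

test_that("increase-mode multiplier is the capped reciprocal factor", {
  p <- par0
  tk <- bl_differentiation_factor(10, p)
  m <- case_multipliers(hypothesis_case(2), 10, p)
  expect_equal(unname(m["k1a"]), 1 / tk)
  # beyond the factor's root the reciprocal blows up and is capped
  m_hi <- case_multipliers(hypothesis_case(2, theta_k_max = 10), 90, p)
  expect_equal(unname(m_hi["k1a"]), 10)
  # decrease mode uses the bounded factor itself
  m_dec <- case_multipliers(hypothesis_case(2,
                                            theta_k_direction = "decrease"),
                            10, p)
  expect_equal(unname(m_dec["k1a"]), tk)
})

test_that("case 13 collapses to case 1 when theta_k is switched off", {
  sim1 <- simulate_treatment(protocol = pfaff_protocol(),
                             case = hypothesis_case(1))
  sim13 <- simulate_treatment(protocol = pfaff_protocol(),
                              case = hypothesis_case(13,
                                                     theta_k_direction = "off"))
  expect_equal(sim1$state, sim13$state, tolerance = 1e-10)
})

test_that("screen: only proliferation-rate cases suppress the
           proliferative capacity", {
  prot <- treatment_protocol(protocol_phase(14, "daily", 90, 1800))
  scr <- screen_cases(protocol = prot, cases = c(1, 2, 5))
  # case 1 (self-proliferation decreased): proliferative flux drops during
  # irradiation
  expect_lt(scr$case_1$proliferative[15], scr$case_1$proliferative[1])
  # division-only cases do not decrease the proliferative compartment
  expect_gte(scr$case_2$total[15] + 1e-6, scr$case_1$total[15])
  expect_gt(scr$case_2$differentiation[2], scr$case_1$differentiation[2])
  # with no treatment all cases coincide
  prot0 <- treatment_protocol(list(), follow_up_days = 10)
  scr0 <- screen_cases(protocol = prot0, cases = c(1, 8))
  expect_equal(scr0$case_1$total, scr0$case_8$total, tolerance = 1e-10)
})
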