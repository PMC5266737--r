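test_that("reference protocol yields 52 session days over 84 days", {
  cal <- build_calendar(pfaff_protocol())
  expect_length(cal, 84)
  expect_equal(sum(cal > 0), 28 + 24)  # 28 daily + 8 weeks x 3/wk
  expect_true(all(cal %in% c(0, 90)))
  # daily phase is solid, 3/wk phase follows the Mon/Wed/Fri pattern
  expect_true(all(cal[1:28] == 90))
  week5 <- cal[29:35]
  expect_equal(which(week5 > 0), c(1, 3, 5))
})

test_that("calendar handles cadences, follow-up and empty protocols", {
  prot <- treatment_protocol(
    list(protocol_phase(14, "every_other_day", fluence = 45)),
    follow_up_days = 7
  )
  cal <- build_calendar(prot)
  expect_length(cal, 21)
  expect_equal(which(cal > 0), seq(1, 13, by = 2))
  expect_equal(build_calendar(treatment_protocol(list(),
                                                 follow_up_days = 5)),
               rep(0, 5))
  alt <- treatment_protocol(
    list(protocol_phase(7, "three_per_week")),
    three_per_week_days = c(2, 4, 6)
  )
  expect_equal(which(build_calendar(alt) > 0), c(2, 4, 6))
  expect_error(treatment_protocol(list(), three_per_week_days = c(1, 1, 2)),
               "distinct")
  expect_error(protocol_phase(-3, "daily"), "non-negative")
  expect_error(protocol_phase(7, "daily", fluence = -1), "fluence")
})

test_that("intensities derive from fluence, session time and duty cycle", {
  ph <- protocol_phase(28, "daily", fluence = 90, session_time = 1800)
  ints <- phase_intensities(ph)
  expect_equal(unname(ints["I_av"]), 50)   # 90 J/cm2 over 30 min
  expect_equal(unname(ints["I_p"]), 50)    # CW: peak equals average
  pw <- protocol_phase(28, "daily", 90, 1800, mode = "PW", duty_cycle = 0.5)
  expect_equal(unname(phase_intensities(pw)["I_p"]), 100)
  expect_gte(unname(phase_intensities(pw)["I_p"]),
             unname(phase_intensities(pw)["I_av"]))
  expect_error(protocol_phase(28, "daily", session_time = 0), "session_time")
  expect_error(protocol_phase(28, "daily", mode = "PW", duty_cycle = 0),
               "duty_cycle")
})

test_that("total delivered fluence is conserved across irradiation modes", {
  cw <- treatment_protocol(protocol_phase(28, "daily", 90, 1800, "CW"))
  pw <- treatment_protocol(protocol_phase(28, "daily", 90, 900, "PW",
                                          duty_cycle = 0.25))
  cal_cw <- build_calendar(cw)
  cal_pw <- build_calendar(pw)
  expect_identical(cal_cw, cal_pw)   # identical model inputs
  expect_equal(sum(cal_cw), 90 * 28)
})
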