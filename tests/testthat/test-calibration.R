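test_that("synthetic dose-response tables behave like the assay", {
  tab0 <- synth_dose_response(noise_sd = 0, n_reps = 1)
  expect_equal(tab0$rel_density[tab0$fluence_J_cm2 == 0], 1)
  expect_true(all(diff(tab0$rel_density) < 0))  # monotone in fluence
  expect_true(all(tab0$rel_density >= 0 & tab0$rel_density <= 1.2))
  # reproducible under a fixed seed
  expect_identical(synth_dose_response(seed = 5),
                   synth_dose_response(seed = 5))
  expect_false(identical(synth_dose_response(seed = 5),
                         synth_dose_response(seed = 6)))
  tab <- synth_dose_response(noise_sd = 0.02, n_reps = 3, seed = 2)
  expect_equal(nrow(tab), 12)
  expect_named(tab, c("fluence_J_cm2", "rel_density", "replicate"))
  expect_error(synth_dose_response(noise_sd = -1), "noise_sd")
})

test_that("noiseless self-consistency recovers the coefficients exactly", {
  tab <- synth_dose_response(a_gamma = 1, b_gamma = -3.4e-3, noise_sd = 0,
                             n_reps = 1)
  fit <- fit_bl_coefficients(tab)
  expect_equal(fit$a_gamma, 1, tolerance = 1e-6)
  expect_equal(fit$b_gamma, -3.4e-3, tolerance = 1e-6)
})

test_that("degenerate tables are rejected as unidentifiable", {
  tab <- synth_dose_response(noise_sd = 0, fluences = 50, n_reps = 3)
  expect_error(fit_bl_coefficients(tab), "unidentifiable")
  tab2 <- synth_dose_response(noise_sd = 0, fluences = c(33, 66, 100))
  expect_error(fit_bl_coefficients(tab2), "control")
  expect_error(fit_bl_coefficients(data.frame(x = 1)), "columns")
})

test_that("noisy recovery: b_gamma within 10% (median over replications)", {
  rel_err <- vapply(1:100, function(seed) {
    tab <- synth_dose_response(noise_sd = 0.02, n_reps = 3, seed = seed)
    fit <- fit_bl_coefficients(tab)
    abs(fit$b_gamma - (-3.4e-3)) / 3.4e-3
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.10)
})

test_that("confidence intervals cover the generating value", {
  tab <- synth_dose_response(noise_sd = 0.02, n_reps = 5, seed = 9)
  fit <- fit_bl_coefficients(tab)
  expect_true(fit$ci["b_gamma", "lower"] <= -3.4e-3 + 2e-3)
  expect_lt(fit$ci["b_gamma", "lower"], fit$ci["b_gamma", "upper"])
})
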