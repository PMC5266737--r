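test_that("both blue-light factors equal 1 on non-treatment days", {
  expect_identical(bl_proliferation_factor(0, par0), 1)
  expect_identical(bl_differentiation_factor(0, par0),
                   par0$c_k - par0$a_k)  # 3.46 - 2.46 = 1
  expect_identical(bl_differentiation_factor(0, par0), 1)
  expect_equal(theta_beta_of_fluence(0, par0), 0)
})

test_that("proliferation factor follows the exponential decay, clamped", {
  expect_equal(bl_proliferation_factor(90, par0), exp(-3.40e-3 * 90))
  expect_equal(bl_proliferation_factor(90, par0), 0.7364, tolerance = 1e-4)
  expect_equal(bl_proliferation_factor(1e6, par0), 0)   # limit F -> Inf
  # a_gamma > 1 would exceed 1 at small F; the factor is clamped
  p <- default_parameters(overrides = list(a_gamma = 1.5))
  expect_equal(bl_proliferation_factor(0, p), 1)
  expect_error(bl_proliferation_factor(-1, par0), "non-negative")
})

test_that("differentiation factor hits zero near its root and clamps", {
  # root of c_k = a_k exp(b_k F): F = log(c_k/a_k)/b_k
  f_root <- log(par0$c_k / par0$a_k) / par0$b_k
  expect_equal(f_root, 17.6, tolerance = 2e-3)
  expect_equal(bl_differentiation_factor(f_root, par0), 0,
               tolerance = 1e-12)
  expect_equal(bl_differentiation_factor(100, par0), 0)  # raw value < 0
})

test_that("both theta factors are non-increasing in fluence", {
  f <- seq(0, 1000, by = 5)
  tg <- bl_proliferation_factor(f, par0)
  tk <- bl_differentiation_factor(f, par0)
  expect_true(all(diff(tg) <= 0))
  expect_true(all(diff(tk) <= 0))
  expect_true(all(tg >= 0 & tg <= 1))
  expect_true(all(tk >= 0 & tk <= 1))
})

test_that("apoptosis increment is a left-closed step function", {
  expect_equal(theta_beta_of_fluence(90, par0), 0)
  expect_equal(theta_beta_of_fluence(499.999, par0), 0)
  expect_equal(theta_beta_of_fluence(500, par0), 0.039)
  expect_equal(theta_beta_of_fluence(600, par0), 0.039)
  expect_equal(theta_beta_of_fluence(749.999, par0), 0.039)
  expect_equal(theta_beta_of_fluence(750, par0), 0.05)
  expect_equal(theta_beta_of_fluence(800, par0), 0.05)
})

test_that("stem regulation spans 1 at homeostasis to omega at zero TA", {
  expect_equal(stem_regulation_factor(par0$Pta_hom, 0, par0), 1)
  expect_equal(stem_regulation_factor(par0$Pta_hom / 2, par0$Pta_hom / 2,
                                      par0), 1)
  expect_equal(stem_regulation_factor(0, 0, par0), 100)
  expect_equal(stem_regulation_factor(2 * par0$Pta_hom, 0, par0),
               100 / 793, tolerance = 1e-12)
  expect_error(stem_regulation_factor(-1, 0, par0), "non-negative")
  p_bad <- par0
  p_bad$Pta_hom <- 0
  expect_error(stem_regulation_factor(1, 1, p_bad), "Pta_hom")
})

test_that("immune killing is a bounded Hill response", {
  expect_equal(immune_killing(0, par0), 0)
  expect_equal(immune_killing(par0$K_a, par0), par0$K_p / 2)
  expect_equal(immune_killing(6459, par0),
               6 * 6459^2 / (380^2 + 6459^2))
  expect_equal(immune_killing(6459, par0), 5.979, tolerance = 1e-3)
  expect_lt(immune_killing(1e9, par0), par0$K_p + 1e-9)
})
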