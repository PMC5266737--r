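test_that("default parameters reproduce the published table", {
  for (nm in names(table1_values)) {
    expect_equal(par0[[nm]], unname(table1_values[nm]),
                 info = nm, tolerance = 1e-12)
  }
})

test_that("apoptotic-index conversion reproduces the published rates", {
  b <- derived_apoptosis_rates(par0)
  # published values are printed to 3 significant figures; beta_1d is the
  # documented outlier (printed 2.01e-6 vs derived 1.996e-6, <1% apart)
  for (nm in names(table1_betas)) {
    tol <- if (nm == "beta_1d") 0.01 else 0.005
    expect_equal(b[[nm]], unname(table1_betas[nm]), tolerance = tol,
                 info = nm)
  }
  expect_equal(apoptosis_rate(0, 0.5), 0)
  expect_equal(apoptosis_rate(0.0012, 1.64e-3), 1.97e-6, tolerance = 5e-3)
  expect_equal(apoptosis_rate(0.00035, 9.72e-1), 3.40e-4, tolerance = 5e-3)
  # cytotoxic increment is additive
  expect_equal(apoptosis_rate(0.5, 1, theta_beta = 0.039), 1 + 0.039)
})

test_that("apoptosis rate rejects out-of-range inputs", {
  expect_error(apoptosis_rate(1, 0.5), "AI")
  expect_error(apoptosis_rate(1.5, 0.5), "AI")
  expect_error(apoptosis_rate(0.5, -1), "non-negative")
  expect_error(apoptosis_rate(0.5, 1, theta_beta = -0.1), "non-negative")
})

test_that("diseased rates: published table vs fold-change products", {
  tab <- derived_diseased_rates(par0, mode = "table")
  expect_equal(tab$gamma1_d, 1.16e-2)
  expect_equal(tab$alpha_d, 2.50e-1)
  prod <- derived_diseased_rates(par0, mode = "product")
  expect_equal(prod$gamma1_d, 3.30e-3 * 4)
  expect_equal(prod$k3_d, 2.16e-1 * 5)
  expect_equal(prod$alpha_d, 7.14e-2 * 4)
  # the two parameterizations genuinely disagree (documented)
  expect_false(isTRUE(all.equal(tab$gamma1_d, prod$gamma1_d)))
  expect_error(derived_diseased_rates(par0, mode = "other"))
  p_prod <- default_parameters(diseased_rates = "product")
  expect_equal(p_prod$gamma1_d, 1.32e-2)
})

test_that("parameter validation reports violated invariants", {
  expect_error(default_parameters(overrides = list(AI_h = 1.5)), "AI_h")
  expect_error(default_parameters(overrides = list(omega = 0.5)), "omega")
  expect_error(default_parameters(overrides = list(b_gamma = 0.1)),
               "b_gamma")
  expect_error(default_parameters(overrides = list(k3_h = -1)), "k3_h")
  expect_error(default_parameters(overrides = list(nonsense = 1)),
               "unknown parameter")
  expect_silent(validate_parameters(par0))
})
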