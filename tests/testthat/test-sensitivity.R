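test_that("KS statistic matches brute-force enumeration and stats::ks.test", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    d <- ks_statistic(x, y)
    expect_equal(d, ks_brute(x, y), info = i)
    expect_equal(d, unname(stats::ks.test(x, y)$statistic), info = i)
  }
  # degenerate cases
  expect_equal(ks_statistic(1:10, 1:10), 0)
  expect_equal(ks_statistic(1:10, 11:20), 1)  # disjoint supports
  expect_error(ks_statistic(numeric(0), 1:3), "non-empty")
})

test_that("MPSA separates influential from inert parameters", {
  # tiny protocol to keep the runs cheap; xi_abs is inert because the
  # incident-fluence convention never reads it
  prot <- treatment_protocol(protocol_phase(7, "daily", 90, 1800))
  m <- mpsa(parameters = c("gamma2_d", "k2s_d", "xi_abs"),
            n_samples = 150, seed = 11, protocol = prot)
  expect_true(all(is.na(m$D) | (m$D >= 0 & m$D <= 1)))
  expect_equal(nrow(m$samples), 150)
  expect_equal(m$n_failed, 0)
  # acceptable/unacceptable counts partition the samples per output
  expect_true(all(m$acceptable_counts >= 0 &
                    m$acceptable_counts <= 150))
  # the inert parameter's D sits at sampling-noise level, far below the
  # diseased TA proliferation rate's
  d_inert <- max(m$D["xi_abs", ], na.rm = TRUE)
  d_gamma <- max(m$D["gamma2_d", ], na.rm = TRUE)
  expect_gt(d_gamma, d_inert)
  expect_lt(d_inert, 0.3)
  expect_error(mpsa(n_samples = 50), "n_samples")
})

test_that("a perfectly separating parameter scores D = 1", {
  # direct construction: classification by thresholding the parameter
  # itself gives disjoint conditional distributions
  set.seed(3)
  theta <- runif(200)
  acc <- theta < stats::median(theta)
  expect_equal(ks_statistic(theta[acc], theta[!acc]), 1)
})

test_that("local sensitivities have the expected signs and magnitudes", {
  prot <- treatment_protocol(protocol_phase(14, "daily", 90, 1800))
  S <- lpsa(parameters = c("alpha_d", "gamma2_d", "xi_abs", "K_p"),
            protocol = prot)
  # faster desquamation removes cells: total density falls
  expect_lt(S["alpha_d", "total"], 0)
  # faster diseased TA proliferation grows the lesion
  expect_gt(S["gamma2_d", "total"], 0)
  # stronger immune killing removes diseased stem cells
  expect_lt(S["K_p", "Psc_d"], 0)
  # a parameter absent from the active equations has zero sensitivity
  expect_equal(unname(S["xi_abs", ]), rep(0, ncol(S)))
})
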