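test_that("chemical-shift perturbation identities hold", {
  expect_equal(csp(0, 0), 0)
  expect_equal(csp(0.3, 0), 0.3)
  expect_equal(csp(0, 1), 0.2)      # nitrogen scaled by 1/5
  expect_equal(csp(3, 20), 5)       # 3-4-5 triangle after scaling
  expect_equal(csp(-0.3, 0), 0.3)   # sign-invariant
  expect_equal(csp(c(0, 0.3), c(1, 0)), c(0.2, 0.3))
  d <- runif(5, -1, 1); n <- runif(5, -5, 5)
  expect_equal(csp(d, n), sqrt(d^2 + (n / 5)^2))
  expect_error(csp(NA, 1), "finite")
})

test_that("csp_profile pairs assignments by residue", {
  free <- tibble::tibble(residue = c(1, 2, 3),
                         hn = c(8.1, 8.3, 7.9),
                         n = c(120, 118, 125))
  bound <- tibble::tibble(residue = c(3, 1, 2),
                          hn = c(7.9, 8.2, 8.3),
                          n = c(126, 120, 118))
  prof <- csp_profile(free, bound)
  expect_equal(prof$residue, c(1, 2, 3))
  expect_equal(prof$csp,
               c(csp(-0.1, 0), csp(0, 0), csp(0, -1)))
  expect_error(csp_profile(free, bound[1:2, ]), "unmatched residues")
})

test_that("noiseless exponential fits recover the rate to 1e-9", {
  for (k in c(4.3e-5, 1.7e-5, 6.9e-6)) {
    ser <- make_decay_series(k)
    fit <- fit_exponential(ser, n_mc = 10, seed = 1)
    expect_lt(abs(fit$k_app - k), 1e-9)
    expect_lt(fit$residual_rms, 1e-10)
  }
})

test_that("rise-direction fits work on saturation-recovery-style data", {
  k <- 2.4e-5
  tt <- seq(0, 2e5, length.out = 30)
  ser <- tibble::tibble(time_s = tt, intensity = 1 - exp(-k * tt))
  fit <- fit_exponential(ser, direction = "rise", n_mc = 10, seed = 2)
  expect_lt(abs(fit$k_app - k), 1e-9)
})

test_that("Monte-Carlo uncertainty brackets the truth on noisy data", {
  k <- 4.3e-5
  ser <- make_decay_series(k, noise_sd = 0.01, seed = 42)
  fit <- fit_exponential(ser, n_mc = 100, seed = 42)
  expect_gt(fit$uncertainty, 0)
  expect_lt(abs(fit$k_app - k), 3 * fit$uncertainty)
  expect_length(fit$mc_k, 100)
  # seeded: same call, same result
  fit2 <- fit_exponential(ser, n_mc = 100, seed = 42)
  expect_identical(fit$k_app, fit2$k_app)
  expect_identical(fit$uncertainty, fit2$uncertainty)
})

test_that("tidy and glance summarise kinetics fits", {
  fit <- fit_exponential(make_decay_series(1e-5), n_mc = 10)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_true("k" %in% td$term)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("k_app", "uncertainty") %in% names(gl)))
  expect_s3_class(fit, "kinetics_fit")
  expect_output(print(fit), "k_app")
})

test_that("decay series generator is seeded and normalised", {
  s1 <- make_decay_series(1e-5, noise_sd = 0.02, seed = 7)
  s2 <- make_decay_series(1e-5, noise_sd = 0.02, seed = 7)
  expect_identical(s1, s2)
  expect_equal(s1$intensity[1], 1)
  s0 <- make_decay_series(2e-5)
  expect_equal(s0$intensity, exp(-2e-5 * s0$time_s))
  expect_error(make_decay_series(-1), "k >= 0")
})
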